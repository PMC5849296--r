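#' Time-calibrate a cladogram against stratigraphic ranges
#'
#' Minimal ("basic") time-scaling: each leaf is placed at its first
#' appearance age (after any curation override), and each internal node at
#' the maximum over its children of (child age + \code{min_branch}).
#' With \code{min_branch = 0} every divergence sits at the oldest first
#' appearance among its descendants, which minimises total implied ghost
#' lineage; a positive \code{min_branch} (e.g. 1 Ma) pushes every divergence
#' that much before its oldest child, which is the usual choice for plotting
#' so that internal branches are visible.
#'
#' Polytomies are calibrated as-is: all children share one parent age.
#'
#' @param tree a \code{"phylo"} cladogram (branch lengths ignored).
#' @param occ an [occurrenceTable()] covering every leaf.
#' @param min_branch minimum parent-child age gap in Ma (>= 0).
#' @return the tree with class \code{c("timeTree","phylo")}, edge lengths in
#'   Ma, and attributes \code{node.ages} (ages for tips then internal nodes,
#'   in \code{ape} numbering) and \code{ranges} (the per-leaf \code{[fad,lad]}
#'   used).
#' @export
calibrateTree <- function(tree, occ, min_branch = 0) {
  stopifnot(inherits(tree, "phylo"), inherits(occ, "occurrenceTable"))
  if (min_branch < 0) stop("min_branch must be >= 0")
  missing_tax <- setdiff(tree$tip.label, occ$taxon)
  if (length(missing_tax))
    stop("leaf without occurrence record: ", paste(missing_tax, collapse = ", "))
  n <- length(tree$tip.label)
  m <- tree$Nnode
  idx <- match(tree$tip.label, occ$taxon)
  ages <- numeric(n + m)
  ages[seq_len(n)] <- occ$fad[idx]
  # postorder over internal nodes: children always processed before parents
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; child <- po$edge[k, 2]
    ages[par] <- max(ages[par], ages[child] + min_branch)
  }
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  attr(tree, "node.ages") <- ages
  attr(tree, "ranges") <- data.frame(taxon = tree$tip.label,
                                     fad = occ$fad[idx], lad = occ$lad[idx])
  attr(tree, "min.branch") <- min_branch
  class(tree) <- c("timeTree", "phylo")
  tree
}

#' @export
print.timeTree <- function(x, ...) {
  ages <- attr(x, "node.ages")
  cat("timeTree:", length(x$tip.label), "leaves, root age",
      format(max(ages), digits = 6), "Ma, min_branch",
      attr(x, "min.branch"), "Ma\n")
  gl <- ghostLineages(x)
  cat("  ghost lineage:", nrow(gl), "segments,",
      format(sum(gl$start - gl$end), digits = 6), "Ma total\n")
  invisible(x)
}

#' Extract ghost-lineage segments from a calibrated tree
#'
#' A ghost segment is the unobserved part of an edge: for a leaf edge, the
#' interval from the divergence down to the leaf's first appearance; an
#' internal edge, carrying no observation, is ghost along its whole length.
#' Zero-length segments are omitted, so with \code{min_branch = 0} the edge
#' leading to the oldest leaf of each clade contributes nothing.
#'
#' @param tt a \code{"timeTree"} from [calibrateTree()].
#' @return data.frame with columns \code{lineage} (leaf name, or
#'   \code{node<k>} for internal edges), \code{start} (older end, Ma),
#'   \code{end} (younger end, Ma).
#' @export
ghostLineages <- function(tt) {
  segs <- .lineageSegments(tt)
  segs[segs$start > segs$end, , drop = FALSE]
}

# all unobserved edge portions, including zero-length ones
.lineageSegments <- function(tt) {
  stopifnot(inherits(tt, "timeTree"))
  ages <- attr(tt, "node.ages")
  rng <- attr(tt, "ranges")
  n <- length(tt$tip.label)
  par <- tt$edge[, 1]; child <- tt$edge[, 2]
  is_tip <- child <= n
  start <- ages[par]
  end <- ifelse(is_tip, rng$fad[child], ages[child])
  lineage <- ifelse(is_tip, tt$tip.label[child], paste0("node", child))
  out <- data.frame(lineage = lineage, start = start, end = end,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
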