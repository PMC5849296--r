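#' Build a descending grid of time bins
#'
#' Bins are contiguous half-open intervals \code{[top, top - width)} in Ma,
#' older edge inclusive, descending from \code{oldest}. Every instant belongs
#' to exactly one bin; an age equal to a bin's older edge belongs to that
#' bin.
#'
#' @param oldest,youngest span covered, Ma (\code{oldest > youngest}).
#' @param bin_width bin width in Ma (default 1).
#' @param labels optional stage/substage label per bin.
#' @return data.frame of class \code{"binGrid"} with columns \code{top},
#'   \code{bottom}, \code{mid} and optional \code{label}.
#' @export
binGrid <- function(oldest, youngest, bin_width = 1, labels = NULL) {
  if (!(oldest > youngest)) stop("oldest must exceed youngest")
  if (bin_width <= 0) stop("bin_width must be positive")
  nb <- ceiling((oldest - youngest) / bin_width - 1e-9)
  top <- oldest - (seq_len(nb) - 1) * bin_width
  out <- data.frame(top = top, bottom = top - bin_width, mid = top - bin_width / 2)
  if (!is.null(labels)) {
    if (length(labels) != nb) stop("labels must have one entry per bin")
    out$label <- labels
  }
  class(out) <- c("binGrid", "data.frame")
  out
}

# range [fad, lad] intersects bin (bottom, top] iff fad > bottom and lad <= top
.rangeInBin <- function(fad, lad, top, bottom) {
  outer(fad, bottom, ">") & outer(lad, top, "<=")
}

#' Taxic diversity curve
#'
#' Range-through species counts per bin: a taxon is counted in every bin its
#' \code{[fad, lad]} interval intersects, i.e. it is treated as present for
#' the entire length of its possible occurrence. Ranges extending beyond the
#' grid are clipped with a warning.
#'
#' @param occ an [occurrenceTable()].
#' @param grid a [binGrid()].
#' @return data.frame with the grid columns plus \code{taxic}.
#' @export
taxicDiversity <- function(occ, grid) {
  stopifnot(inherits(occ, "occurrenceTable"), inherits(grid, "binGrid"))
  if (nrow(occ) == 0L) stop("empty occurrence table")
  if (any(occ$fad > max(grid$top)) || any(occ$lad < min(grid$bottom)))
    warning("ranges extend beyond the bin grid and are clipped")
  hit <- .rangeInBin(occ$fad, occ$lad, grid$top, grid$bottom)
  out <- as.data.frame(grid)
  out$taxic <- colSums(hit)
  out
}

#' Phylogenetic (ghost-inclusive) diversity curve
#'
#' Counts, per bin, the lineages implied by a calibrated tree: observed
#' stratigraphic ranges (as in [taxicDiversity()]) plus ghost segments —
#' the unobserved portions of edges between a divergence and the first
#' appearance below it. Segment occupancy is open at the divergence and
#' closed at the first appearance, so a lineage is never double-counted in
#' the bin where its ghost portion hands over to its observed range, and an
#' edge ending exactly at a bin's older edge does not leak into that bin.
#' In bins younger than every divergence no ghost can be inferred and
#' phylogenetic diversity equals taxic diversity (the Signor-Lipps terminal
#' bias: with no younger relatives, ghost lineages cannot be drawn).
#'
#' @param tt a \code{"timeTree"} from [calibrateTree()].
#' @param grid a [binGrid()].
#' @param occ optional [occurrenceTable()] for the taxic component; defaults
#'   to the ranges stored in \code{tt}. Taxon sets must agree.
#' @return data.frame with the grid columns plus \code{taxic} and
#'   \code{phylogenetic}.
#' @export
phyloDiversity <- function(tt, grid, occ = NULL) {
  stopifnot(inherits(tt, "timeTree"), inherits(grid, "binGrid"))
  rng <- attr(tt, "ranges")
  if (is.null(occ)) {
    occ <- occurrenceTable(rng$taxon, rng$fad, rng$lad)
  } else if (!setequal(occ$taxon, tt$tip.label)) {
    stop("taxon sets differ between tree and occurrence table")
  }
  out <- taxicDiversity(occ, grid)
  segs <- ghostLineages(tt)
  # ghost occupancy (end, start]: intersects bin (bottom, top] iff
  # start > bottom and end < top (end itself already covered by the range)
  if (nrow(segs)) {
    hit <- outer(segs$start, grid$bottom, ">") & outer(segs$end, grid$top, "<")
    out$phylogenetic <- out$taxic + colSums(hit)
  } else {
    out$phylogenetic <- out$taxic
  }
  out
}
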