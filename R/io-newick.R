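#' Read a newick tree
#'
#' Parses a newick string (or file) into an \code{ape} \code{"phylo"} object.
#' Polytomies are allowed and branch lengths, when present, are preserved.
#' Leaf names must be unique. A single-leaf tree is accepted in the dialect
#' \code{"A;"}.
#'
#' @param text newick string. Exactly one of \code{text}/\code{file}.
#' @param file path to a newick file.
#' @return an object of class \code{"phylo"}.
#' @seealso [writeNewick()]
#' @export
readNewick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  .checkNewickSyntax(text)
  # single-leaf dialect "A;" has no parentheses; ape cannot represent it directly
  if (!grepl("(", text, fixed = TRUE)) {
    lab <- sub(";$", "", text)
    lab <- sub(":[0-9.eE+-]+$", "", lab)
    if (!nzchar(lab)) stop("newick parse error: empty taxon label")
    return(.singleTipPhylo(lab))
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("newick parse error: unparseable input")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("negative branch lengths in input")
  phy
}

# balance/termination pre-check so malformed input fails with a position
.checkNewickSyntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error at position %d: unbalanced ')'", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("newick parse error at position %d: %d unclosed '('",
                 length(chars), depth))
  if (!grepl(";\\s*$", text))
    stop(sprintf("newick parse error at position %d: missing terminal ';'",
                 max(1L, length(chars))))
  invisible(TRUE)
}

.singleTipPhylo <- function(label) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                 tip.label = label, Nnode = 1L),
            class = "phylo", order = "cladewise")
}

#' Write a newick tree
#'
#' Serialises a \code{"phylo"} object (optionally carrying node ages from
#' [calibrateTree()]) to newick. If the tree has node ages but no branch
#' lengths, edge lengths are emitted as parent age minus child age.
#' Single-leaf trees are written as \code{"A;"}.
#'
#' @param tree a \code{"phylo"} (or \code{"timeTree"}) object.
#' @param file optional path; when omitted the string is returned.
#' @param digits significant digits for branch lengths.
#' @return the newick string, invisibly when written to a file.
#' @export
writeNewick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ages <- attr(tree, "node.ages")
  if (is.null(tree$edge.length) && !is.null(ages))
    tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  if (length(tree$tip.label) == 1L) {
    out <- paste0(tree$tip.label, ";")
  } else {
    out <- ape::write.tree(tree, digits = digits)
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
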