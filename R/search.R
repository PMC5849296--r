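# Heuristic maximum-parsimony search: random addition sequences + SPR branch
# swapping, optional parsimony ratchet. Trees are manipulated as nested lists
# of tip indices (leaf = integer, internal node = list of >= 2 children),
# which makes pruning/regrafting simple; conversion to "phylo" happens at the
# boundary.

.nl2phylo <- function(nl, taxa) {
  n <- length(taxa)
  edges <- list(); nid <- n
  build <- function(node) {
    if (!is.list(node)) return(node)
    nid <<- nid + 1L
    me <- nid
    for (ch in node) {
      child <- build(ch)
      edges[[length(edges) + 1L]] <<- c(me, child)
    }
    me
  }
  root <- build(nl)
  edge <- do.call(rbind, edges)
  structure(list(edge = edge, tip.label = taxa, Nnode = nid - n),
            class = "phylo", order = "cladewise")
}

.phylo2nl <- function(phy) {
  n <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], factor(phy$edge[, 1], levels = seq_len(n + phy$Nnode)))
  rec <- function(v) {
    if (v <= n) return(v)
    lapply(kids[[v]], rec)
  }
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  rec(root)
}

# score a nested-list tree without building a phylo: assemble the traversal
# plan directly
.nlPlan <- function(nl, n) {
  children <- vector("list", 2L * n)
  order <- integer(0); nid <- n
  build <- function(node) {
    if (!is.list(node)) return(node)
    ids <- vapply(node, build, 0L)
    nid <<- nid + 1L
    children[[nid]] <<- ids
    order <<- c(order, nid)
    nid
  }
  root <- build(nl)
  list(n = n, children = children, order = order, root = root)
}

.nlLength <- function(nl, cm, weights) {
  plan <- .nlPlan(nl, nTaxa(cm))
  total <- 0
  for (j in seq_along(cm$cells)) {
    s <- if (cm$kind[j] == "unordered") {
      .stepsUnordered(plan, cm$cells[[j]])
    } else {
      iv <- .cellIntervals(cm, j)
      .stepsLinear(plan, iv$lo, iv$hi)
    }
    total <- total + weights[j] * s
  }
  total
}

# paths address subtrees: integer vectors of child positions from the root
.subtreePaths <- function(nl, path = integer(0)) {
  if (!is.list(nl)) return(list(path))
  out <- if (length(path)) list(path) else list()
  for (i in seq_along(nl))
    out <- c(out, .subtreePaths(nl[[i]], c(path, i)))
  out
}

.getAt <- function(nl, path) {
  for (i in path) nl <- nl[[i]]
  nl
}

.setAt <- function(nl, path, value) {
  if (!length(path)) return(value)
  nl[[path[1]]] <- .setAt(nl[[path[1]]], path[-1], value)
  nl
}

# attach `sub` beside the subtree at `path` (splitting its edge); empty path
# attaches at the root
.attachAt <- function(nl, path, sub) {
  old <- .getAt(nl, path)
  .setAt(nl, path, list(old, sub))
}

# detach the subtree at `path`, suppressing the resulting degree-2 node
.detachAt <- function(nl, path) {
  parent_path <- path[-length(path)]
  pos <- path[length(path)]
  parent <- .getAt(nl, parent_path)
  parent[[pos]] <- NULL
  if (length(parent) == 1L) parent <- parent[[1]]
  .setAt(nl, parent_path, parent)
}

# all trees one SPR move away (prune any subtree, regraft on any edge of the
# remainder, or at its root)
.sprNeighbors <- function(nl) {
  out <- list()
  for (p in .subtreePaths(nl)) {
    sub <- .getAt(nl, p)
    rest <- .detachAt(nl, p)
    if (!is.list(rest)) next           # remainder is a single tip
    sites <- c(.subtreePaths(rest), list(NULL))
    for (s in sites) {
      out[[length(out) + 1L]] <-
        if (is.null(s)) list(rest, sub) else .attachAt(rest, s, sub)
    }
  }
  out
}

.sprOptimize <- function(nl, cm, weights) {
  best <- .nlLength(nl, cm, weights)
  repeat {
    improved <- FALSE
    for (cand in .sprNeighbors(nl)) {
      len <- .nlLength(cand, cm, weights)
      if (len < best - 1e-9) {
        nl <- cand; best <- len; improved <- TRUE
        break
      }
    }
    if (!improved) return(list(tree = nl, length = best))
  }
}

# random addition sequence starting tree: insert taxa in random order at the
# cheapest position (ties broken at random)
.randomAddition <- function(cm, weights) {
  n <- nTaxa(cm)
  ord <- sample.int(n)
  nl <- list(ord[1], ord[2])
  for (t in ord[-(1:2)]) {
    sites <- c(.subtreePaths(nl), list(NULL))
    lens <- vapply(sites, function(s) {
      cand <- if (is.null(s)) list(nl, t) else .attachAt(nl, s, t)
      .nlLength(cand, cm, weights)
    }, 0)
    pick <- which(lens < min(lens) + 1e-9)
    s <- sites[[if (length(pick) > 1L) sample(pick, 1L) else pick]]
    nl <- if (is.null(s)) list(nl, t) else .attachAt(nl, s, t)
  }
  nl
}

# canonical unrooted-topology key: the sorted set of non-trivial bipartitions,
# each normalised to the side not containing tip 1
.topologyKey <- function(nl, n) {
  splits <- character(0)
  tipsBelow <- function(node) {
    if (!is.list(node)) return(node)
    tips <- sort(unlist(lapply(node, tipsBelow)))
    if (length(tips) >= 2L && length(tips) <= n - 2L) {
      side <- if (1L %in% tips) setdiff(seq_len(n), tips) else tips
      splits[[length(splits) + 1L]] <<- paste(side, collapse = ",")
    }
    tips
  }
  tipsBelow(nl)
  paste(sort(unique(splits)), collapse = "|")
}

# collapse internal edges whose removal leaves the length unchanged
.collapseZero <- function(nl, cm, weights) {
  base <- .nlLength(nl, cm, weights)
  repeat {
    done <- TRUE
    for (p in .subtreePaths(nl)) {
      sub <- .getAt(nl, p)
      if (!is.list(sub)) next
      parent <- .getAt(nl, p[-length(p)])
      flat <- c(parent[-p[length(p)]], sub)
      cand <- .setAt(nl, p[-length(p)], flat)
      if (.nlLength(cand, cm, weights) <= base + 1e-9) {
        nl <- cand; done <- FALSE
        break
      }
    }
    if (done) return(nl)
  }
}

#' Heuristic maximum-parsimony tree search
#'
#' Basic search: each replicate builds a random addition sequence starting
#' tree (taxa inserted in random order at the cheapest position) and improves
#' it by subtree pruning-and-regrafting until no move shortens the tree.
#' With \code{ratchet = TRUE} each replicate is followed by ratchet cycles
#' that upweight a random quarter of the characters, re-optimize, restore
#' equal weights and re-optimize, keeping the result when it is no worse.
#' All distinct equally best topologies across replicates are retained;
#' zero-length internal branches (whose collapse leaves the length unchanged)
#' are collapsed in the reported trees.
#'
#' @param cm a [characterMatrix()] (continuous characters rescaled).
#' @param n_replicates number of random addition sequence replicates.
#' @param ratchet logical; run parsimony-ratchet cycles per replicate.
#' @param seed RNG seed (the search is deterministic given the seed).
#' @param ratchet_cycles cycles per replicate when \code{ratchet} is on.
#' @return list of class \code{"parsimonySearch"}: \code{trees} (list of
#'   \code{"phylo"}, zero-length branches collapsed), \code{length},
#'   \code{score} (the [treeLength()] of the first best tree), and the
#'   search settings.
#' @export
heuristicSearch <- function(cm, n_replicates = 10, ratchet = FALSE, seed = 0,
                            ratchet_cycles = 3) {
  stopifnot(inherits(cm, "characterMatrix"))
  if (nTaxa(cm) < 4L) stop("need at least 4 taxa to search")
  if (any(cm$kind == "continuous") && !isTRUE(attr(cm, "rescaled")))
    stop("continuous characters must pass through rescaleContinuous() first")
  w <- cm$weight
  res <- withSeed(seed, {
    best_len <- Inf; best <- list()
    for (r in seq_len(n_replicates)) {
      nl <- .randomAddition(cm, w)
      opt <- .sprOptimize(nl, cm, w)
      if (ratchet) {
        for (cyc in seq_len(ratchet_cycles)) {
          wp <- w * ifelse(runif(length(w)) < 0.25, 2, 1)
          pert <- .sprOptimize(opt$tree, cm, wp)
          back <- .sprOptimize(pert$tree, cm, w)
          if (back$length <= opt$length + 1e-9) opt <- back
        }
      }
      if (opt$length < best_len - 1e-9) {
        best_len <- opt$length; best <- list(opt$tree)
      } else if (opt$length < best_len + 1e-9) {
        best <- c(best, list(opt$tree))
      }
    }
    list(len = best_len, trees = best)
  })
  collapsed <- lapply(res$trees, .collapseZero, cm = cm, weights = w)
  keys <- vapply(collapsed, .topologyKey, "", n = nTaxa(cm))
  collapsed <- collapsed[!duplicated(keys)]
  phylos <- lapply(collapsed, .nl2phylo, taxa = cm$taxa)
  structure(list(trees = phylos, length = res$len,
                 score = treeLength(phylos[[1]], cm),
                 n_replicates = n_replicates, ratchet = ratchet, seed = seed),
            class = "parsimonySearch")
}

#' @export
print.parsimonySearch <- function(x, ...) {
  cat(sprintf("parsimonySearch: %d best tree(s) of length %.6g (CI = %.3f, RI = %.3f)\n",
              length(x$trees), x$length, x$score$ci, x$score$ri))
  cat("  replicates:", x$n_replicates,
      if (x$ratchet) "(with ratchet)" else "(no ratchet)",
      " seed:", x$seed, "\n")
  invisible(x)
}
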