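#' Rescale continuous characters to unit range
#'
#' Maps every continuous character onto \code{[0, 1]} by
#' \code{(x - min) / (max - min)} over its observed values, so that one full
#' sweep of any continuous character costs one step, commensurate with a
#' binary discrete character. Step cost between values is then the absolute
#' difference. Characters with zero observed range are uninformative and are
#' dropped with a warning. Continuous characters must pass through this
#' rescaling before [treeLength()].
#'
#' @param cm a [characterMatrix()].
#' @return the rescaled \code{"characterMatrix"} (attribute
#'   \code{rescaled = TRUE}).
#' @export
rescaleContinuous <- function(cm) {
  stopifnot(inherits(cm, "characterMatrix"))
  drop <- integer(0)
  for (j in which(cm$kind == "continuous")) {
    v <- cm$cells[[j]]
    obs <- v[!is.na(v)]
    if (length(obs) == 0L || diff(range(obs)) == 0) {
      warning("zero-range continuous character dropped: ", j)
      drop <- c(drop, j)
      next
    }
    cm$cells[[j]] <- (v - min(obs)) / diff(range(obs))
  }
  if (length(drop)) {
    keep <- setdiff(seq_along(cm$cells), drop)
    cm$cells <- cm$cells[keep]
    cm$kind <- cm$kind[keep]
    cm$weight <- cm$weight[keep]
    cm$inapplicable <- cm$inapplicable[, keep, drop = FALSE]
  }
  attr(cm, "rescaled") <- TRUE
  cm
}

# ---- internal tree plumbing -------------------------------------------------

# bottom-up traversal plan: children list per node, internal nodes ordered
# children-before-parent
.treePlan <- function(phy) {
  n <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  children <- split(po$edge[, 2], factor(po$edge[, 1], levels = seq_len(n + phy$Nnode)))
  ord <- unique(po$edge[, 1])
  list(n = n, children = children, order = ord, root = ord[length(ord)])
}

# exact Sankoff pass for an unordered character (0/1 cost), any multifurcation.
# leafSets: list of integer state vectors per tip (integer(0) = missing)
.stepsUnordered <- function(plan, leafSets) {
  states <- sort(unique(unlist(leafSets)))
  if (length(states) <= 1L) return(0)
  S <- length(states)
  cost <- matrix(Inf, plan$n + length(plan$order), S)
  for (t in seq_len(plan$n)) {
    st <- leafSets[[t]]
    if (length(st) == 0L) cost[t, ] <- 0
    else cost[t, match(st, states)] <- 0
  }
  for (v in plan$order) {
    acc <- numeric(S)
    for (ch in plan$children[[v]]) {
      cc <- cost[ch, ]
      acc <- acc + pmin(cc, min(cc) + 1)
    }
    cost[v, ] <- acc
  }
  min(cost[plan$root, ])
}

# exact bottom-up interval (Farris/Wagner) pass for linear step costs,
# generalised to multifurcations: at each node the children's distance
# functions sum to a convex piecewise-linear f whose minimising set is the
# interval between the two middle order statistics of the children's interval
# endpoints; the accumulated minimum is added to the running length.
# Missing leaves carry the interval (-Inf, Inf) and constrain nothing.
.stepsLinear <- function(plan, leafLo, leafHi) {
  m <- plan$n + length(plan$order)
  lo <- c(leafLo, numeric(length(plan$order)))
  hi <- c(leafHi, numeric(length(plan$order)))
  total <- 0
  for (v in plan$order) {
    ch <- plan$children[[v]]
    cl <- lo[ch]; cu <- hi[ch]
    k <- length(ch)
    e <- sort(c(cl, cu))
    L <- e[k]; U <- e[k + 1L]
    if (is.infinite(L) && L < 0) {        # all children unconstrained
      lo[v] <- -Inf; hi[v] <- Inf
      next
    }
    fin <- is.finite(cl)                  # unconstrained children cost 0
    total <- total + sum(pmax(cl[fin] - L, 0) + pmax(L - cu[fin], 0))
    lo[v] <- L; hi[v] <- U
  }
  total
}

# per-cell intervals for ordered/continuous characters
.cellIntervals <- function(cm, j) {
  if (cm$kind[j] == "continuous") {
    v <- cm$cells[[j]]
    lo <- ifelse(is.na(v), -Inf, v)
    hi <- ifelse(is.na(v), Inf, v)
  } else {
    lo <- vapply(cm$cells[[j]], function(s) if (length(s)) min(s) else -Inf, 0)
    hi <- vapply(cm$cells[[j]], function(s) if (length(s)) max(s) else Inf, 0)
  }
  list(lo = lo, hi = hi)
}

# minimum conceivable steps on any tree
.minSteps <- function(cm, j) {
  if (cm$kind[j] == "unordered") {
    cells <- Filter(length, cm$cells[[j]])
    if (!length(cells)) return(0)
    states <- sort(unique(unlist(cells)))
    for (k in seq_along(states)) {
      subsets <- combn(states, k, simplify = FALSE)
      for (s in subsets)
        if (all(vapply(cells, function(cc) any(cc %in% s), TRUE)))
          return(k - 1)
    }
    length(states) - 1
  } else {
    iv <- .cellIntervals(cm, j)
    fin <- is.finite(iv$lo)
    if (sum(fin) < 2L) return(0)
    max(0, max(iv$lo[fin]) - min(iv$hi[fin]))
  }
}

# steps on a star phylogeny (the maximum relevant for the retention index)
.maxSteps <- function(cm, j) {
  if (cm$kind[j] == "unordered") {
    cells <- Filter(length, cm$cells[[j]])
    if (!length(cells)) return(0)
    states <- sort(unique(unlist(cells)))
    hits <- vapply(states, function(s)
      sum(vapply(cells, function(cc) s %in% cc, TRUE)), 0L)
    length(cells) - max(hits)
  } else {
    iv <- .cellIntervals(cm, j)
    fin <- is.finite(iv$lo)
    if (sum(fin) < 2L) return(0)
    lo <- iv$lo[fin]; hi <- iv$hi[fin]
    e <- sort(c(lo, hi))
    x <- e[length(lo)]                     # median interval endpoint
    sum(pmax(lo - x, 0) + pmax(x - hi, 0))
  }
}

#' Parsimony length of a tree and per-character step accounting
#'
#' Scores every character on the given tree: unordered characters by an
#' exact Sankoff pass under equal (0/1) step costs, ordered and (rescaled)
#' continuous characters by the bottom-up interval method with linear step
#' cost \code{|a - b|}; both passes are exact on multifurcating trees.
#' Missing and inapplicable cells constrain nothing; polymorphic cells
#' contribute their state set (any member state is free). Also computes each
#' character's minimum conceivable steps (on the best possible tree) and its
#' steps on a star phylogeny, from which the ensemble consistency and
#' retention indices follow.
#'
#' @param tree a \code{"phylo"} whose tips match the matrix taxa.
#' @param cm a [characterMatrix()]; continuous characters must have been
#'   rescaled with [rescaleContinuous()].
#' @param weights optional per-character weights overriding \code{cm$weight}.
#' @return an object of class \code{"treeScore"}: list with \code{length},
#'   per-character \code{steps}, \code{min_steps}, \code{max_steps},
#'   \code{weights}, and ensemble \code{ci}, \code{ri}.
#' @export
treeLength <- function(tree, cm, weights = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(cm, "characterMatrix"))
  if (!setequal(tree$tip.label, cm$taxa))
    stop("taxon sets differ between tree and character matrix")
  if (any(cm$kind == "continuous") && !isTRUE(attr(cm, "rescaled")))
    stop("continuous characters must pass through rescaleContinuous() first")
  if (is.null(weights)) weights <- cm$weight
  perm <- match(tree$tip.label, cm$taxa)
  plan <- .treePlan(tree)
  p <- nChars(cm)
  steps <- numeric(p)
  for (j in seq_len(p)) {
    if (cm$kind[j] == "unordered") {
      steps[j] <- .stepsUnordered(plan, cm$cells[[j]][perm])
    } else {
      iv <- .cellIntervals(cm, j)
      steps[j] <- .stepsLinear(plan, iv$lo[perm], iv$hi[perm])
    }
  }
  mins <- vapply(seq_len(p), function(j) .minSteps(cm, j), 0)
  maxs <- vapply(seq_len(p), function(j) .maxSteps(cm, j), 0)
  score <- structure(list(length = sum(weights * steps), steps = steps,
                          min_steps = mins, max_steps = maxs,
                          weights = weights),
                     class = "treeScore")
  ix <- tryCatch(ciRi(score), error = function(e) c(ci = NA_real_, ri = NA_real_))
  score$ci <- ix[["ci"]]; score$ri <- ix[["ri"]]
  score
}

#' @export
print.treeScore <- function(x, ...) {
  cat(sprintf("treeScore: length %.6g (CI = %.3f, RI = %.3f), %d characters\n",
              x$length, x$ci, x$ri, length(x$steps)))
  invisible(x)
}

#' Ensemble consistency and retention indices
#'
#' \code{CI = sum(m_i) / sum(s_i)} and
#' \code{RI = (sum(g_i) - sum(s_i)) / (sum(g_i) - sum(m_i))}, weighted, where
#' \code{m_i} is the minimum conceivable steps of character \code{i} on any
#' tree, \code{s_i} its observed steps and \code{g_i} its steps on a star
#' phylogeny. All variable characters enter both sums by default (invariant
#' characters contribute zero to every term); characters with
#' \code{g_i = m_i}, which cannot express homoplasy, are excluded from the
#' RI ratio per convention, and \code{informative_only = TRUE} excludes them
#' from CI as well.
#'
#' @param score a \code{"treeScore"} from [treeLength()].
#' @param informative_only drop characters with \code{g_i = m_i} from CI too.
#' @return named numeric vector \code{c(ci =, ri =)}.
#' @export
ciRi <- function(score, informative_only = FALSE) {
  stopifnot(inherits(score, "treeScore"))
  w <- score$weights
  s <- score$steps; m <- score$min_steps; g <- score$max_steps
  keep_ci <- if (informative_only) g > m else rep(TRUE, length(s))
  if (sum(w[keep_ci] * s[keep_ci]) == 0)
    stop("zero observed steps: CI undefined")
  ci <- sum(w[keep_ci] * m[keep_ci]) / sum(w[keep_ci] * s[keep_ci])
  keep <- g > m
  ri <- if (any(keep)) {
    (sum(w[keep] * g[keep]) - sum(w[keep] * s[keep])) /
      (sum(w[keep] * g[keep]) - sum(w[keep] * m[keep]))
  } else NA_real_
  c(ci = ci, ri = ri)
}
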