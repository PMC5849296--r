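#' Rarefy a disparity metric by resampling taxa
#'
#' For each subsample size, draws \code{n_reps} taxon subsets uniformly
#' without replacement from the group, evaluates the metric on the
#' full-data ordination scores of the subset (the ordination is not
#' recomputed, so all replicates share one geometry), and reports the mean
#' and 2.5/97.5 percentile bounds. At the full group size every draw is the
#' whole group, so the interval collapses onto the full-group value.
#'
#' @param ord an [pcoa()] ordination.
#' @param members taxon names forming the group.
#' @param metric \code{"sum"} ([sumOfRanges()]) or \code{"product"}
#'   ([productOfRanges()]).
#' @param levels subsample sizes (each between 1 and \code{length(members)}).
#' @param n_reps resamples per level (default 5000).
#' @param seed RNG seed (required for published runs; default 0).
#' @param axes axes passed to the metric; default all retained.
#' @param replace resample with replacement instead (off by default).
#' @param recompute re-ordinate each subsample instead of subsetting the
#'   full-data scores (sensitivity-analysis mode; requires \code{fm}).
#' @param fm the [functionalMatrix()] behind \code{ord}, needed only when
#'   \code{recompute = TRUE}.
#' @return data.frame of class \code{"rarefactionCurve"}: \code{level},
#'   \code{mean}, \code{lower}, \code{upper}; attributes \code{metric},
#'   \code{n_reps}, \code{seed}.
#' @export
rarefy <- function(ord, members, metric = c("sum", "product"), levels,
                   n_reps = 5000, seed = 0, axes = NULL, replace = FALSE,
                   recompute = FALSE, fm = NULL) {
  metric <- match.arg(metric)
  fn <- if (metric == "sum") sumOfRanges else productOfRanges
  .memberScores(ord, members, axes)  # validates members
  if (recompute && is.null(fm))
    stop("recompute = TRUE needs the functional matrix `fm`")
  evalSubset <- function(s) {
    if (!recompute) return(fn(ord, s, axes))
    d <- fm$data[s, , drop = FALSE]
    keep <- colSums(!is.na(d)) > 0L     # a character can vanish in a subset
    sub <- functionalMatrix(d[, keep, drop = FALSE], fm$kinds[keep],
                            levels = fm$levels)
    o <- tryCatch(suppressWarnings(pcoa(gowerDist(sub))),
                  error = function(e) NULL)
    if (is.null(o)) 0 else fn(o, rownames(o$scores))
  }
  N <- length(members)
  levels <- as.integer(levels)
  if (any(levels < 1L)) stop("levels must be >= 1")
  if (any(levels > N)) stop("level exceeds group size (", N, ")")
  out <- withSeed(seed, {
    do.call(rbind, lapply(levels, function(L) {
      if (L == N && !replace) {
        full <- evalSubset(members)
        reps <- rep(full, 1L)
      } else {
        reps <- vapply(seq_len(n_reps), function(i)
          evalSubset(sample(members, L, replace = replace)), 0)
      }
      q <- quantile(reps, c(0.025, 0.975), names = FALSE)
      data.frame(level = L, mean = mean(reps), lower = q[1], upper = q[2])
    }))
  })
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  class(out) <- c("rarefactionCurve", "data.frame")
  out
}

# run code under a local RNG seed, restoring global state afterwards
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
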