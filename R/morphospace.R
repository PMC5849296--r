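#' Gower dissimilarity for mixed, incomplete trait data
#'
#' Pairwise dissimilarity \eqn{d_{ij} = \sum_k w_{ijk}\delta_{ijk} /
#' \sum_k w_{ijk}} where \eqn{w_{ijk} = 1} iff character \eqn{k} is observed
#' in both taxa. Per-character contributions: continuous and ordered
#' characters use the range-scaled absolute difference
#' \eqn{|x_i - x_j| / R_k} (ordered states coded as equally spaced ranks);
#' categorical characters contribute 0/1 for match/mismatch. Ranges
#' \eqn{R_k} are taken over the whole matrix — all time bins pooled — so that
#' taxa from different bins live in one comparable space. Continuous
#' characters with zero observed range carry no signal and are dropped with
#' a warning.
#'
#' @param fm a [functionalMatrix()].
#' @return a \code{stats::dist} object (values in \code{[0, 1]}).
#' @export
gowerDist <- function(fm) {
  stopifnot(inherits(fm, "functionalMatrix"))
  n <- nrow(fm$data)
  taxa <- rownames(fm$data)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (j in colnames(fm$data)) {
    v <- fm$data[[j]]
    kind <- fm$kinds[[j]]
    if (kind == "ordered") v <- as.numeric(match(v, fm$levels[[j]]) - 1L)
    obs <- !is.na(v)
    w <- outer(obs, obs, "&")
    if (kind == "categorical") {
      delta <- outer(v, v, "!=")
      delta[!w] <- FALSE
      contrib <- delta * 1
    } else {
      R <- diff(range(v[obs]))
      if (R == 0) {
        warning("zero-range character dropped: ", j)
        next
      }
      vv <- v; vv[!obs] <- 0  # masked below
      contrib <- abs(outer(vv, vv, "-")) / R
      contrib[!w] <- 0
    }
    num <- num + contrib
    den <- den + w
  }
  offdiag <- row(den) != col(den)
  if (any(den[offdiag] == 0)) {
    bad <- which(den == 0 & offdiag, arr.ind = TRUE)[1, ]
    stop("taxon pair with no jointly observed characters: ",
         taxa[bad[1]], " / ", taxa[bad[2]])
  }
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(taxa, taxa)
  stats::as.dist(d)
}

#' Principal coordinates analysis
#'
#' Classical metric MDS: squared dissimilarities are double-centred
#' (\eqn{B = -\tfrac12 J D^{(2)} J}), the Gram matrix is
#' eigendecomposed, and scores are eigenvectors scaled by the square roots of
#' their eigenvalues. Axes whose eigenvalue falls below
#' \code{tol * max(eigenvalue)} are not retained; negative eigenvalues (which
#' arise because Gower dissimilarities need not be Euclidean-embeddable) are
#' dropped by default, or absorbed with the Lingoes additive-constant
#' correction via \code{correction = "lingoes"}. Percent variance is each
#' positive eigenvalue over the sum of positive eigenvalues.
#'
#' @param d a \code{dist} object or symmetric dissimilarity matrix.
#' @param correction \code{"none"} (default) or \code{"lingoes"}.
#' @param tol relative eigenvalue tolerance for axis retention.
#' @return an object of class \code{"ordination"}: list with \code{scores}
#'   (taxa x axes), \code{eigenvalues} (retained), \code{pct_variance},
#'   \code{all_eigenvalues}, \code{correction}.
#' @export
pcoa <- function(d, correction = c("none", "lingoes"), tol = 1e-10) {
  correction <- match.arg(correction)
  D <- as.matrix(d)
  if (nrow(D) < 2L) stop("need at least two points")
  taxa <- rownames(D) %||% paste0("t", seq_len(nrow(D)))
  ev <- .pcoaEigen(D)
  if (correction == "lingoes" && min(ev$values) < -1e-12) {
    c2 <- -min(ev$values)
    D2 <- D^2 + 2 * c2
    diag(D2) <- 0
    ev <- .pcoaEigen(sqrt(D2))
  }
  lam <- ev$values
  lmax <- max(lam)
  if (lmax <= 0) stop("no positive eigenvalue: degenerate configuration")
  keep <- which(lam > tol * lmax)
  scores <- ev$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam[keep]), length(keep))
  rownames(scores) <- taxa
  colnames(scores) <- paste0("Axis", seq_along(keep))
  structure(list(scores = scores,
                 eigenvalues = lam[keep],
                 pct_variance = 100 * lam[keep] / sum(lam[lam > 0]),
                 all_eigenvalues = lam,
                 correction = correction),
            class = "ordination")
}

.pcoaEigen <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  eigen((B + t(B)) / 2, symmetric = TRUE)
}

#' @export
print.ordination <- function(x, ...) {
  cat("ordination:", nrow(x$scores), "points,", ncol(x$scores), "retained axes",
      if (x$correction != "none") paste0("(", x$correction, " correction)"), "\n")
  k <- min(7L, length(x$pct_variance))
  cat("  % variance:", paste(sprintf("%.1f", x$pct_variance[seq_len(k)]),
                             collapse = ", "),
      if (length(x$pct_variance) > k) "...", "\n")
  invisible(x)
}

.memberScores <- function(ord, members, axes = NULL) {
  stopifnot(inherits(ord, "ordination"))
  if (length(members) == 0L) stop("empty member set")
  miss <- setdiff(members, rownames(ord$scores))
  if (length(miss)) stop("members absent from ordination: ",
                         paste(miss, collapse = ", "))
  if (is.null(axes)) axes <- seq_len(ncol(ord$scores))
  ord$scores[members, axes, drop = FALSE]
}

#' Sum of ranges disparity
#'
#' Total spread of a group in ordination space: the sum over axes of the
#' range (max minus min) of the member scores. Zero for a single taxon.
#'
#' @param ord an [pcoa()] ordination.
#' @param members taxon names (subset of the ordination).
#' @param axes axes to use; default all retained axes.
#' @return a single number.
#' @export
sumOfRanges <- function(ord, members, axes = NULL) {
  s <- .memberScores(ord, members, axes)
  if (nrow(s) <= 1L) return(0)
  sum(apply(s, 2, function(x) diff(range(x))))
}

#' Product of ranges disparity
#'
#' Volume proxy of occupied morphospace: the product over axes of the range
#' of the member scores. Zero for a single taxon or any zero-range axis.
#'
#' @inheritParams sumOfRanges
#' @return a single number.
#' @export
productOfRanges <- function(ord, members, axes = NULL) {
  s <- .memberScores(ord, members, axes)
  if (nrow(s) <= 1L) return(0)
  prod(apply(s, 2, function(x) diff(range(x))))
}

#' Per-group disparity table
#'
#' @param ord an [pcoa()] ordination.
#' @param groups named character/factor: group label per taxon (e.g. the
#'   \code{bin} of a [functionalMatrix()]).
#' @param axes axes to use; default all retained axes.
#' @return data.frame with one row per group: \code{group}, \code{n_taxa},
#'   \code{sum_of_ranges}, \code{product_of_ranges}, \code{axes_used}.
#' @export
disparity <- function(ord, groups, axes = NULL) {
  groups <- groups[!is.na(groups)]
  if (is.null(axes)) axes <- seq_len(ncol(ord$scores))
  split_taxa <- split(names(groups), as.character(groups))
  out <- do.call(rbind, lapply(names(split_taxa), function(g) {
    mem <- split_taxa[[g]]
    data.frame(group = g, n_taxa = length(mem),
               sum_of_ranges = sumOfRanges(ord, mem, axes),
               product_of_ranges = productOfRanges(ord, mem, axes),
               axes_used = length(axes))
  }))
  rownames(out) <- NULL
  out
}

#' Scan axis-subset choices for the range metrics
#'
#' Range-based disparity depends on how many ordination axes are retained,
#' and published values do not always state the choice. This audit helper
#' recomputes both metrics per group for every leading axis subset
#' (axes 1..k for each k) and for all retained axes, so a reported value can
#' be matched against the subset that produced it.
#'
#' @inheritParams disparity
#' @param max_axes largest leading subset to scan (default: all retained).
#' @return data.frame with columns \code{axes} (k, the leading-subset size),
#'   \code{group}, \code{n_taxa}, \code{sum_of_ranges},
#'   \code{product_of_ranges}.
#' @export
disparityAxisScan <- function(ord, groups, max_axes = NULL) {
  K <- ncol(ord$scores)
  if (is.null(max_axes)) max_axes <- K
  max_axes <- min(max_axes, K)
  out <- do.call(rbind, lapply(seq_len(max_axes), function(k) {
    d <- disparity(ord, groups, axes = seq_len(k))
    d$axes_used <- NULL
    cbind(axes = k, d)
  }))
  rownames(out) <- NULL
  out
}

#' Isometric mass ratio from a linear dimension
#'
#' Under isometric scaling, mass scales with the cube of any linear
#' dimension, so two individuals whose homologous bones measure
#' \code{length_a} and \code{length_b} differ in mass by
#' \code{(length_a / length_b)^3}.
#'
#' @param length_a,length_b positive lengths (same unit, e.g. mm).
#' @return the mass ratio (multiply by 100 for percent).
#' @examples
#' isometricMassRatio(2, 1)    # 8
#' isometricMassRatio(165, 93) # ~5.59, i.e. ~560%
#' @export
isometricMassRatio <- function(length_a, length_b) {
  if (any(length_a <= 0) || any(length_b <= 0)) stop("lengths must be positive")
  (length_a / length_b)^3
}
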