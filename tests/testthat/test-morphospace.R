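test_that("gower distance: identity, simple mismatch arithmetic, bounds", {
  df <- data.frame(a = c("x", "x", "y"), b = c("p", "p", "p"),
                   c = c(1, 1, 3), d = c(0, 0, 1),
                   row.names = c("t1", "t2", "t3"))
  fm <- functionalMatrix(df, c(a = "categorical", b = "categorical",
                               c = "continuous", d = "continuous"))
  D <- as.matrix(gowerDist(fm))
  expect_equal(D["t1", "t2"], 0)            # identical rows
  expect_equal(D["t1", "t3"], 0.75)         # three of four characters disagree fully
  df2 <- df; df2["t3", c("c", "d")] <- c(1, 0)
  fm2 <- functionalMatrix(df2, c(a = "categorical", b = "categorical",
                                 c = "continuous", d = "continuous"))
  expect_warning(gowerDist(fm2), "zero-range")
  D2 <- as.matrix(suppressWarnings(gowerDist(fm2)))
  # both continuous characters now carry no range and drop; one categorical
  # mismatch over the two remaining characters
  expect_equal(D2["t1", "t3"], 0.5)
})

test_that("one categorical mismatch among four observed characters gives 1/4", {
  df <- data.frame(a = c("x", "y"), b = c("p", "p"),
                   c = c(0, 0), d = c("m", "m"),
                   row.names = c("t1", "t2"))
  # give the continuous character range via a third taxon
  df <- rbind(df, t3 = list("x", "q", 2, "n"))
  fm <- functionalMatrix(df, c(a = "categorical", b = "categorical",
                               c = "continuous", d = "categorical"))
  expect_equal(as.matrix(gowerDist(fm))["t1", "t2"], 0.25)
})

test_that("gower equals the naive cell-by-cell oracle on random mixed data", {
  set.seed(99)
  for (i in 1:25) {
    fm <- randomFunctionalMatrix(n = sample(5:10, 1), missing_frac = 0.2)
    D <- as.matrix(gowerDist(fm))
    expect_equal(D, naiveGower(fm), tolerance = 1e-12)
    expect_true(all(D >= 0 & D <= 1 + 1e-12))
    expect_true(isSymmetric(D))
  }
})

test_that("gower agrees with cluster::daisy on complete mixed data", {
  set.seed(4)
  df <- data.frame(a = factor(sample(c("x", "y", "z"), 8, TRUE)),
                   o = factor(sample(c("lo", "mid", "hi"), 8, TRUE),
                              levels = c("lo", "mid", "hi"), ordered = TRUE),
                   c1 = runif(8), c2 = rnorm(8),
                   row.names = paste0("t", 1:8))
  fm <- functionalMatrix(
    data.frame(a = as.character(df$a), o = as.character(df$o),
               c1 = df$c1, c2 = df$c2, row.names = rownames(df)),
    c(a = "categorical", o = "ordered", c1 = "continuous", c2 = "continuous"),
    levels = list(o = c("lo", "mid", "hi")))
  ref <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(as.matrix(gowerDist(fm)), ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("gower errors when a pair shares no observed characters", {
  df <- data.frame(a = c("x", NA, "x"), b = c(NA, "p", "p"),
                   row.names = c("t1", "t2", "t3"))
  fm <- functionalMatrix(df, c(a = "categorical", b = "categorical"))
  expect_error(gowerDist(fm), "no jointly observed")
})

test_that("pcoa: collinear configuration collapses to one axis", {
  x <- c(0, 1, 3)
  D <- as.matrix(dist(x))
  ord <- pcoa(D)
  expect_equal(ncol(ord$scores), 1L)
  expect_equal(diff(range(ord$scores[, 1])), 3)
  expect_equal(ord$pct_variance[1], 100)
})

test_that("pcoa reconstructs Euclidean distances to 1e-9", {
  set.seed(12)
  for (i in 1:10) {
    pts <- matrix(rnorm(2 * 12), ncol = 2)
    D <- dist(pts)
    ord <- pcoa(D)
    expect_lt(max(abs(dist(ord$scores) - D)), 1e-9)
    # eigenvalue sum equals the trace of the centred Gram matrix
    B <- pterodiv:::.pcoaEigen(as.matrix(D))
    expect_equal(sum(ord$all_eigenvalues), sum(diag(
      (function(M) M)( -0.5 * (diag(12) - 1/12) %*% as.matrix(D)^2 %*%
                         (diag(12) - 1/12)))), tolerance = 1e-8)
  }
})

test_that("pcoa matches ape::pcoa on a Gower matrix; lingoes removes negatives", {
  set.seed(3)
  fm <- randomFunctionalMatrix(n = 9, missing_frac = 0.15)
  D <- gowerDist(fm)
  ours <- pcoa(D)
  ref <- ape::pcoa(D)
  k <- min(ncol(ours$scores), 5)
  expect_equal(ours$eigenvalues[1:k], ref$values$Eigenvalues[1:k],
               tolerance = 1e-8)
  for (a in 1:k)
    expect_equal(abs(ours$scores[, a]), abs(ref$vectors[, a]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  lin <- pcoa(D, correction = "lingoes")
  expect_true(min(lin$all_eigenvalues) > -1e-8)
})

test_that("range metrics: hand values, degenerate groups, monotonicity", {
  sc <- matrix(c(0, 0,  2, 1,  1, 3), ncol = 2, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), NULL))
  ord <- structure(list(scores = sc, eigenvalues = c(1, 1),
                        pct_variance = c(50, 50), correction = "none"),
                   class = "ordination")
  expect_equal(sumOfRanges(ord, c("a", "b", "c")), 2 + 3)
  expect_equal(productOfRanges(ord, c("a", "b", "c")), 2 * 3)
  expect_equal(sumOfRanges(ord, "a"), 0)
  expect_equal(productOfRanges(ord, "a"), 0)
  expect_equal(productOfRanges(ord, c("a", "b"), axes = 1), 2)
  expect_error(sumOfRanges(ord, character(0)), "empty")
  expect_error(sumOfRanges(ord, "zz"), "absent")

  set.seed(31)
  fm <- randomFunctionalMatrix(10, 0.1)
  o2 <- pcoa(gowerDist(fm))
  taxa <- rownames(o2$scores)
  for (i in 1:20) {
    small <- sample(taxa, 3)
    big <- union(small, sample(taxa, 3))
    expect_gte(sumOfRanges(o2, big), sumOfRanges(o2, small))
    expect_gte(productOfRanges(o2, big), productOfRanges(o2, small))
  }
  # time-averaging: pooling two sub-bins never decreases either metric
  binA <- taxa[1:4]; binB <- taxa[5:8]
  expect_gte(sumOfRanges(o2, c(binA, binB)),
             max(sumOfRanges(o2, binA), sumOfRanges(o2, binB)))
  expect_gte(productOfRanges(o2, c(binA, binB)),
             max(productOfRanges(o2, binA), productOfRanges(o2, binB)))
})

test_that("axis-subset scan is consistent with direct disparity calls", {
  set.seed(14)
  fm <- randomFunctionalMatrix(9, 0.1)
  ord <- pcoa(gowerDist(fm))
  groups <- setNames(rep(c("G1", "G2"), length.out = 9), rownames(ord$scores))
  scan <- disparityAxisScan(ord, groups)
  for (k in unique(scan$axes)) {
    direct <- disparity(ord, groups, axes = seq_len(k))
    sub <- scan[scan$axes == k, ]
    expect_equal(sub$sum_of_ranges, direct$sum_of_ranges)
    expect_equal(sub$product_of_ranges, direct$product_of_ranges)
  }
})

test_that("isometric scaling follows the cube law", {
  expect_equal(isometricMassRatio(2, 1), 8)
  expect_equal(isometricMassRatio(10, 10), 1)
  expect_error(isometricMassRatio(0, 1), "positive")
})
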