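mkDiscrete <- function(states_by_taxon, kind = "unordered") {
  n <- length(states_by_taxon)
  characterMatrix(list(lapply(states_by_taxon, function(s)
    if (length(s) == 1 && is.na(s)) integer(0) else as.integer(s))),
    paste0("t", seq_len(n)), kind)
}

test_that("unit-range rescaling of continuous characters", {
  cmFrom <- function(v) characterMatrix(list(v), paste0("t", seq_along(v)),
                                        "continuous")
  expect_equal(rescaleContinuous(cmFrom(c(2, 4, 6)))$cells[[1]], c(0, 0.5, 1))
  expect_equal(rescaleContinuous(cmFrom(c(0, 0.25, 1)))$cells[[1]],
               c(0, 0.25, 1))                        # already unit range
  expect_equal(rescaleContinuous(cmFrom(c(NA, 10, 20)))$cells[[1]],
               c(NA, 0, 1))                          # missing ignored in range
  expect_warning(out <- rescaleContinuous(cmFrom(c(5, 5, 5))), "zero-range")
  expect_equal(nChars(out), 0L)
})

test_that("single derived taxon costs one step on any topology", {
  cm <- mkDiscrete(list(0L, 0L, 0L, 1L))
  for (nwk in c("((t1,t2),(t3,t4));", "(((t1,t2),t3),t4);", "((t1,t4),(t2,t3));")) {
    expect_equal(treeLength(readNewick(nwk), cm)$length, 1)
  }
})

test_that("tree length equals exhaustive assignment enumeration (discrete)", {
  set.seed(17)
  for (i in 1:12) {
    n <- sample(5:7, 1)
    cm <- randomDiscreteMatrix(n, 3, n_states = 3, p_missing = 0.15, p_poly = 0.15)
    tr <- ape::rtree(n, tip.label = cm$taxa)
    sc <- treeLength(tr, cm)
    expect_equal(sc$length, bruteTreeLength(tr, cm))
    expect_true(all(sc$min_steps <= sc$steps + 1e-12))
    expect_true(all(sc$steps <= sc$max_steps + 1e-12))
  }
})

test_that("tree length matches phangorn Fitch on binary characters", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample(6:10, 1)
    cm <- randomDiscreteMatrix(n, 8, n_states = 2, p_missing = 0.1, p_poly = 0)
    tr <- ape::rtree(n, tip.label = cm$taxa)
    states <- sapply(cm$cells, function(col) vapply(col, function(s)
      if (length(s) == 0) "?" else as.character(s), ""))
    rownames(states) <- cm$taxa
    pd <- phangorn::phyDat(states, type = "USER", levels = c("0", "1"),
                           ambiguity = "?")
    expect_equal(treeLength(tr, cm)$length,
                 as.numeric(phangorn::parsimony(tr, pd)))
  }
})

test_that("ordered characters accrue linear step costs", {
  cm <- mkDiscrete(list(0L, 2L, 0L, 2L), kind = "ordered")
  # ((0,2),(0,2)): best assignment repeats the sweep on both sides
  expect_equal(treeLength(readNewick("((t1,t2),(t3,t4));"), cm)$length, 4)
  # ((0,0),(2,2)) needs a single sweep of 2
  cm2 <- mkDiscrete(list(0L, 0L, 2L, 2L), kind = "ordered")
  expect_equal(treeLength(readNewick("((t1,t2),(t3,t4));"), cm2)$length, 2)
})

test_that("continuous characters: interval method vs grid brute force", {
  v <- c(0, 0.5, 1)
  cm <- characterMatrix(list(v), c("t1", "t2", "t3"), "continuous")
  cm <- rescaleContinuous(cm)
  expect_equal(treeLength(readNewick("((t1,t2),t3);"), cm)$length, 1)

  set.seed(29)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    v <- round(runif(n), 2)
    v[sample(n, 1)] <- NA
    cm <- characterMatrix(list(v), paste0("t", 1:n), "continuous")
    attr(cm, "rescaled") <- TRUE
    tr <- ape::rtree(n, tip.label = cm$taxa)
    expect_equal(treeLength(tr, cm)$length, bruteTreeLength(tr, cm),
                 tolerance = 1e-9)
  }
})

test_that("multifurcating trees are scored exactly (vs brute force)", {
  set.seed(37)
  for (i in 1:8) {
    n <- 6
    tr <- ape::di2multi(ape::rtree(n), tol = 0.6)  # induce polytomies
    cm <- randomDiscreteMatrix(n, 2, n_states = 3, p_missing = 0.1, p_poly = 0.1)
    tr$tip.label <- cm$taxa
    expect_equal(treeLength(tr, cm)$length, bruteTreeLength(tr, cm))
    v <- round(runif(n), 2)
    cmc <- characterMatrix(list(v), cm$taxa, "continuous")
    attr(cmc, "rescaled") <- TRUE
    expect_equal(treeLength(tr, cmc)$length, bruteTreeLength(tr, cmc),
                 tolerance = 1e-9)
  }
})

test_that("parsimony length is invariant to the root position", {
  set.seed(41)
  cm <- randomDiscreteMatrix(8, 6, n_states = 3, p_missing = 0.1, p_poly = 0.1)
  tr <- ape::rtree(8, tip.label = cm$taxa)
  base <- treeLength(tr, cm)$length
  for (tip in sample(cm$taxa, 3)) {
    rr <- ape::root(ape::unroot(tr), outgroup = tip, resolve.root = TRUE)
    expect_equal(treeLength(rr, cm)$length, base)
  }
})

test_that("consistency and retention indices: clean and homoplastic cases", {
  # homoplasy-free: two congruent binary characters on a 4-taxon tree
  cells <- list(lapply(c(0L, 0L, 1L, 1L), identity),
                lapply(c(0L, 0L, 1L, 1L), identity))
  cm <- characterMatrix(cells, paste0("t", 1:4), rep("unordered", 2))
  sc <- treeLength(readNewick("((t1,t2),(t3,t4));"), cm)
  expect_equal(sc$ci, 1)
  expect_equal(sc$ri, 1)

  # one binary character with two independent origins: m=1, s=2, g=2
  cm2 <- mkDiscrete(list(1L, 0L, 1L, 0L))
  sc2 <- treeLength(readNewick("((t1,t2),(t3,t4));"), cm2)
  expect_equal(unname(sc2$steps), 2)
  expect_equal(unname(sc2$min_steps), 1)
  expect_equal(unname(sc2$max_steps), 2)
  expect_equal(sc2$ci, 0.5)
  expect_equal(sc2$ri, 0)

  # invariant matrix: CI undefined
  cm3 <- mkDiscrete(list(0L, 0L, 0L, 0L))
  sc3 <- treeLength(readNewick("((t1,t2),(t3,t4));"), cm3)
  expect_error(ciRi(sc3), "undefined")
})

test_that("scoring requires matching taxa and rescaled continuous input", {
  cm <- randomDiscreteMatrix(5, 2)
  expect_error(treeLength(ape::rtree(5, tip.label = paste0("x", 1:5)), cm),
               "taxon sets differ")
  v <- c(0, 3, 7, 2, 9)
  cmc <- characterMatrix(list(v), cm$taxa, "continuous")
  tr <- ape::rtree(5, tip.label = cm$taxa)
  expect_error(treeLength(tr, cmc), "rescaleContinuous")
})
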