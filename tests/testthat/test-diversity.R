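test_that("range-through counting respects the half-open bin convention", {
  occ <- occurrenceTable("T1", fad = 70, lad = 66)
  g <- binGrid(70, 65)
  td <- taxicDiversity(occ, g)
  # present in [70,69) ... [67,66), and in [66,65) because its lad equals
  # that bin's older edge
  expect_equal(td$taxic, c(1, 1, 1, 1, 1))

  pt <- occurrenceTable("P", fad = 66, lad = 66)       # point occurrence
  expect_equal(taxicDiversity(pt, g)$taxic, c(0, 0, 0, 0, 1))

  dj <- occurrenceTable(c("A", "B"), fad = c(80, 70), lad = c(78, 66))
  gd <- binGrid(80, 66)
  td2 <- taxicDiversity(dj, gd)
  interior <- td2$top <= 77 & td2$top > 70
  expect_true(all(td2$taxic[interior] == 0))
})

test_that("taxic counts agree with a per-bin brute-force membership oracle", {
  set.seed(21)
  fad <- runif(200, 66, 90)
  occ <- occurrenceTable(paste0("t", 1:200), fad, fad - runif(200, 0, 8))
  occ$lad <- pmax(occ$lad, 60)
  g <- binGrid(90, 60)
  td <- taxicDiversity(occ, g)
  for (b in seq_len(nrow(g))) {
    manual <- sum(vapply(seq_len(200), function(i) {
      any_in <- occ$fad[i] > g$bottom[b] && occ$lad[i] <= g$top[b]
      any_in
    }, TRUE))
    expect_equal(td$taxic[b], manual, ignore_attr = TRUE)
  }
})

test_that("phylogenetic diversity dominates taxic and matches hand enumeration", {
  tr <- readNewick("((B,C),A);")
  occ <- occurrenceTable(c("A", "B", "C"), fad = c(75, 72, 68), lad = c(74, 70, 66))
  tt <- calibrateTree(tr, occ, 0)
  pd <- phyloDiversity(tt, binGrid(76, 65))
  # hand-enumerated per bin from the segment table:
  # segments: clade(B,C) occupies (72,75], ghost of C occupies (68,72]
  expect_equal(pd$taxic,        c(0, 1, 1, 0, 1, 1, 1, 0, 1, 1, 1))
  expect_equal(pd$phylogenetic, c(0, 2, 2, 1, 2, 2, 2, 1, 1, 1, 1))
  expect_true(all(pd$phylogenetic >= pd$taxic))
  # terminal bins (younger than every divergence and fad): equality
  expect_equal(pd$phylogenetic[pd$top <= 68], pd$taxic[pd$top <= 68])
})

test_that("PD >= TD with terminal equality on random calibrated trees", {
  set.seed(33)
  for (i in 1:15) {
    n <- sample(5:15, 1)
    tr <- ape::rtree(n)
    fad <- runif(n, 70, 90)
    occ <- occurrenceTable(tr$tip.label, fad, pmax(66, fad - runif(n, 0, 6)))
    tt <- calibrateTree(tr, occ, sample(c(0, 1), 1))
    g <- binGrid(95, 60)
    pd <- phyloDiversity(tt, g)
    expect_true(all(pd$phylogenetic >= pd$taxic))
    # bins younger than every first appearance can host no ghost segment
    youngest_fad <- min(occ$fad)
    idx <- pd$top <= youngest_fad
    expect_equal(pd$phylogenetic[idx], pd$taxic[idx])
  }
})

test_that("identical fads with min_branch 0 collapse the two curves", {
  tr <- ape::rtree(6)
  occ <- occurrenceTable(tr$tip.label, rep(80, 6), rep(70, 6))
  tt <- calibrateTree(tr, occ, 0)
  pd <- phyloDiversity(tt, binGrid(85, 65))
  expect_equal(pd$phylogenetic, pd$taxic)
})

test_that("presence pooled from a refined grid reproduces coarse membership", {
  # a taxon occupies a 1-Ma bin iff it occupies at least one of its 0.5-Ma
  # halves (per-taxon max-pooling of presence)
  set.seed(8)
  fad <- runif(50, 70, 80)
  occ <- occurrenceTable(paste0("t", 1:50), fad, pmax(68, fad - runif(50, 0, 4)))
  coarse <- binGrid(80, 68, 1)
  fine <- binGrid(80, 68, 0.5)
  memC <- pterodiv:::.rangeInBin(occ$fad, occ$lad, coarse$top, coarse$bottom)
  memF <- pterodiv:::.rangeInBin(occ$fad, occ$lad, fine$top, fine$bottom)
  pooled <- memF[, seq(1, ncol(memF), 2)] | memF[, seq(2, ncol(memF), 2)]
  expect_equal(unname(pooled), unname(memC))
})

test_that("grid and curve validation", {
  expect_error(binGrid(60, 70), "oldest")
  expect_error(taxicDiversity(occurrenceTable("A", 70, 66), binGrid(80, 75)),
               NA)  # clipping warns, does not error
  expect_warning(taxicDiversity(occurrenceTable("A", 90, 66), binGrid(80, 70)),
                 "clipped")
  tr <- ape::rtree(4)
  occ <- occurrenceTable(tr$tip.label, 80:77, 76:73)
  tt <- calibrateTree(tr, occ, 0)
  other <- occurrenceTable(c("x", "y", "z", "w"), 80:77, 76:73)
  expect_error(phyloDiversity(tt, binGrid(85, 70), occ = other), "taxon sets differ")
})
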