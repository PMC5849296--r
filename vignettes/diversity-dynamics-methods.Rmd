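---
title: "Methods: time-scaled diversity curves, Gower/PCoA disparity and parsimony auditing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-scaled diversity curves, Gower/PCoA disparity and parsimony auditing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pterodiv)
```

This vignette documents the models and procedures behind `pterodiv`, the
assumptions they rest on, the tunable parameters and their defaults, the
numerical choices made where the design was genuinely open, and what the
synthetic-data tests do and do not establish about real fossil data.

Ages are in Ma before present everywhere, and larger numbers are older; that
single convention (the geological one) governs every comparison in the code.

## Time calibration and ghost lineages

`calibrateTree()` implements minimal ("basic") time-scaling. Each leaf is
placed at its first appearance age (FAD); in post-order, each internal node
is placed at

    age(node) = max over children of (age(child) + min_branch).

The only parameter is `min_branch`, the minimum parent-to-child age gap in
Ma. `min_branch = 0` is the default for diversity work: it is the unique
calibration that minimises total implied ghost lineage for the given
topology (the test suite checks this against brute-force enumeration of
discretised age assignments). `min_branch = 1` is the conventional choice
for plotting, pushing every divergence 1 Ma before its oldest descendant so
internal branches are visible. Whether such an offset should apply once per
divergence or once per chain of simultaneous divergences is ambiguous in
general; we apply it per parent-child pair, the simple post-order rule above.

Assumptions worth stating: the cladogram is taken as given (no topological
uncertainty is propagated); a taxon is treated as present over the whole of
its possible occurrence, so calibration uses the *older* bound of an
uncertain FAD (and a curation override, `override_fad`, lets one substitute
a relative's first occurrence when a taxon's own range is effectively
unconstrained); polytomies calibrate as-is, all children sharing one parent
age. Stochastic time-scaling (cal3-type), tip-dating and node-age confidence
intervals are out of scope.

A *ghost segment* is the unobserved part of an edge: for a leaf edge the
interval from the divergence down to the leaf's FAD, for an internal edge
its whole length. `ghostLineages()` reports all non-zero segments.

## Diversity curves

Bins are half-open intervals `[t, t − width)`, older edge inclusive, so
every instant belongs to exactly one bin and a point occurrence (FAD = LAD)
falls in the bin whose older edge it equals. `taxicDiversity()` counts a
taxon in every bin its range intersects (range-through counting, no
abundance weighting). `phyloDiversity()` adds ghost segments, with segment
occupancy open at the divergence and closed at the FAD. That boundary choice
is what makes the counts add up: a lineage is never double-counted in the
bin where its ghost portion hands over to its observed range, an edge ending
exactly at a bin's older edge does not leak into that bin, and the
point-in-time lineage count equals the number of edges crossing that
instant. Two invariants follow and are tested: phylogenetic ≥ taxic in every
bin, and equality in all bins younger than every first appearance, where no
ghost can be inferred — the Signor-Lipps terminal artefact, which is why a
modest terminal decline in phylogenetic diversity is expected even under a
sudden extinction.

One consistency law deserves a note: refining the grid (e.g. 0.5-Ma bins)
and pooling does *not* reproduce coarse counts by taking the maximum of the
sub-bin counts — two taxa occupying disjoint half-bins give a coarse count
of 2 but a max-pooled count of 1. The quantity that pools correctly is
per-taxon *presence* (a taxon occupies a coarse bin iff it occupies at least
one of its sub-bins), and that is the form the test suite asserts.

## Gower dissimilarity and ordination

`gowerDist()` computes, for taxa *i, j* over characters *k*,

    d(i,j) = sum_k w_ijk * delta_ijk / sum_k w_ijk

with `w_ijk = 1` only when both taxa are observed for character *k*.
Continuous and ordered characters contribute range-scaled absolute
differences (ordered states are coded as equally spaced ranks — the
parameter-free choice absent any measured spacing); categorical characters
contribute 0/1. Three choices matter and are deliberate:

* **Ranges are pooled over the whole matrix**, not per time bin, because the
  two bins are compared inside a single ordination and must share one
  geometry.
* **Wingspan and ratio characters enter untransformed** (no log). A
  `log`-type transform would change the weighting of large-bodied taxa; with
  nothing to calibrate such a choice against, the identity scale is the
  default and users can transform upstream.
* **Zero-range continuous characters are dropped with a warning** (they
  carry no signal but would otherwise divide by zero); a taxon pair sharing
  no observed character is a hard error, since its dissimilarity is
  undefined rather than zero.

`pcoa()` is classical metric scaling: `B = -0.5 * J D^2 J`, symmetric
eigendecomposition, scores = eigenvectors scaled by the square roots of
eigenvalues. Gower matrices need not be Euclidean-embeddable, so negative
eigenvalues can appear; they are *dropped* by default — matching the common
default of desktop palaeontology software — and percent variance is taken
over the positive spectrum. A Lingoes additive-constant correction is
available behind `correction = "lingoes"` for users who want a fully
Euclidean embedding. Axes are retained down to a relative eigenvalue
tolerance of `1e-10` times the leading eigenvalue, which discards only
numerical noise.

## Disparity metrics and the axis-subset audit

`sumOfRanges()` and `productOfRanges()` measure, for a taxon subset, the
total spread and the occupied-volume proxy across ordination axes. Both are
zero for singletons and monotone non-decreasing under adding members, which
is also why time-averaging inflates them: pooling two sub-bins can only
grow a range. Both default to *all retained axes*: published range metrics
do not always state how many axes were used, and all-positive-axes is the
parameter-free choice. Because that reporting gap is common,
`disparityAxisScan()` recomputes both metrics for every leading axis subset
so a published value can be matched to the subset that produced it; the test
suite verifies the scan uniquely pinpoints a known subset on synthetic data.

`isometricMassRatio(a, b) = (a/b)^3` is the cube-law mass ratio under
isometry — the standard back-of-envelope for arguing that two bone-length
populations cannot be one species.

## Rarefaction

`rarefy()` draws taxon subsets uniformly without replacement (default
`n_reps = 5000`) at each subsample size and evaluates the metric on the
*full-data* ordination scores of the subset. The ordination is deliberately
not recomputed per replicate: all replicates must live in one geometry for
bins to be comparable (a per-replicate re-ordination mode exists behind a
flag for sensitivity analysis, and resampled units are taxa — the trait
matrix has one row per taxon). The 95% band is the 2.5th/97.5th percentile
of the replicate distribution, the simplest interval consistent with a
percentile bootstrap; at the full group size the band collapses onto the
full-group value. Every call takes an explicit seed and identical seeds
reproduce the curve bit-for-bit.

## Parsimony scoring and search

`treeLength()` scores unordered characters with an exact Sankoff pass under
0/1 costs and ordered/continuous characters with the bottom-up interval
(Farris/Wagner) method under linear cost `|a − b|`; both passes are exact on
multifurcating trees (the interval rule generalises to polytomies by taking
the middle two order statistics of the children's interval endpoints, and
the tests check it against brute-force enumeration over internal-node
assignments). Missing (`?`) and inapplicable (`-`) cells constrain nothing —
inapplicable codings are reductive, preserved for reporting but scored as
missing — and polymorphic cells contribute their state set. Continuous
characters must first pass `rescaleContinuous()`, which maps each onto
`[0, 1]` so that one full sweep costs one step, commensurate with a binary
character; non-contiguous polymorphic sets under linear cost are treated as
their spanning interval.

For the indices, each character needs its minimum conceivable steps `m` and
its maximum relevant steps `g`: `m` is a minimum-state-cover computation for
unordered characters and the interval-gap bound for linear ones; `g` is the
steps on a star phylogeny (best single median state, or the weighted-median
point for linear costs). Then CI = Σm/Σs and RI = (Σg − Σs)/(Σg − Σm),
computed over all variable characters (invariant ones contribute zero to
every term); characters with `g = m` cannot express homoplasy and are
excluded from the RI ratio, and an `informative_only` flag extends that
exclusion to CI. For continuous characters no printed convention exists for
`m` and `g`; the rescaled range and star-tree cost used here are documented
as this package's convention.

`heuristicSearch()` is deliberately modest: random addition sequences
(taxa inserted in random order at the cheapest position, ties broken at
random), SPR branch swapping to a local optimum, and an optional parsimony
ratchet (a random quarter of characters doubled in weight, re-optimise,
restore, re-optimise, keep if no worse). All equally best distinct unrooted
topologies are retained, and internal branches whose collapse leaves the
length unchanged are collapsed in the reported trees. Implied weighting,
TBR, and branch-support measures are non-goals; the search's job here is
auditing published tree statistics at modest problem sizes, and on six-taxon
problems the tests require it to find the global optimum known from
exhaustive enumeration of all 105 topologies.

## Synthetic data: what it emulates, and what it does not

The generator's defaults are the study conditions: 20 taxa spanning
86.3–66.0 Ma, binned into Santonian-Campanian (86.3–72.1 Ma, 14.2 Ma long)
and Maastrichtian (72.1–66.0 Ma, 6.1 Ma long) by range midpoint; first
appearances uniform over the span with exponential range durations (rate
0.25 / Ma, i.e. mean species duration 4 Ma — a realistic figure for fossil
vertebrate species); a topology in which older taxa attach deeper; Brownian
trait evolution on the 1-Ma-calibrated tree (`brownian_sigma2 = 0.1` per Ma
on the reference scale) and a 3-state equal-rates Markov chain for habitat
(0.05 transitions / Ma); 20% Bernoulli missingness. The seven functional
characters carry the study schema verbatim (habitat; wingspan in metres;
three ordered grades; two limb ratios), so the CSV/YAML/newick/TNT readers
are exercised on exactly the layout they claim to support.

Two generator choices deserve justification. Ordered grades are cut at
*fixed* thresholds on the trait scale, not at sample quantiles: a strongly
curved jaw is an absolute property of a fossil, and quantile-based grading
would relabel identical morphologies depending on their samplemates (it
also, by construction, erases any between-group variance signal). And
wingspan is never masked: size is estimable from almost any identifiable
specimen, and a complete character guarantees Gower's precondition that
every taxon pair shares at least one observation.

What passing tests show: the pipeline's algebra is right (oracles and
invariants), seeds reproduce everything, and a 4-fold Brownian-rate contrast
between two 20-taxon clades is recovered as higher sum-of-ranges in ≥95% of
replicates. What they do not show: robustness to non-random (taphonomic)
missingness, correlated character evolution, directional trends, or
heterogeneous sampling through time — none of which the generator models,
and all of which affect real fossil data.

## Problem sizes and determinism

The test suite and the acceptance script run at small problem sizes chosen
for tight oracles rather than realism: exhaustive parsimony checks use 5–7
taxa (where enumeration over assignments or all 105 six-taxon topologies is
feasible), searches use ≤8 taxa, rarefaction oracles enumerate C(5,3)
subsets, and the end-to-end synthetic pipeline uses the default 20 taxa.
All randomness flows through explicit seeds (`withSeed()` restores global
RNG state, so library calls never leak state between stages); identical
seeds give byte-identical CSV/JSON outputs, which the command-line layer
records in a per-run manifest.

## Known limitations

* Calibration offers only minimal scaling; branch durations of zero are
  real outputs at `min_branch = 0` and downstream users who need positive
  lengths (e.g. for Brownian simulation) should calibrate with
  `min_branch = 1`.
* Gower + PCoA with dropped negative eigenvalues slightly distorts distances
  when the matrix is strongly non-Euclidean; the Lingoes flag exists, but
  default results match the dropped-axes convention.
* The heuristic search does not scale to hundreds of taxa in pure R and is
  not meant to replace dedicated search programs; it audits scores and
  reproduces optima at small sizes.
* Rarefaction treats taxa as exchangeable sampling units; specimen-level
  abundance rarefaction is not modelled.
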