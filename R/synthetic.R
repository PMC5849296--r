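#' Late Cretaceous stage boundaries (GTS 2012)
#'
#' Ages in Ma for the stages used when binning the latest Cretaceous record.
#' The Santonian-Campanian bin pools two stages; durations follow directly
#' from the boundaries.
#'
#' @return data.frame with columns \code{stage}, \code{top} (older boundary,
#'   Ma) and \code{bottom} (younger boundary, Ma).
#' @examples
#' gtsStages()
#' binDuration("Santonian-Campanian") # 14.2
#' @export
gtsStages <- function() {
  data.frame(stage = c("Coniacian", "Santonian", "Campanian", "Maastrichtian"),
             top = c(89.8, 86.3, 83.6, 72.1),
             bottom = c(86.3, 83.6, 72.1, 66.0))
}

#' @rdname gtsStages
#' @param bin \code{"Santonian-Campanian"} or \code{"Maastrichtian"}.
#' @return \code{binDuration}: the bin's duration in Ma.
#' @export
binDuration <- function(bin = c("Santonian-Campanian", "Maastrichtian")) {
  bin <- match.arg(bin)
  st <- gtsStages()
  if (bin == "Santonian-Campanian") {
    st$top[st$stage == "Santonian"] - st$bottom[st$stage == "Campanian"]
  } else {
    st$top[st$stage == "Maastrichtian"] - st$bottom[st$stage == "Maastrichtian"]
  }
}

#' Configure the synthetic-data generator
#'
#' Defaults emulate the latest Cretaceous study system: a marine/terrestrial
#' pterosaur assemblage spanning the Santonian through the end-Maastrichtian
#' (86.3-66.0 Ma) with two time bins, species stratigraphic ranges of a few
#' Ma, and the seven functional characters of the study schema (habitat;
#' wingspan; jaw curvature, cervical and hindlimb elongation as ordered
#' grades; ulna:humerus and metacarpal IV:humerus ratios).
#'
#' @param n_taxa number of taxa.
#' @param oldest,youngest time span in Ma.
#' @param bins named list of bin boundaries \code{c(top, bottom)}; taxa are
#'   labelled by the bin containing their range midpoint.
#' @param extinction_rate per-Ma extinction intensity; range durations are
#'   exponential with mean \code{1/extinction_rate}.
#' @param brownian_sigma2 Brownian-motion rate (variance per Ma) for
#'   continuous traits.
#' @param discrete_rate per-Ma transition intensity of the continuous-time
#'   Markov chain generating categorical traits.
#' @param missing_fraction Bernoulli masking fraction applied to the
#'   functional matrix, in \code{[0, 1)}.
#' @param n_discrete_chars,n_continuous_chars size of the emitted
#'   phylogenetic character matrix.
#' @param seed RNG seed (mandatory; every generator call is reproducible).
#' @return list of class \code{"simulationConfig"}.
#' @export
simulationConfig <- function(n_taxa = 20,
                             oldest = 86.3, youngest = 66.0,
                             bins = list("Santonian-Campanian" = c(86.3, 72.1),
                                         "Maastrichtian" = c(72.1, 66.0)),
                             extinction_rate = 0.25,
                             brownian_sigma2 = 0.1,
                             discrete_rate = 0.05,
                             missing_fraction = 0.2,
                             n_discrete_chars = 30,
                             n_continuous_chars = 4,
                             seed = 1) {
  stopifnot(n_taxa >= 4, oldest > youngest,
            extinction_rate >= 0, brownian_sigma2 >= 0, discrete_rate >= 0,
            missing_fraction >= 0, missing_fraction < 1,
            length(seed) == 1, is.finite(seed))
  structure(as.list(environment()), class = "simulationConfig")
}

#' Simulate stratigraphic ranges
#'
#' First appearances are uniform over the configured span; range durations
#' are exponential with rate \code{extinction_rate}, truncated at the younger
#' end of the span. Each taxon gets the bin label containing its range
#' midpoint.
#'
#' @param cfg a [simulationConfig()].
#' @return an [occurrenceTable()] with a \code{bin} column.
#' @export
simulateOccurrences <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  withSeed(cfg$seed, {
    span <- cfg$oldest - cfg$youngest
    if (span <= 0) stop("degenerate time span")
    fad <- cfg$oldest - runif(cfg$n_taxa) * span
    dur <- if (cfg$extinction_rate > 0) rexp(cfg$n_taxa, cfg$extinction_rate)
           else rep(0, cfg$n_taxa)
    lad <- pmax(cfg$youngest, fad - dur)
    mid <- (fad + lad) / 2
    bin <- rep(NA_character_, cfg$n_taxa)
    for (b in names(cfg$bins))
      bin[mid <= cfg$bins[[b]][1] & mid > cfg$bins[[b]][2]] <- b
    occurrenceTable(sprintf("taxon_%02d", seq_len(cfg$n_taxa)), fad, lad,
                    bin = bin)
  })
}

# random resolved topology consistent with first appearances: taxa join the
# growing tree in order of decreasing age, attaching on a random existing edge
.agesConsistentTopology <- function(taxa, fad) {
  ord <- order(-fad)
  nl <- list(ord[1], ord[2])
  for (t in ord[-(1:2)]) {
    sites <- c(.subtreePaths(nl), list(NULL))
    s <- sites[[sample.int(length(sites), 1L)]]
    nl <- if (is.null(s)) list(nl, t) else .attachAt(nl, s, t)
  }
  .nl2phylo(nl, taxa)
}

#' Simulate a cladogram, functional traits and a phylogenetic character
#' matrix on it
#'
#' Builds a resolved topology in which older taxa attach deeper (sequential
#' attachment in order of decreasing first appearance), time-calibrates it
#' against the simulated ranges (1 Ma minimum branches, so no branch has zero
#' length), and evolves traits along it: continuous traits by Brownian motion
#' (variance proportional to path length in Ma), categorical traits by a
#' continuous-time Markov chain, ordered traits by thresholding a Brownian
#' trait into three grades. A Bernoulli missingness mask is applied to the
#' functional matrix (repaired minimally so no taxon or character is entirely
#' missing). Discrete phylogenetic characters for parsimony are evolved the
#' same way and emitted together with Brownian continuous characters.
#'
#' @param cfg a [simulationConfig()].
#' @param occ the matching [simulateOccurrences()] output.
#' @return list with elements \code{tree} (\code{"phylo"}, branch lengths in
#'   Ma), \code{traits} (a [functionalMatrix()] with the seven-character
#'   study schema), \code{charmatrix} (a [characterMatrix()]), and
#'   \code{schema} (list, the YAML-ready trait schema).
#' @export
simulateTreeAndTraits <- function(cfg, occ) {
  stopifnot(inherits(cfg, "simulationConfig"), inherits(occ, "occurrenceTable"))
  withSeed(cfg$seed + 1, {
    phy <- .agesConsistentTopology(occ$taxon, occ$fad)
    tt <- calibrateTree(phy, occ, min_branch = 1)
    n <- length(tt$tip.label)

    bm <- function(sigma2, root = 0)
      ape::rTraitCont(tt, model = "BM", sigma = sqrt(sigma2), root.value = root)
    mk <- function(k, rate) {
      states <- letters[seq_len(k)]
      as.character(ape::rTraitDisc(tt, model = "ER", k = k, rate = rate,
                                   states = states))
    }
    # ordered grades are absolute morphology classes, so the thresholds are
    # fixed on the trait scale rather than sample quantiles
    grade3 <- function(x, labels) {
      cut(x, breaks = c(-Inf, -0.8, 0.8, Inf), labels = labels)
    }

    habitat <- c(a = "continental", b = "brackish", c = "marine")[
      mk(3, cfg$discrete_rate)]
    wingspan <- pmax(0.5, 4 + bm(cfg$brownian_sigma2 * 4))   # metres
    jaw <- grade3(bm(cfg$brownian_sigma2),
                  c("straight", "curved", "strongly_curved"))
    cerv <- grade3(bm(cfg$brownian_sigma2), c("short", "moderate", "elongate"))
    hind <- grade3(bm(cfg$brownian_sigma2), c("short", "moderate", "elongate"))
    ulna_hum <- pmax(0.1, 1 + bm(cfg$brownian_sigma2 / 4))
    mcIV_hum <- pmax(0.1, 0.9 + bm(cfg$brownian_sigma2 / 4))

    df <- data.frame(habitat = unname(habitat), wingspan = unname(wingspan),
                     jaw_curvature = as.character(jaw),
                     cervical_elongation = as.character(cerv),
                     hindlimb_elongation = as.character(hind),
                     ulna_humerus = unname(ulna_hum),
                     metacarpalIV_humerus = unname(mcIV_hum),
                     row.names = tt$tip.label)
    # Bernoulli mask; wingspan stays complete (size is estimable for any
    # reasonably preserved specimen), which also guarantees every taxon pair
    # shares at least one observed character as Gower requires
    mask <- matrix(runif(n * ncol(df)) < cfg$missing_fraction, n, ncol(df))
    mask[, match("wingspan", colnames(df))] <- FALSE
    for (j in seq_len(ncol(df))) if (all(mask[, j])) mask[sample.int(n, 1), j] <- FALSE
    df[mask] <- NA

    kinds <- c(habitat = "categorical", wingspan = "continuous",
               jaw_curvature = "ordered", cervical_elongation = "ordered",
               hindlimb_elongation = "ordered",
               ulna_humerus = "continuous", metacarpalIV_humerus = "continuous")
    lv <- list(jaw_curvature = c("straight", "curved", "strongly_curved"),
               cervical_elongation = c("short", "moderate", "elongate"),
               hindlimb_elongation = c("short", "moderate", "elongate"))
    bin <- setNames(occ$bin[match(tt$tip.label, occ$taxon)], tt$tip.label)
    traits <- functionalMatrix(df, kinds, levels = lv, bin = bin)

    # phylogenetic character matrix: Markov discrete + Brownian continuous
    cells <- list(); kind <- character(0)
    for (j in seq_len(cfg$n_discrete_chars)) {
      k <- sample(2:3, 1)
      st <- match(mk(k, 0.1), letters) - 1L
      cells[[length(cells) + 1L]] <- as.list(as.integer(st))
      kind <- c(kind, "unordered")
    }
    for (j in seq_len(cfg$n_continuous_chars)) {
      cells[[length(cells) + 1L]] <- unname(bm(0.05))
      kind <- c(kind, "continuous")
    }
    cm <- characterMatrix(cells, tt$tip.label, kind)

    schema <- list(
      characters = list(
        habitat = list(kind = "categorical",
                       states = c("continental", "brackish", "marine")),
        wingspan = list(kind = "continuous", unit = "m"),
        jaw_curvature = list(kind = "ordered", states = lv$jaw_curvature),
        cervical_elongation = list(kind = "ordered",
                                   states = lv$cervical_elongation),
        hindlimb_elongation = list(kind = "ordered",
                                   states = lv$hindlimb_elongation),
        ulna_humerus = list(kind = "continuous"),
        metacarpalIV_humerus = list(kind = "continuous")),
      bin_column = "bin")

    list(tree = phy, timetree = tt, traits = traits, charmatrix = cm,
         schema = schema)
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Emits \code{occ.csv}, \code{traits.csv}, \code{schema.yaml},
#' \code{tree.nwk} and \code{matrix.tnt} in the formats the package readers
#' accept, exercising the whole IO surface.
#'
#' @param cfg a [simulationConfig()].
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
writeSyntheticDataset <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  occ <- simulateOccurrences(cfg)
  sim <- simulateTreeAndTraits(cfg, occ)
  writeOccurrences(occ, file.path(dir, "occ.csv"))
  td <- cbind(taxon = rownames(sim$traits$data), sim$traits$data,
              bin = unname(sim$traits$bin))
  write.csv(td, file.path(dir, "traits.csv"), row.names = FALSE, quote = FALSE)
  yaml::write_yaml(sim$schema, file.path(dir, "schema.yaml"))
  writeNewick(sim$tree, file.path(dir, "tree.nwk"))
  writeCharacterMatrix(sim$charmatrix, file.path(dir, "matrix.tnt"))
  invisible(dir)
}
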