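# Independent reference implementations used as oracles. These are written
# naively (cell-by-cell loops, exhaustive enumeration) and deliberately share
# no code with the package internals they check.

# -- Gower: direct double loop over taxon pairs and characters ---------------
naiveGower <- function(fm) {
  df <- fm$data
  n <- nrow(df)
  vals <- df
  for (j in colnames(df)) {
    if (fm$kinds[[j]] == "ordered")
      vals[[j]] <- as.numeric(match(df[[j]], fm$levels[[j]]) - 1L)
  }
  rng <- sapply(colnames(df), function(j) {
    if (fm$kinds[[j]] == "categorical") NA_real_
    else diff(range(vals[[j]], na.rm = TRUE))
  })
  D <- matrix(0, n, n, dimnames = list(rownames(df), rownames(df)))
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i == k) next
    num <- 0; den <- 0
    for (j in colnames(df)) {
      xi <- vals[i, j]; xk <- vals[k, j]
      if (is.na(xi) || is.na(xk)) next
      if (fm$kinds[[j]] == "categorical") {
        num <- num + (xi != xk)
      } else {
        if (rng[[j]] == 0) next
        num <- num + abs(as.numeric(xi) - as.numeric(xk)) / rng[[j]]
      }
      den <- den + 1
    }
    D[i, k] <- num / den
  }
  D
}

# -- random mixed functional matrix ------------------------------------------
randomFunctionalMatrix <- function(n = 6, missing_frac = 0.2) {
  taxa <- paste0("t", seq_len(n))
  df <- data.frame(
    cat1 = sample(c("x", "y", "z"), n, replace = TRUE),
    ord1 = sample(c("lo", "mid", "hi"), n, replace = TRUE),
    con1 = runif(n, 0, 10),
    con2 = rnorm(n),
    cat2 = sample(c("p", "q"), n, replace = TRUE),
    row.names = taxa)
  mask <- matrix(runif(n * 5) < missing_frac, n, 5)
  mask[, 1] <- FALSE   # keep one character complete so every pair overlaps
  for (j in 2:5) if (sum(!mask[, j]) < 2) mask[sample(n, 2), j] <- FALSE
  df[mask] <- NA
  functionalMatrix(df,
                   kinds = c(cat1 = "categorical", ord1 = "ordered",
                             con1 = "continuous", con2 = "continuous",
                             cat2 = "categorical"),
                   levels = list(ord1 = c("lo", "mid", "hi")))
}

# -- parsimony: exhaustive minimisation over internal-node assignments -------
# Scores one character by trying every assignment of candidate states to the
# internal nodes; exact for any (also multifurcating) tree.
bruteCharSteps <- function(phy, leaf_allowed, candidates, cost_fn) {
  n <- length(phy$tip.label)
  internal <- (n + 1):(n + phy$Nnode)
  grids <- rep(list(candidates), length(internal))
  best <- Inf
  assign_grid <- expand.grid(grids)
  for (r in seq_len(nrow(assign_grid))) {
    st <- as.numeric(assign_grid[r, ])
    names(st) <- internal
    total <- 0
    for (e in seq_len(nrow(phy$edge))) {
      a <- phy$edge[e, 1]; b <- phy$edge[e, 2]
      sa <- st[as.character(a)]
      if (b <= n) {
        allowed <- leaf_allowed[[b]]
        total <- total + if (length(allowed) == 0L) 0
                         else min(vapply(allowed, cost_fn, 0, y = sa))
      } else {
        total <- total + cost_fn(st[as.character(b)], sa)
      }
    }
    best <- min(best, total)
  }
  best
}

bruteTreeLength <- function(phy, cm) {
  total <- 0
  perm <- match(phy$tip.label, cm$taxa)   # leaf i of the tree <-> its taxon
  for (j in seq_along(cm$cells)) {
    if (cm$kind[j] == "unordered") {
      allowed <- cm$cells[[j]][perm]
      states <- sort(unique(unlist(allowed)))
      s <- bruteCharSteps(phy, allowed, states,
                          function(x, y) as.numeric(x != y))
    } else if (cm$kind[j] == "ordered") {
      allowed <- cm$cells[[j]][perm]
      states <- seq(min(unlist(allowed)), max(unlist(allowed)))
      s <- bruteCharSteps(phy, allowed, states,
                          function(x, y) abs(x - y))
    } else {
      v <- cm$cells[[j]][perm]
      allowed <- lapply(v, function(x) if (is.na(x)) numeric(0) else x)
      states <- sort(unique(v[!is.na(v)]))
      s <- bruteCharSteps(phy, allowed, states,
                          function(x, y) abs(x - y))
    }
    total <- total + cm$weight[j] * s
  }
  total
}

# -- random discrete character matrix ----------------------------------------
randomDiscreteMatrix <- function(n_taxa, n_chars, n_states = 3,
                                 p_missing = 0.1, p_poly = 0.1) {
  cells <- lapply(seq_len(n_chars), function(j) {
    lapply(seq_len(n_taxa), function(t) {
      u <- runif(1)
      if (u < p_missing) integer(0)
      else if (u < p_missing + p_poly) sort(sample(0:(n_states - 1), 2))
      else sample(0:(n_states - 1), 1)
    })
  })
  characterMatrix(cells, paste0("t", seq_len(n_taxa)),
                  rep("unordered", n_chars))
}

# -- all unrooted binary topologies, as rooted nested lists -------------------
# built by inserting taxon k on every edge of every (k-1)-taxon tree; returns
# one rooted representative per distinct unrooted topology
allTopologies <- function(n) {
  trees <- list(list(1L, 2L, 3L))
  for (k in 4:n) {
    nxt <- list()
    for (tr in trees) {
      # each subtree corresponds to one edge of the unrooted tree (the root
      # trifurcation is the unrooted central node, not an edge)
      for (s in pterodiv:::.subtreePaths(tr)) {
        nxt[[length(nxt) + 1L]] <- pterodiv:::.attachAt(tr, s, k)
      }
    }
    trees <- nxt
  }
  keys <- vapply(trees, pterodiv:::.topologyKey, "", n = n)
  trees[!duplicated(keys)]
}

nl2phylo <- function(nl, taxa) pterodiv:::.nl2phylo(nl, taxa)
topoKey <- function(phy) pterodiv:::.topologyKey(pterodiv:::.phylo2nl(phy),
                                                 length(phy$tip.label))
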