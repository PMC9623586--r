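# Shared helpers: independent oracles and cached fixtures.

# Brute-force average-linkage agglomeration with a strict cut: merge the
# closest pair of clusters (mean of all member-pair distances) while that
# distance is below the cutoff, recomputing every inter-cluster average
# from scratch after each merge.  Independent of the hclust-based
# implementation.
oracle_average_linkage <- function(dmat, cutoff) {
  m <- nrow(dmat)
  clusters <- as.list(seq_len(m))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d <- mean(dmat[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    if (best_d >= cutoff) break
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  labels <- integer(m)
  for (g in seq_along(clusters)) labels[clusters[[g]]] <- g
  labels
}

# Canonical form of a partition: map labels to order of first appearance.
canonical_partition <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

random_torsions <- function(m, n) {
  matrix(stats::runif(m * n, -180, 180), m, n)
}

# Cached toy chains (built once per test session).
.fixture_env <- new.env()

cached_chain <- function(n_residues, wells, seed) {
  key <- sprintf("chain_%d_%d_%d", n_residues, wells, seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_rotamer_chain(n_residues, wells, seed = seed)
  .fixture_env[[key]]
}

cached_toy_library <- function(chain, key) {
  k <- paste0("lib_", key)
  if (is.null(.fixture_env[[k]])) .fixture_env[[k]] <- toy_library(chain)
  .fixture_env[[k]]
}

# Two-rotamer ensemble with exactly known cluster probabilities: two
# centers far apart, the planted probability realized through free
# energies, several degenerate members per center so population sums are
# exact.
two_cluster_ensemble <- function(p2, n_per = 3L, temperature = 298) {
  kT <- 0.0019872041 * temperature
  f2 <- -kT * log(p2 / (1 - p2))
  torsions <- rbind(matrix(rep(c(-60), n_per), ncol = 1),
                    matrix(rep(c(120), n_per), ncol = 1))
  fe <- c(rep(0 + kT * log(n_per), n_per), rep(f2 + kT * log(n_per), n_per))
  conformation_ensemble(torsions, fe)
}
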