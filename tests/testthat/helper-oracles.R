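# Independent brute-force oracles used to cross-check the implementation.

# Tanimoto by explicit set arithmetic on bit indices.
oracle_tanimoto <- function(a, b) {
  A <- which(a == 1)
  B <- which(b == 1)
  u <- length(union(A, B))
  if (u == 0) return(0)
  length(intersect(A, B)) / u
}

# Pearson chi-square (no continuity correction) via stats::chisq.test.
oracle_chisq <- function(a, b, c, d) {
  suppressWarnings(stats::chisq.test(rbind(c(a, b), c(c, d)),
                                     correct = FALSE)$statistic[[1]])
}

# Phi from the binary-variable Pearson correlation definition.
oracle_phi <- function(a, b, c, d) {
  x <- c(rep(1, a), rep(1, b), rep(0, c), rep(0, d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  suppressWarnings(stats::cor(x, y))
}

# RMSE after optimal rigid alignment (translation + rotation/reflection):
# minimize ||Yc Q - Xc|| over orthogonal Q via SVD of t(Yc) Xc.
procrustes_rmse <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Yc) %*% Xc)
  Q <- s$u %*% t(s$v)
  sqrt(mean((Yc %*% Q - Xc)^2))
}

# All-pairs shortest paths by Floyd-Warshall over an undirected edge list.
oracle_floyd_warshall <- function(edges, nodes) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[i]; b <- edges$protein_b[i]
    if (a %in% nodes && b %in% nodes) D[a, b] <- D[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Connected components by flood fill over an adjacency list.
oracle_components <- function(nodes, edges) {
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character())
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character()
  comps <- list()
  for (v in nodes) {
    if (v %in% seen) next
    queue <- v
    comp <- character()
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    seen <- c(seen, comp)
  }
  comps
}

# Articulation nodes by deletion: the component containing v splits into
# >= 2 parts exactly when deleting v raises the total component count.
oracle_articulation <- function(nodes, edges) {
  base <- length(oracle_components(nodes, edges))
  out <- character()
  for (v in nodes) {
    rest <- setdiff(nodes, v)
    e <- edges[edges[, 1] != v & edges[, 2] != v, , drop = FALSE]
    if (length(oracle_components(rest, e)) > base) out <- c(out, v)
  }
  sort(out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random bit fingerprint as 0/1 vector
rand_bits <- function(n, p = 0.2) as.integer(stats::runif(n) < p)

# Small dataset shared across test files (cached: generation is the slow part).
small_config <- function(seed = 42) {
  generator_config(
    n_plants = 20, edible_fraction = 0.4, n_compounds = 250,
    n_neighbor_proteins = 25, n_planted_clusters = 2, cluster_size = 3,
    plants_per_group = 6, markers_per_group = 2, n_background_pairs = 60,
    n_decoy_pairs = 80, n_analog_pairs = 6, n_reactions = 40,
    n_metabolites = 35, fingerprint_bits = 256, rng_seed = seed
  )
}

.dataset_cache <- new.env(parent = emptyenv())
small_dataset <- function(seed = 42) {
  key <- as.character(seed)
  if (is.null(.dataset_cache[[key]])) {
    .dataset_cache[[key]] <- generate_dataset(small_config(seed))
  }
  .dataset_cache[[key]]
}
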