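# Phi-coefficient co-targeting network over targeted proteins: chi-square
# significance (chi2 = n * phi^2, 1 df), Bonferroni correction, component
# and bridge structure, intra-set shortest-path statistics.

#' Phi coefficient of a 2x2 contingency table
#'
#' phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)), the Pearson correlation of
#' two binary variables; phi^2 relates to the chi-square statistic by
#' chi2 = n * phi^2.
#'
#' @param a,b,c,d cell counts; `a` may instead be a 2x2 matrix
#'   `rbind(c(a, b), c(c, d))`.
#' @return phi in \[-1, 1\], or `NA` when a marginal is zero (undefined).
#' @export
phi_coefficient <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  n <- a + b + c + d
  if (n == 0) stop("phi_coefficient: all-zero table")
  m1 <- a + b; m2 <- c + d; m3 <- a + c; m4 <- b + d
  if (any(c(m1, m2, m3, m4) == 0)) return(NA_real_)
  (a * d - b * c) / sqrt(m1 * m2 * m3 * m4)
}

#' Phi coefficient with chi-square test
#'
#' Tests association in a 2x2 table without continuity correction, so the
#' identity chi2 = n * phi^2 holds exactly; p is the upper tail of the
#' chi-square distribution with 1 degree of freedom.
#'
#' @inheritParams phi_coefficient
#' @return list `phi`, `chi2`, `p_value`, `n`, `evaluable` (FALSE when a
#'   marginal is zero, in which case the test is skipped).
#' @export
phi_test <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  n <- a + b + c + d
  phi <- phi_coefficient(a, b, c, d)
  if (is.na(phi)) {
    return(list(phi = NA_real_, chi2 = NA_real_, p_value = NA_real_, n = n,
                evaluable = FALSE))
  }
  chi2 <- n * phi^2
  list(phi = phi, chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       n = n, evaluable = TRUE)
}

#' Build the significant phi co-targeting network
#'
#' Tests every unordered pair of proteins targeted by at least one plant.
#' For each pair the 2x2 table counts plants targeting both / one / neither
#' (n = number of plants in the matrix). Pairs with a zero marginal (a
#' protein targeted by all or by no plants) are not evaluable and are
#' neither tested nor counted in the Bonferroni multiplier. Edges with
#' Bonferroni-adjusted p <= `alpha` are retained, including significant
#' negative-phi edges (proteins consistently avoided together), flagged by
#' sign.
#'
#' @param m a [plant_protein_matrix()].
#' @param alpha significance level on adjusted p, default 0.05 (inclusive).
#' @return object of class `phi_network`: list with `nodes` (protein,
#'   `n_plants` size), `edges` (`protein_a`, `protein_b`, `phi`, `chi2`,
#'   `p_value`, `p_adjusted`), `n` (plants), `m_tests` (evaluable pairs),
#'   `alpha`.
#' @export
build_phi_network <- function(m, alpha = 0.05) {
  stopifnot(inherits(m, "plant_protein_matrix"))
  inc <- m$incidence
  n <- nrow(inc)
  targeted <- colnames(inc)[colSums(inc) > 0]
  if (length(targeted) < 2) stop("build_phi_network: need >= 2 targeted proteins")
  inc <- inc[, targeted, drop = FALSE]

  counts <- colSums(inc)              # plants targeting each protein
  both <- t(inc) %*% inc              # a: plants targeting both
  idx <- which(upper.tri(both), arr.ind = TRUE)
  a <- both[idx]
  ni <- counts[idx[, 1]]
  nj <- counts[idx[, 2]]
  b <- ni - a
  c_ <- nj - a
  d <- n - a - b - c_
  evaluable <- ni > 0 & ni < n & nj > 0 & nj < n
  denom <- sqrt(ni * (n - ni) * nj * (n - nj))
  phi <- ifelse(evaluable, (a * d - b * c_) / denom, NA_real_)
  chi2 <- n * phi^2
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  m_tests <- sum(evaluable)
  p_adj <- pmin(1, m_tests * p)

  keep <- evaluable & p_adj <= alpha
  edges <- data.frame(
    protein_a = targeted[idx[keep, 1]],
    protein_b = targeted[idx[keep, 2]],
    phi = phi[keep],
    chi2 = chi2[keep],
    p_value = p[keep],
    p_adjusted = p_adj[keep],
    stringsAsFactors = FALSE
  )
  edges$sign <- ifelse(edges$phi >= 0, "co-targeted", "avoided")
  nodes <- data.frame(protein_id = targeted, n_plants = as.integer(counts),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, n = n, m_tests = m_tests,
                 alpha = alpha),
            class = "phi_network")
}

#' @export
print.phi_network <- function(x, ...) {
  cat(sprintf("phi_network: %d tested proteins, %d evaluable pairs, %d significant edges (alpha = %g, Bonferroni)\n",
              nrow(x$nodes), x$m_tests, nrow(x$edges), x$alpha))
  invisible(x)
}

# igraph over the retained edges only (isolated tested proteins excluded)
phi_network_graph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("protein_a", "protein_b")],
                                directed = FALSE)
}

#' Connected components and bridging proteins of a phi network
#'
#' Components are computed over the significant-edge graph; bridges are
#' articulation nodes whose removal increases the component count.
#'
#' @param net a [build_phi_network()] result.
#' @return list `components` (list of protein-id character vectors, largest
#'   first) and `bridges` (articulation protein ids).
#' @export
components_and_bridges <- function(net) {
  stopifnot(inherits(net, "phi_network"))
  if (nrow(net$edges) == 0) return(list(components = list(), bridges = character()))
  g <- phi_network_graph(net)
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  comps <- lapply(unname(comps), sort)
  comps <- comps[order(-vapply(comps, length, integer(1)))]
  bridges <- sort(names(igraph::articulation_points(g)))
  list(components = comps, bridges = bridges)
}

#' Shortest-path statistics within a protein set over a PPI graph
#'
#' Unweighted shortest paths between all unordered pairs of the set over
#' the (undirected) PPI graph; the mean and maximum are taken over
#' reachable pairs, and unreachable pairs (including proteins absent from
#' the graph) are counted separately.
#'
#' @param proteins character vector (length >= 2).
#' @param ppi edge table with `protein_a`, `protein_b` (scores ignored).
#' @return list `mean_distance`, `max_distance`, `unreachable_pairs`,
#'   `n_pairs`.
#' @export
intra_cluster_distance <- function(proteins, ppi) {
  proteins <- unique(proteins)
  if (length(proteins) < 2) stop("intra_cluster_distance: need >= 2 proteins")
  g <- igraph::graph_from_data_frame(ppi[, c("protein_a", "protein_b")],
                                     directed = FALSE)
  present <- intersect(proteins, igraph::V(g)$name)
  n_pairs <- choose(length(proteins), 2)
  if (length(present) < 2) {
    return(list(mean_distance = NA_real_, max_distance = NA_real_,
                unreachable_pairs = n_pairs, n_pairs = n_pairs))
  }
  dm <- igraph::distances(g, v = present, to = present)
  dvals <- dm[upper.tri(dm)]
  reachable <- dvals[is.finite(dvals)]
  unreachable <- n_pairs - length(reachable)
  list(
    mean_distance = if (length(reachable) > 0) mean(reachable) else NA_real_,
    max_distance = if (length(reachable) > 0) max(reachable) else NA_real_,
    unreachable_pairs = unreachable,
    n_pairs = n_pairs
  )
}
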