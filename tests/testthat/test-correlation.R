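test_that("phi_coefficient matches the closed-form marginal formula", {
  expect_equal(phi_coefficient(5, 0, 0, 5), 1)
  expect_equal(phi_coefficient(4, 1, 1, 4), 0.6)   # (16-1)/sqrt(5^4) = 15/25
  expect_equal(phi_coefficient(2, 2, 2, 2), 0)
  expect_equal(phi_coefficient(0, 5, 5, 0), -1)
  expect_true(is.na(phi_coefficient(3, 2, 0, 0)))  # zero marginal
  expect_error(phi_coefficient(0, 0, 0, 0), "all-zero")
  # matrix interface
  expect_equal(phi_coefficient(rbind(c(4, 1), c(1, 4))), 0.6)
})

test_that("chi-square identity chi2 = n * phi^2 holds to 1e-10 on 1000 random tables", {
  set.seed(17)
  checked <- 0
  while (checked < 1000) {
    tab <- sample(0:20, 4, replace = TRUE)
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    res <- phi_test(a, b, c, d)
    n <- a + b + c + d
    expect_lt(abs(res$chi2 - n * res$phi^2), 1e-10)
    expect_equal(res$chi2, oracle_chisq(a, b, c, d), tolerance = 1e-10)
    expect_equal(res$phi, oracle_phi(a, b, c, d), tolerance = 1e-10)
    expect_lte(abs(res$phi), 1 + 1e-12)
    checked <- checked + 1
  }
})

test_that("phi_test handles independence and degenerate tables", {
  res <- phi_test(2, 2, 2, 2)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
  deg <- phi_test(3, 2, 0, 0)
  expect_false(deg$evaluable)
  expect_true(is.na(deg$p_value))
})

test_that("phi is symmetric and sign-flips under column complement", {
  set.seed(23)
  for (i in 1:50) {
    tab <- sample(1:15, 4, replace = TRUE)
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    # swapping the two variables transposes the table
    expect_equal(phi_coefficient(a, b, c, d), phi_coefficient(a, c, b, d))
    # complementing one variable swaps its rows
    expect_equal(phi_coefficient(a, b, c, d), -phi_coefficient(c, d, a, b))
  }
})

test_that("build_phi_network tests evaluable pairs and keeps significant edges", {
  # 10 plants; A and B identical columns (targeted by 5), C targeted by all
  inc <- cbind(A = c(rep(1L, 5), rep(0L, 5)),
               B = c(rep(1L, 5), rep(0L, 5)),
               C = rep(1L, 10),
               D = c(rep(0L, 5), rep(1L, 5)))
  rownames(inc) <- paste0("P", 1:10)
  m <- plant_protein_matrix(inc)
  net <- build_phi_network(m)
  # C has a zero "not targeted" marginal: its pairs are not evaluable
  expect_equal(net$m_tests, 3)  # AB, AD, BD
  ab <- net$edges[net$edges$protein_a == "A" & net$edges$protein_b == "B", ]
  expect_equal(ab$phi, 1)
  expect_equal(ab$chi2, 10)
  # negative edges are retained and flagged
  ad <- net$edges[net$edges$protein_a == "A" & net$edges$protein_b == "D", ]
  if (nrow(ad) > 0) expect_identical(ad$sign, "avoided")
  expect_true(all(net$edges$p_adjusted <= net$alpha))
  expect_error(build_phi_network(plant_protein_matrix(inc[, 1, drop = FALSE])),
               ">= 2 targeted")
})

test_that("Bonferroni-retained edges shrink as alpha decreases", {
  ds <- small_dataset()
  filtered <- suppressMessages(filter_records(ds$bioactivity))
  tab <- build_interaction_table(ds$plant_compounds, ds$compounds,
                                 aggregate_evidence(filtered))
  m <- build_matrix(tab, ds$plants)
  alphas <- c(0.1, 0.05, 0.01, 0.001)
  sizes <- vapply(alphas, function(a) nrow(build_phi_network(m, a)$edges),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("components and bridges match the node-deletion oracle", {
  # two triangles sharing one node: shared node is articulating
  edges <- data.frame(
    protein_a = c("A", "B", "A", "X", "Y", "X"),
    protein_b = c("B", "X", "X", "Y", "Z", "Z"),
    phi = 1, chi2 = 10, p_value = 1e-6, p_adjusted = 1e-5, sign = "co-targeted",
    stringsAsFactors = FALSE
  )
  net <- structure(list(nodes = data.frame(protein_id = c("A", "B", "X", "Y", "Z"),
                                           n_plants = 1L),
                        edges = edges, n = 10, m_tests = 6, alpha = 0.05),
                   class = "phi_network")
  cb <- components_and_bridges(net)
  expect_length(cb$components, 1)
  expect_identical(cb$bridges, "X")

  # single edge: one component, no articulation
  net$edges <- edges[1, ]
  cb2 <- components_and_bridges(net)
  expect_length(cb2$components, 1)
  expect_length(cb2$bridges, 0)

  # random graphs vs oracle
  set.seed(29)
  for (rep in 1:10) {
    nodes <- paste0("N", 1:12)
    e <- data.frame(protein_a = sample(nodes, 14, TRUE),
                    protein_b = sample(nodes, 14, TRUE), stringsAsFactors = FALSE)
    e <- e[e$protein_a != e$protein_b, ]
    e <- e[!duplicated(paste(pmin(e$protein_a, e$protein_b),
                             pmax(e$protein_a, e$protein_b))), ]
    net$edges <- cbind(e, phi = 1, chi2 = 1, p_value = 1, p_adjusted = 1,
                       sign = "co-targeted")
    cb <- components_and_bridges(net)
    present <- sort(unique(c(e$protein_a, e$protein_b)))
    oc <- oracle_components(present, e)
    expect_setequal(vapply(cb$components, paste, "", collapse = ","),
                    vapply(oc, paste, "", collapse = ","))
    expect_identical(cb$bridges, oracle_articulation(present, e))
  }
})

test_that("intra_cluster_distance matches the Floyd-Warshall oracle", {
  path <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "C"),
                     stringsAsFactors = FALSE)
  res <- intra_cluster_distance(c("A", "C"), path)
  expect_equal(res$mean_distance, 2)
  expect_equal(res$max_distance, 2)
  tri <- data.frame(protein_a = c("A", "B", "C"), protein_b = c("B", "C", "A"),
                    stringsAsFactors = FALSE)
  res2 <- intra_cluster_distance(c("A", "B", "C"), tri)
  expect_equal(res2$mean_distance, 1)
  expect_equal(res2$max_distance, 1)
  expect_error(intra_cluster_distance("A", tri), ">= 2")

  set.seed(41)
  for (rep in 1:5) {
    nodes <- paste0("N", 1:20)
    e <- data.frame(protein_a = sample(nodes, 25, TRUE),
                    protein_b = sample(nodes, 25, TRUE), stringsAsFactors = FALSE)
    e <- e[e$protein_a != e$protein_b, ]
    set <- sample(nodes, 8)
    res <- intra_cluster_distance(set, e)
    D <- oracle_floyd_warshall(e, nodes)[set, set]
    dv <- D[upper.tri(D)]
    reach <- dv[is.finite(dv)]
    if (length(reach) > 0) {
      expect_equal(res$mean_distance, mean(reach))
      expect_equal(res$max_distance, max(reach))
    }
    expect_equal(res$unreachable_pairs, sum(!is.finite(dv)))
  }
})

test_that("unreachable pairs include proteins absent from the PPI graph", {
  e <- data.frame(protein_a = "A", protein_b = "B", stringsAsFactors = FALSE)
  res <- intra_cluster_distance(c("A", "B", "GHOST"), e)
  expect_equal(res$mean_distance, 1)
  expect_equal(res$unreachable_pairs, 2)
})
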