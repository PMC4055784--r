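ppi_df <- function(...) {
  m <- rbind(...)
  data.frame(protein_a = m[, 1], protein_b = m[, 2],
             score = as.numeric(m[, 3]), stringsAsFactors = FALSE)
}

test_that("expand_neighbors applies the strict score threshold", {
  ppi <- ppi_df(c("A", "B", 401), c("A", "C", 400), c("A", "D", 399))
  expect_identical(expand_neighbors("A", ppi), "B")
  expect_identical(expand_neighbors("A", ppi[0, ]), character())
  # edge direction is irrelevant
  rev <- ppi_df(c("B", "A", 401))
  expect_identical(expand_neighbors("A", rev), "B")
})

test_that("expand_neighbors is order-independent and monotone in the threshold", {
  set.seed(5)
  prot <- paste0("P", 1:30)
  ppi <- data.frame(protein_a = sample(prot, 100, TRUE),
                    protein_b = sample(prot, 100, TRUE),
                    score = runif(100, 0, 1000), stringsAsFactors = FALSE)
  ppi <- ppi[ppi$protein_a != ppi$protein_b, ]
  seeds <- c("P1", "P2")
  base <- expand_neighbors(seeds, ppi)
  expect_identical(expand_neighbors(seeds, ppi[sample(nrow(ppi)), ]), base)
  for (thr in c(200, 400, 600, 800)) {
    expect_true(all(expand_neighbors(seeds, ppi, thr + 100) %in%
                      expand_neighbors(seeds, ppi, thr)))
  }
})

test_that("dedupe_ppi collapses reciprocal rows keeping the max score", {
  ppi <- ppi_df(c("A", "B", 500), c("B", "A", 700), c("A", "A", 900))
  out <- dedupe_ppi(ppi)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 700)
  expect_identical(out$protein_a, "A")
})

test_that("organism and expression filters prune the space", {
  ppi <- ppi_df(c("S1", "N1", 900), c("S1", "N2", 900))
  ppi$organism <- c("Homo sapiens", "Saccharomyces cerevisiae")
  expression <- data.frame(protein_id = c("S1", "N1", "N2"),
                           positive = c(TRUE, FALSE, TRUE),
                           stringsAsFactors = FALSE)
  # organism filter removes the yeast edge before expansion; the expression
  # filter then removes N1
  sp <- target_space(list(drug_target = "S1"), ppi, expression = expression,
                     allowed_organisms = "Homo sapiens")
  expect_identical(sp$neighbors$drug_target, character())
  expect_identical(sp$seeds$drug_target, "S1")

  # without the organism filter N2 would be a neighbor
  sp2 <- target_space(list(drug_target = "S1"), ppi, expression = expression)
  expect_identical(sp2$neighbors$drug_target, "N2")

  # all-positive expression leaves the space unchanged
  expression$positive <- TRUE
  sp3 <- target_space(list(drug_target = "S1"), ppi, expression = expression)
  expect_setequal(sp3$neighbors$drug_target, c("N1", "N2"))

  # expression filter applies to seeds too
  expr4 <- data.frame(protein_id = c("S1", "N1", "N2"),
                      positive = c(FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  sp4 <- target_space(list(drug_target = "S1"), ppi, expression = expr4)
  expect_identical(sp4$seeds$drug_target, character())
})

test_that("edges without organism labels are kept with a warning", {
  ppi <- ppi_df(c("S1", "N1", 900))
  ppi$organism <- NA_character_
  expect_warning(sp <- target_space(list(a = "S1"), ppi,
                                    allowed_organisms = "Homo sapiens"),
                 "treated as allowed")
  expect_identical(sp$neighbors$a, "N1")
  expect_warning(target_space(list(a = "S1"), ppi_df(c("S1", "N1", 900)),
                              allowed_organisms = "Homo sapiens"),
                 "no organism column")
})

test_that("filtered space is a subset of the unfiltered space per category", {
  ds <- small_dataset()
  unfiltered <- suppressWarnings(target_space(ds$seeds, ds$ppi))
  filtered <- suppressWarnings(
    target_space(ds$seeds, ds$ppi, expression = ds$expression,
                 allowed_organisms = DEFAULT_ORGANISMS))
  for (cat_name in names(ds$seeds)) {
    expect_true(all(filtered$seeds[[cat_name]] %in% unfiltered$seeds[[cat_name]]))
    expect_true(all(filtered$neighbors[[cat_name]] %in% unfiltered$neighbors[[cat_name]]))
    # neighbors exclude own seeds
    expect_length(intersect(filtered$neighbors[[cat_name]],
                            filtered$seeds[[cat_name]]), 0)
  }
})

test_that("category_overlap matches brute-force set enumeration", {
  disjoint <- list(a = c("P1", "P2"), b = c("P3", "P4", "P5"),
                   c = c("P6", "P7", "P8", "P9"))
  ov <- category_overlap(disjoint)
  expect_equal(ov$unique_seed_total, 9)
  identical_sets <- list(a = paste0("P", 1:5), b = paste0("P", 1:5),
                         c = paste0("P", 1:5))
  ov2 <- category_overlap(identical_sets)
  expect_equal(ov2$unique_seed_total, 5)
  expect_equal(ov2$regions[["a&b&c"]], 5)

  set.seed(77)
  for (rep in 1:20) {
    sets <- list(a = sample(paste0("P", 1:15), sample(1:10, 1)),
                 b = sample(paste0("P", 1:15), sample(1:10, 1)),
                 c = sample(paste0("P", 1:15), sample(1:10, 1)))
    ov <- category_overlap(sets)
    expect_equal(ov$unique_seed_total, length(unique(unlist(sets))))
    # inclusion-exclusion consistency: region counts sum to the union size
    expect_equal(sum(unlist(ov$regions)), ov$unique_seed_total)
    # triple overlap region matches direct intersection
    triple <- length(Reduce(intersect, sets))
    expect_equal(ov$regions[["a&b&c"]] %||% 0, triple)
  }
})

test_that("apply_filters rebuilds the space under new filters", {
  ds <- small_dataset()
  sp <- suppressWarnings(target_space(ds$seeds, ds$ppi))
  filt <- suppressWarnings(apply_filters(sp, expression = ds$expression,
                                         ppi = ds$ppi,
                                         allowed_organisms = DEFAULT_ORGANISMS))
  direct <- suppressWarnings(
    target_space(ds$seeds, ds$ppi, expression = ds$expression,
                 allowed_organisms = DEFAULT_ORGANISMS))
  expect_identical(filt$seeds, direct$seeds)
  expect_identical(filt$neighbors, direct$neighbors)
})
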