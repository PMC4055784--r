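make_record <- function(type = "Ki", value = 6, organism = "Homo sapiens",
                        key = "KEY", protein = "PR001") {
  data.frame(compound_inchikey = key, protein_id = protein, organism = organism,
             type = type, value = value, stringsAsFactors = FALSE)
}

test_that("filter_records keeps allowed type/organism combinations and preserves order", {
  recs <- rbind(
    make_record("Ki", 6, "Homo sapiens", "A"),
    make_record("Ki", 6, "Danio rerio", "B"),
    make_record("IC50", 7, "Mus musculus", "C"),
    make_record("AC50", 7, "Homo sapiens", "D"),
    make_record("inhibition", 50, "Rattus norvegicus", "E")
  )
  expect_message(out <- filter_records(recs), "unknown measurement type")
  expect_identical(out$compound_inchikey, c("A", "C", "E"))
  expect_identical(filter_records(recs[0, ]), recs[0, ])
})

test_that("filter_records clamps out-of-range inhibition and drops negative potency", {
  recs <- rbind(make_record("inhibition", 120, key = "A"),
                make_record("inhibition", -5, key = "B"),
                make_record("potency", -1, key = "C"))
  expect_message(expect_warning(out <- filter_records(recs), "clamped"))
  expect_equal(out$value, c(100, 0))
  expect_false("C" %in% out$compound_inchikey)
})

test_that("positivity thresholds are strict on all three measurement scales", {
  # at-threshold values are negative; just-over values positive
  expect_false(is_positive("Ki", 5.5))
  expect_true(is_positive("Ki", 5.500001))
  expect_true(is_positive("IC50", 6.0))
  expect_false(is_positive("Kd", 5.4))
  expect_false(is_positive("inhibition", 20.0))
  expect_true(is_positive("inhibition", 20.5))
  expect_false(is_positive("potency", 500.0))
  expect_true(is_positive("potency", 499.9))
  expect_error(is_positive("AC50", 1), "unknown measurement type")
})

test_that("aggregate_evidence computes the positive-evidence frequency with inclusive 0.5 call", {
  recs <- rbind(
    make_record("Ki", 6), make_record("Ki", 7), make_record("Ki", 8),
    make_record("Ki", 4),                      # 3/4 positive
    make_record("Ki", 6, protein = "PR002"), make_record("Ki", 4, protein = "PR002"),
    make_record("Ki", 4, protein = "PR003"), make_record("Ki", 5, protein = "PR003")
  )
  ev <- aggregate_evidence(recs)
  ev <- ev[order(ev$protein_id), ]
  expect_equal(ev$probability, c(0.75, 0.5, 0))
  expect_equal(ev$interacting, c(TRUE, TRUE, FALSE))
  expect_equal(ev$n_total, c(4L, 2L, 2L))
  expect_error(aggregate_evidence(recs[0, ]), "no records")
})

test_that("aggregate_evidence is permutation-invariant", {
  set.seed(9)
  recs <- do.call(rbind, lapply(1:40, function(i) {
    make_record("Ki", runif(1, 3, 9), key = sample(c("A", "B", "C"), 1),
                protein = sample(c("P1", "P2"), 1))
  }))
  ev1 <- aggregate_evidence(recs)
  perm <- recs[sample(nrow(recs)), ]
  ev2 <- aggregate_evidence(perm)
  key <- function(e) e[order(e$compound_inchikey, e$protein_id), ]
  expect_equal(key(ev1), key(ev2), ignore_attr = TRUE)
})

test_that("interacting calls shrink monotonically as thresholds tighten", {
  set.seed(11)
  recs <- do.call(rbind, lapply(1:200, function(i) {
    type <- sample(BIOACTIVITY_TYPES, 1)
    value <- switch(type, inhibition = runif(1, 0, 100),
                    potency = runif(1, 1, 1000), runif(1, 3, 9))
    make_record(type, value, key = paste0("K", sample(1:30, 1)),
                protein = paste0("P", sample(1:10, 1)))
  }))
  loose <- sum(aggregate_evidence(recs)$interacting)
  tight <- sum(aggregate_evidence(recs, pchembl_threshold = 6.5,
                                  inhibition_threshold = 40,
                                  potency_threshold = 200)$interacting)
  expect_lte(tight, loose)
})

test_that("tanimoto matches the set-arithmetic oracle exactly on 1000 random pairs", {
  expect_equal(tanimoto(c(1, 1, 1, 0), c(1, 1, 1, 0)), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  # bits {1,2,3} vs {2,3,4}: |int| 2, |union| 4
  expect_equal(tanimoto(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 0)), 0.5)
  expect_equal(tanimoto(rep(0, 8), rep(0, 8)), 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "lengths differ")
  set.seed(123)
  for (i in 1:1000) {
    a <- rand_bits(64, runif(1, 0, 0.6))
    b <- rand_bits(64, runif(1, 0, 0.6))
    expect_identical(tanimoto(a, b), oracle_tanimoto(a, b))
  }
})

test_that("tanimoto accepts bit-string fingerprints and is symmetric", {
  expect_equal(tanimoto("1101", "1001"), tanimoto("1001", "1101"))
  expect_equal(tanimoto("1101", c(1, 0, 0, 1)), 2 / 3)
})

test_that("match_compound applies inclusive Tc and strict MW boundaries", {
  # 20-bit fingerprints engineered to hit Tc exactly 0.85: |int| 17, |union| 20
  fp_a <- c(rep(1, 17), 1, 1, 1)
  fp_b <- c(rep(1, 17), 0, 0, 0)
  stopifnot(oracle_tanimoto(fp_a, fp_b) == 0.85)
  pack <- function(x) paste(x, collapse = "")
  ref <- data.frame(
    compound_id = c("R1", "R2", "R3"),
    inchikey = c("KEYAAA", "KEYBBB", "KEYCCC"),
    fingerprint = c(pack(fp_b), pack(fp_b), pack(fp_a)),
    mw = c(349, 350, 300), stringsAsFactors = FALSE
  )
  query <- list(inchikey = "KEYCCC", fingerprint = pack(fp_a), mw = 300)
  res <- match_compound(query, ref)
  expect_identical(res$exact$compound_id, "R3")
  expect_identical(res$similar$compound_id, "R1")   # Tc = 0.85, dMW = 49: hit
  # R2: dMW = 50 exactly -> excluded by the strict MW rule
  expect_false("R2" %in% res$similar$compound_id)
  expect_equal(res$similar$tanimoto, 0.85)

  expect_error(match_compound(list(inchikey = "X", mw = 1), ref), "no fingerprint")
  exact_only <- match_compound(list(inchikey = "KEYAAA", mw = 1), ref,
                               similarity = FALSE)
  expect_identical(exact_only$exact$compound_id, "R1")
})

test_that("build_interaction_table routes direct and similar interactions correctly", {
  pack <- function(x) paste(x, collapse = "")
  base_fp <- c(rep(1, 20), rep(0, 12))
  near_fp <- c(rep(1, 19), 0, rep(0, 11), 1)   # Tc 19/21 = 0.905
  far_fp <- c(rep(0, 20), rep(1, 12))
  compounds <- data.frame(
    compound_id = c("C1", "C2", "C3"),
    inchikey = c("KEY1", "KEY2", "KEY3"),
    fingerprint = c(pack(base_fp), pack(near_fp), pack(far_fp)),
    mw = c(300, 310, 300), tpsa = 1, slogp = 1, stringsAsFactors = FALSE
  )
  plant_compounds <- data.frame(
    plant_id = c("PL1", "PL1", "PL2", "PL2"),
    compound_id = c("C1", "C2", "C2", "C3"), stringsAsFactors = FALSE
  )
  # only C1 has evidence; C2 is similar to C1; C3 is neither
  evidence <- data.frame(
    compound_inchikey = c("KEY1", "KEY1"), protein_id = c("T1", "T2"),
    n_positive = c(2L, 0L), n_total = c(2L, 2L), probability = c(1, 0),
    interacting = c(TRUE, FALSE), stringsAsFactors = FALSE
  )
  tab <- build_interaction_table(plant_compounds, compounds, evidence)
  expect_setequal(tab$route[tab$compound_id == "C1"], "direct")
  expect_setequal(tab$route[tab$compound_id == "C2"], "similar")
  # non-interacting evidence (T2) contributes no rows
  expect_false("T2" %in% tab$protein_id)
  # C3 has no route at all
  expect_false("C3" %in% tab$compound_id)
  # PL2 carries C2, so it reaches T1 through the similarity route
  expect_true(any(tab$plant_id == "PL2" & tab$protein_id == "T1"))
})

test_that("similarity route is restricted to seed proteins when a target space is given", {
  pack <- function(x) paste(x, collapse = "")
  fp <- pack(c(rep(1, 20), rep(0, 4)))
  compounds <- data.frame(
    compound_id = c("C1", "C2"), inchikey = c("KEY1", "KEY2"),
    fingerprint = c(fp, fp), mw = c(300, 301), stringsAsFactors = FALSE
  )
  plant_compounds <- data.frame(plant_id = c("PL1", "PL1"),
                                compound_id = c("C1", "C2"),
                                stringsAsFactors = FALSE)
  evidence <- data.frame(
    compound_inchikey = c("KEY1", "KEY1"), protein_id = c("SEED1", "NB1"),
    n_positive = 1L, n_total = 1L, probability = 1, interacting = TRUE,
    stringsAsFactors = FALSE
  )
  ppi <- data.frame(protein_a = "SEED1", protein_b = "NB1", score = 900,
                    stringsAsFactors = FALSE)
  space <- target_space(list(drug_target = "SEED1"), ppi)
  tab <- build_interaction_table(plant_compounds, compounds, evidence, space = space)
  direct <- tab[tab$route == "direct", ]
  similar <- tab[tab$route == "similar", ]
  expect_setequal(direct$protein_id, c("SEED1", "NB1"))   # seeds + neighbors
  expect_setequal(similar$protein_id, "SEED1")            # seeds only
})
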