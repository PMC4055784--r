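# Synthetic study generator: plants, compounds with heavy-tailed sharing,
# seed/neighbor protein space, bioactivity records with planted true
# interactions and decoys, planted plant-group -> protein-cluster
# co-targeting structure, and a toy colon metabolic network. Every stage of
# the pipeline is exercisable against the planted truth.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe a desk-scale study: 80 plants, 1,200 compounds whose
#' plants-per-compound counts follow a truncated power law (most compounds
#' plant-specific), a candidate space of three 8-seed categories plus 40
#' neighbor proteins, three planted plant-group/protein-cluster co-targeting
#' assignments, and bioactivity noise calibrated so planted pairs carry
#' mostly positive evidence (85 percent per record) and decoy pairs mostly
#' negative (10 percent).
#'
#' @param n_plants number of plants.
#' @param edible_fraction fraction of plants flagged edible.
#' @param n_compounds number of phytochemicals.
#' @param sharing_alpha exponent of the truncated power-law distribution of
#'   plants per compound (larger = more plant-specific compounds).
#' @param n_seed_targets_per_category named counts for the three seed
#'   categories.
#' @param n_neighbor_proteins number of first-degree-neighbor proteins.
#' @param expression_positive_rate probability a non-planted protein is
#'   expression-positive (planted cluster proteins are always positive).
#' @param records_per_pair candidate record counts per assayed pair.
#' @param planted_positive_rate,decoy_positive_rate per-record probability
#'   that a planted (resp. decoy) pair's measurement exceeds its threshold.
#' @param disallowed_organism_rate per-record probability of a non-rodent,
#'   non-human assay organism (filtered downstream).
#' @param n_planted_clusters,cluster_size,plants_per_group,markers_per_group
#'   planted co-targeting structure: each cluster of `cluster_size` proteins
#'   is targeted by `markers_per_group` marker compounds found in exactly
#'   one disjoint group of `plants_per_group` plants.
#' @param n_background_pairs additional planted compound-protein pairs on
#'   non-cluster proteins (bulk true interactions).
#' @param n_decoy_pairs assayed pairs with no planted interaction.
#' @param n_analog_pairs evidence-free compounds made structurally similar
#'   (few fingerprint bit flips, close MW) to an evidenced compound, to
#'   exercise the similarity route.
#' @param n_reactions,n_metabolites,n_pathways toy metabolic network size.
#' @param metabolite_exact_fraction fraction of metabolites sharing an
#'   InChIKey with some compound (exact matches).
#' @param n_similar_metabolites metabolites made structurally similar to a
#'   compound without key identity.
#' @param fingerprint_bits,fingerprint_density fingerprint length and
#'   expected set-bit fraction.
#' @param ppi_extra_edges additional random PPI edges (mixed scores).
#' @param rng_seed integer seed; fixed seed gives byte-identical output.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_plants = 80,
                             edible_fraction = 0.35,
                             n_compounds = 1200,
                             sharing_alpha = 2,
                             n_seed_targets_per_category = c(drug_target = 8,
                                                             kegg_pathway = 8,
                                                             prognostic_signature = 8),
                             n_neighbor_proteins = 40,
                             expression_positive_rate = 0.92,
                             records_per_pair = 2:4,
                             planted_positive_rate = 0.85,
                             decoy_positive_rate = 0.10,
                             disallowed_organism_rate = 0.03,
                             n_planted_clusters = 3,
                             cluster_size = 7,
                             plants_per_group = 20,
                             markers_per_group = 3,
                             n_background_pairs = 250,
                             n_decoy_pairs = 300,
                             n_analog_pairs = 25,
                             n_reactions = 120,
                             n_metabolites = 90,
                             n_pathways = 8,
                             metabolite_exact_fraction = 0.4,
                             n_similar_metabolites = 5,
                             fingerprint_bits = 1024,
                             fingerprint_density = 0.05,
                             ppi_extra_edges = 120,
                             rng_seed = 20140517) {
  cfg <- as.list(environment())
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  counts <- c("n_plants", "n_compounds", "n_neighbor_proteins", "n_reactions",
              "n_metabolites", "n_pathways", "fingerprint_bits")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      stop("generator_config: ", nm, " must be a positive count")
    }
  }
  rates <- c("edible_fraction", "expression_positive_rate", "planted_positive_rate",
             "decoy_positive_rate", "disallowed_organism_rate",
             "metabolite_exact_fraction", "fingerprint_density")
  for (nm in rates) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop("generator_config: ", nm, " must be in [0, 1]")
  }
  if (any(cfg$n_seed_targets_per_category <= 0) ||
      length(cfg$n_seed_targets_per_category) != 3 ||
      is.null(names(cfg$n_seed_targets_per_category))) {
    stop("generator_config: n_seed_targets_per_category must be three named positive counts")
  }
  n_proteins <- sum(cfg$n_seed_targets_per_category) + cfg$n_neighbor_proteins
  if (cfg$n_planted_clusters * cfg$cluster_size > n_proteins) {
    stop("generator_config: planted clusters need more proteins than are generated")
  }
  if (cfg$n_planted_clusters * cfg$plants_per_group > cfg$n_plants) {
    stop("generator_config: planted plant groups need more plants than are generated")
  }
  if (cfg$n_planted_clusters * cfg$markers_per_group +
      cfg$n_analog_pairs * 2 > cfg$n_compounds) {
    stop("generator_config: not enough compounds for markers and analog pairs")
  }
  if (cfg$sharing_alpha <= 1) stop("generator_config: sharing_alpha must exceed 1")
  invisible(cfg)
}

#' Expected plant-specific compound fraction under the sharing law
#'
#' Probability that a compound occurs in exactly one plant under the
#' truncated power law P(k) proportional to k^-alpha, k = 1..n_plants.
#'
#' @param sharing_alpha power-law exponent.
#' @param n_plants truncation point.
#' @return numeric scalar in (0, 1).
#' @export
expected_specific_fraction <- function(sharing_alpha, n_plants) {
  k <- seq_len(n_plants)
  w <- k^(-sharing_alpha)
  w[1] / sum(w)
}

rand_inchikey <- function(n) {
  blk <- function(len) {
    vapply(seq_len(n), function(i)
      paste(sample(LETTERS, len, replace = TRUE), collapse = ""), character(1))
  }
  paste0(blk(14), "-", blk(10), "-N")
}

rand_fingerprint <- function(n, bits, density) {
  vapply(seq_len(n), function(i) {
    paste(ifelse(stats::runif(bits) < density, "1", "0"), collapse = "")
  }, character(1))
}

flip_fingerprint_bits <- function(fp, n_flips) {
  bits <- strsplit(fp, "", fixed = TRUE)[[1]]
  idx <- sample(length(bits), n_flips)
  bits[idx] <- ifelse(bits[idx] == "1", "0", "1")
  paste(bits, collapse = "")
}

# Perturb a fingerprint while guaranteeing Tc >= 0.85 to the original:
# with s set bits, f flips give worst-case Tc (s - f) / (s + f), so f is
# capped well below 0.08 * s (and sparse fingerprints are left untouched).
make_analog_fingerprint <- function(fp) {
  s <- sum(as_fingerprint(fp))
  f <- if (s >= 17) max(1L, floor(0.06 * s)) else if (s >= 7) 1L else 0L
  if (f == 0L) fp else flip_fingerprint_bits(fp, f)
}

# Draw a measurement record for a pair given its positive/negative call.
draw_records <- function(n, positive) {
  type <- sample(BIOACTIVITY_TYPES, n, replace = TRUE)
  value <- numeric(n)
  pch <- type %in% c("Ki", "IC50", "EC50", "Kd")
  value[pch & positive] <- stats::runif(sum(pch & positive), 5.6, 9.5)
  value[pch & !positive] <- stats::runif(sum(pch & !positive), 3.0, 5.4)
  inh <- type == "inhibition"
  value[inh & positive] <- stats::runif(sum(inh & positive), 25, 95)
  value[inh & !positive] <- stats::runif(sum(inh & !positive), 0, 18)
  pot <- type == "potency"
  value[pot & positive] <- stats::runif(sum(pot & positive), 1, 450)
  value[pot & !positive] <- stats::runif(sum(pot & !positive), 550, 5000)
  data.frame(type = type, value = value, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Produces every input table the pipeline consumes, plus a truth manifest
#' recording the planted compound-protein interactions, planted protein
#' clusters, planted plant groups and analog pairs. Deterministic under
#' `config$rng_seed`.
#'
#' @param config a [generator_config()].
#' @return list of class `phytonet_dataset`: `plants`, `plant_compounds`,
#'   `compounds`, `bioactivity`, `ppi`, `seeds` (list), `expression`,
#'   `reactions`, `metabolites`, `truth`, `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  validate_generator_config(config)
  set.seed(config$rng_seed)

  # ---- plants -------------------------------------------------------------
  plant_ids <- sprintf("PL%03d", seq_len(config$n_plants))
  edible <- rep(FALSE, config$n_plants)
  edible[sample(config$n_plants, round(config$edible_fraction * config$n_plants))] <- TRUE
  plants <- data.frame(plant_id = plant_ids,
                       plant_name = paste0("plant_", seq_along(plant_ids)),
                       edible = edible, stringsAsFactors = FALSE)

  # ---- protein space: seeds, neighbors, PPI -------------------------------
  n_seed <- config$n_seed_targets_per_category
  seed_pool <- sprintf("PR%03d", seq_len(max(3L, sum(n_seed) - 2L)))
  seeds <- lapply(n_seed, function(k) sort(sample(seed_pool, k)))
  names(seeds) <- names(n_seed)
  seed_union <- unique(unlist(seeds, use.names = FALSE))
  neighbor_ids <- sprintf("PR%03d", length(seed_pool) + seq_len(config$n_neighbor_proteins))
  all_proteins <- c(seed_pool, neighbor_ids)

  # every neighbor is wired to >= 1 seed above the confidence threshold
  ppi <- data.frame(
    protein_a = sample(seed_union, length(neighbor_ids), replace = TRUE),
    protein_b = neighbor_ids,
    score = sample(401:999, length(neighbor_ids), replace = TRUE),
    organism = "Homo sapiens", stringsAsFactors = FALSE
  )
  # seed-seed backbone keeps the graph connected for path statistics
  if (length(seed_union) > 1) {
    ppi <- rbind(ppi, data.frame(
      protein_a = seed_union[-length(seed_union)],
      protein_b = seed_union[-1],
      score = sample(401:999, length(seed_union) - 1, replace = TRUE),
      organism = "Homo sapiens", stringsAsFactors = FALSE))
  }
  extra <- data.frame(
    protein_a = sample(all_proteins, config$ppi_extra_edges, replace = TRUE),
    protein_b = sample(all_proteins, config$ppi_extra_edges, replace = TRUE),
    score = sample(150:999, config$ppi_extra_edges, replace = TRUE),
    organism = sample(c(DEFAULT_ORGANISMS, "Saccharomyces cerevisiae"),
                      config$ppi_extra_edges, replace = TRUE,
                      prob = c(0.6, 0.15, 0.15, 0.1)),
    stringsAsFactors = FALSE
  )
  ppi <- rbind(ppi, extra)
  ppi <- ppi[ppi$protein_a != ppi$protein_b, , drop = FALSE]
  rownames(ppi) <- NULL

  # ---- planted clusters and plant groups ----------------------------------
  # clusters live inside the candidate space (seeds or wired neighbors) so
  # the planted structure survives target-space assembly
  space_proteins <- c(seed_union, neighbor_ids)
  cluster_proteins <- sample(space_proteins,
                             config$n_planted_clusters * config$cluster_size)
  planted_clusters <- split(cluster_proteins,
                            rep(seq_len(config$n_planted_clusters),
                                each = config$cluster_size))
  planted_clusters <- lapply(unname(planted_clusters), sort)
  group_plants <- sample(plant_ids,
                         config$n_planted_clusters * config$plants_per_group)
  planted_groups <- split(group_plants,
                          rep(seq_len(config$n_planted_clusters),
                              each = config$plants_per_group))
  planted_groups <- lapply(unname(planted_groups), sort)

  # expression: planted cluster proteins always positive
  expression <- data.frame(
    protein_id = all_proteins,
    positive = stats::runif(length(all_proteins)) < config$expression_positive_rate,
    stringsAsFactors = FALSE
  )
  expression$positive[expression$protein_id %in% cluster_proteins] <- TRUE

  # ---- compounds ----------------------------------------------------------
  nc <- config$n_compounds
  compounds <- data.frame(
    compound_id = sprintf("CMP%04d", seq_len(nc)),
    inchikey = rand_inchikey(nc),
    mw = stats::rlnorm(nc, log(350), 0.35),
    tpsa = pmax(0, stats::rnorm(nc, 90, 40)),
    slogp = stats::rnorm(nc, 2, 1.5),
    fingerprint = rand_fingerprint(nc, config$fingerprint_bits,
                                   config$fingerprint_density),
    group = "phytochemical",
    stringsAsFactors = FALSE
  )

  # heavy-tailed plant sharing
  k_plants <- sample(seq_len(config$n_plants), nc, replace = TRUE,
                     prob = seq_len(config$n_plants)^(-config$sharing_alpha))
  assignment <- lapply(k_plants, function(k) sample(plant_ids, k))

  # roles: markers (cluster drivers), analogs (evidence-free similars),
  # analog templates (evidenced), the rest free
  n_markers <- config$n_planted_clusters * config$markers_per_group
  special <- sample(nc, n_markers + 2 * config$n_analog_pairs)
  marker_idx <- special[seq_len(n_markers)]
  analog_idx <- special[n_markers + seq_len(config$n_analog_pairs)]
  template_idx <- special[n_markers + config$n_analog_pairs +
                            seq_len(config$n_analog_pairs)]

  marker_by_cluster <- split(marker_idx,
                             rep(seq_len(config$n_planted_clusters),
                                 each = config$markers_per_group))
  for (g in seq_len(config$n_planted_clusters)) {
    for (i in marker_by_cluster[[g]]) assignment[[i]] <- planted_groups[[g]]
  }
  for (j in seq_len(config$n_analog_pairs)) {
    ai <- analog_idx[j]; ti <- template_idx[j]
    compounds$fingerprint[ai] <- make_analog_fingerprint(compounds$fingerprint[ti])
    compounds$mw[ai] <- compounds$mw[ti] + stats::runif(1, -20, 20)
  }

  plant_compounds <- data.frame(
    plant_id = unlist(assignment, use.names = FALSE),
    compound_id = rep(compounds$compound_id, lengths(assignment)),
    stringsAsFactors = FALSE
  )

  # ---- planted interactions ----------------------------------------------
  marker_pairs <- do.call(rbind, lapply(seq_len(config$n_planted_clusters), function(g) {
    expand.grid(compound_idx = marker_by_cluster[[g]],
                protein_id = planted_clusters[[g]],
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  marker_pairs$kind <- "marker"

  background_proteins <- setdiff(all_proteins, cluster_proteins)
  free_idx <- setdiff(seq_len(nc), c(marker_idx, analog_idx))
  bg <- unique(data.frame(
    compound_idx = sample(free_idx, config$n_background_pairs, replace = TRUE),
    protein_id = sample(background_proteins, config$n_background_pairs, replace = TRUE),
    stringsAsFactors = FALSE
  ))
  # analog templates need evidence of their own: guarantee each >= 1 planted pair
  tmpl <- data.frame(
    compound_idx = template_idx,
    protein_id = sample(background_proteins, length(template_idx), replace = TRUE),
    stringsAsFactors = FALSE
  )
  bg <- unique(rbind(bg, tmpl))
  bg$kind <- "background"
  planted <- rbind(marker_pairs, bg)
  planted <- planted[!duplicated(planted[, c("compound_idx", "protein_id")]), ]

  # decoys: assayed pairs with no planted interaction (analogs stay unassayed)
  decoy_pool_idx <- setdiff(seq_len(nc), analog_idx)
  decoy <- unique(data.frame(
    compound_idx = sample(decoy_pool_idx, config$n_decoy_pairs, replace = TRUE),
    protein_id = sample(all_proteins, config$n_decoy_pairs, replace = TRUE),
    stringsAsFactors = FALSE
  ))
  decoy_key <- paste(decoy$compound_idx, decoy$protein_id)
  planted_key <- paste(planted$compound_idx, planted$protein_id)
  decoy <- decoy[!(decoy_key %in% planted_key), , drop = FALSE]

  # ---- bioactivity records ------------------------------------------------
  make_records <- function(pairs, positive_rate) {
    if (nrow(pairs) == 0) return(NULL)
    n_rec <- sample(config$records_per_pair, nrow(pairs), replace = TRUE)
    rec_pair <- rep(seq_len(nrow(pairs)), n_rec)
    total <- length(rec_pair)
    pos <- stats::runif(total) < positive_rate
    vals <- draw_records(total, pos)
    org <- ifelse(stats::runif(total) < config$disallowed_organism_rate,
                  "Danio rerio",
                  sample(DEFAULT_ORGANISMS, total, replace = TRUE))
    data.frame(
      compound_inchikey = compounds$inchikey[pairs$compound_idx[rec_pair]],
      protein_id = pairs$protein_id[rec_pair],
      organism = org,
      type = vals$type,
      value = vals$value,
      stringsAsFactors = FALSE
    )
  }
  bioactivity <- rbind(make_records(planted, config$planted_positive_rate),
                       make_records(decoy, config$decoy_positive_rate))
  bioactivity <- bioactivity[sample(nrow(bioactivity)), , drop = FALSE]
  rownames(bioactivity) <- NULL

  # ---- metabolic network --------------------------------------------------
  nm <- config$n_metabolites
  metabolites <- data.frame(
    metabolite_id = sprintf("MET%03d", seq_len(nm)),
    inchikey = rand_inchikey(nm),
    mw = stats::rlnorm(nm, log(250), 0.4),
    fingerprint = rand_fingerprint(nm, config$fingerprint_bits,
                                   config$fingerprint_density),
    stringsAsFactors = FALSE
  )
  n_exact <- round(config$metabolite_exact_fraction * nm)
  if (n_exact > 0) {
    src <- sample(nc, n_exact)
    tgt <- sample(nm, n_exact)
    metabolites$inchikey[tgt] <- compounds$inchikey[src]
    metabolites$mw[tgt] <- compounds$mw[src]
    metabolites$fingerprint[tgt] <- compounds$fingerprint[src]
  }
  if (config$n_similar_metabolites > 0) {
    sim_tgt <- sample(setdiff(seq_len(nm), if (n_exact > 0) tgt else integer()),
                      config$n_similar_metabolites)
    sim_src <- sample(setdiff(seq_len(nc), if (n_exact > 0) src else integer()),
                      config$n_similar_metabolites)
    for (j in seq_len(config$n_similar_metabolites)) {
      metabolites$fingerprint[sim_tgt[j]] <-
        make_analog_fingerprint(compounds$fingerprint[sim_src[j]])
      metabolites$mw[sim_tgt[j]] <- compounds$mw[sim_src[j]] + stats::runif(1, -20, 20)
    }
  }

  pathways <- paste0("pathway_", LETTERS[seq_len(config$n_pathways)])
  rx_rows <- lapply(seq_len(config$n_reactions), function(r) {
    n_sub <- sample(1:3, 1)
    n_prod <- sample(1:2, 1)
    mets <- sample(metabolites$metabolite_id, n_sub + n_prod)
    data.frame(
      reaction_id = sprintf("RXN%03d", r),
      metabolite_id = mets,
      role = c(rep("substrate", n_sub), rep("product", n_prod)),
      enzyme_id = sample(all_proteins, 1),
      pathway = sample(pathways, 1),
      stringsAsFactors = FALSE
    )
  })
  reactions <- do.call(rbind, rx_rows)
  rownames(reactions) <- NULL

  truth <- list(
    planted_interactions = data.frame(
      compound_id = compounds$compound_id[planted$compound_idx],
      inchikey = compounds$inchikey[planted$compound_idx],
      protein_id = planted$protein_id,
      kind = planted$kind,
      stringsAsFactors = FALSE
    ),
    planted_clusters = planted_clusters,
    planted_plant_groups = planted_groups,
    analog_pairs = data.frame(
      analog_id = compounds$compound_id[analog_idx],
      template_id = compounds$compound_id[template_idx],
      stringsAsFactors = FALSE
    )
  )

  structure(list(plants = plants, plant_compounds = plant_compounds,
                 compounds = compounds, bioactivity = bioactivity, ppi = ppi,
                 seeds = seeds, expression = expression, reactions = reactions,
                 metabolites = metabolites, truth = truth, config = config),
            class = "phytonet_dataset")
}

#' @export
print.phytonet_dataset <- function(x, ...) {
  cat(sprintf(paste0("phytonet_dataset: %d plants, %d compounds, %d bioactivity records,\n",
                     "  %d proteins (%d seeds), %d PPI edges, %d reactions\n"),
              nrow(x$plants), nrow(x$compounds), nrow(x$bioactivity),
              nrow(x$expression), length(unique(unlist(x$seeds))),
              nrow(x$ppi), length(unique(x$reactions$reaction_id))))
  invisible(x)
}

#' Fixture matrix for the worked efficacy example
#'
#' Builds a two-plant incidence matrix in which the focal plant targets
#' exactly `n_targeted_by_plant` proteins and the union of all plants'
#' targets has exactly `n_total_targeted` members (a reference plant covers
#' the union), so the focal plant's efficacy is
#' `n_targeted_by_plant / n_total_targeted`.
#'
#' @param n_targeted_by_plant proteins targeted by the focal plant.
#' @param n_total_targeted size of the targeted union; must be >=
#'   `n_targeted_by_plant`.
#' @return a [plant_protein_matrix()] with plants `"focal"` and
#'   `"reference"`.
#' @export
generate_worked_example_matrix <- function(n_targeted_by_plant, n_total_targeted) {
  if (n_targeted_by_plant < 0 || n_total_targeted < n_targeted_by_plant) {
    stop("generate_worked_example_matrix: need 0 <= n_targeted_by_plant <= n_total_targeted")
  }
  if (n_total_targeted == 0) stop("generate_worked_example_matrix: empty targeted union")
  proteins <- sprintf("X%d", seq_len(n_total_targeted))
  inc <- rbind(
    focal = c(rep(1L, n_targeted_by_plant),
              rep(0L, n_total_targeted - n_targeted_by_plant)),
    reference = rep(1L, n_total_targeted)
  )
  colnames(inc) <- proteins
  plant_protein_matrix(inc, plants = data.frame(plant_id = c("focal", "reference"),
                                                edible = c(TRUE, FALSE),
                                                stringsAsFactors = FALSE))
}
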