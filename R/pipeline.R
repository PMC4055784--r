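# End-to-end orchestration: generate or load inputs, aggregate bioactivity
# evidence, assemble the target space, build the interactome, the phi
# co-targeting network, metabolic perturbations and the chemical-space
# embedding, with one config and a reproducible run report.

#' Pipeline configuration
#'
#' Consolidates every threshold of the analysis with its standard default:
#' pChEMBL > 5.5, inhibition > 20 percent, potency < 500 uM, interaction
#' probability P >= 0.5, Tc >= 0.85, |deltaMW| < 50 g/mol, PPI confidence
#' score > 400, Bonferroni-adjusted alpha 0.05, pathway highlight at > 20
#' plants. The config is serialized into the run manifest for provenance.
#'
#' @param generator a [generator_config()] used when no dataset is given.
#' @param input_dir optional directory of input tables (see
#'   [read_dataset()]); overrides the generator.
#' @param pchembl_threshold,inhibition_threshold,potency_threshold
#'   bioactivity positivity thresholds.
#' @param probability_threshold interaction-call threshold on P.
#' @param tc_threshold,mw_window compound similarity rule.
#' @param score_threshold PPI confidence threshold.
#' @param alpha significance level for the phi network.
#' @param highlight_threshold pathway highlight rule (plants per reaction).
#' @param allowed_organisms accepted assay / PPI evidence organisms.
#' @param mds_dimensions chemical-space embedding dimension.
#' @param max_mds_compounds cap on compounds entering the MDS embedding
#'   (subsampled deterministically when exceeded).
#' @param outdir optional output directory; `NULL` keeps results in memory.
#' @param rng_seed seed forwarded to the generator.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_dir = NULL,
                            pchembl_threshold = 5.5,
                            inhibition_threshold = 20,
                            potency_threshold = 500,
                            probability_threshold = 0.5,
                            tc_threshold = 0.85,
                            mw_window = 50,
                            score_threshold = 400,
                            alpha = 0.05,
                            highlight_threshold = 20,
                            allowed_organisms = DEFAULT_ORGANISMS,
                            mds_dimensions = 2,
                            max_mds_compounds = 500,
                            outdir = NULL,
                            rng_seed = NULL) {
  if (!is.null(rng_seed)) generator$rng_seed <- rng_seed
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) generate or load inputs; (2) assemble and filter the
#' candidate target space; (3) filter, threshold and aggregate bioactivity
#' records and build the interaction table (direct + similarity routes);
#' (4) build the plant-protein matrix, efficacy table, plant projection and
#' connectivity ratio; (5) build the significant phi network with its
#' components and bridges; (6) metabolic matching and substrate
#' perturbation counts; (7) chemical-space embedding. Identical config and
#' seed give identical reports.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional pre-built [generate_dataset()] result.
#' @return list of class `pipeline_run`: all stage outputs plus `report`, a
#'   named list of per-stage record counts, and `manifest` (files written,
#'   when `outdir` is set).
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- inputs ---------------------------------------------------------------
  if (is.null(dataset)) {
    dataset <- if (!is.null(config$input_dir)) {
      stage("load", read_dataset(config$input_dir))
    } else {
      stage("generate", generate_dataset(config$generator))
    }
  }
  report$plants <- nrow(dataset$plants)
  report$compounds <- nrow(dataset$compounds)
  report$bioactivity_records_raw <- nrow(dataset$bioactivity)

  # -- target space ---------------------------------------------------------
  space <- stage("target_space", suppressWarnings(
    target_space(dataset$seeds, dataset$ppi, expression = dataset$expression,
                 allowed_organisms = config$allowed_organisms,
                 score_threshold = config$score_threshold)))
  ov <- category_overlap(space)
  report$unique_seed_proteins <- ov$unique_seed_total
  report$unique_neighbor_proteins <- ov$unique_neighbor_total

  # -- bioactivity ----------------------------------------------------------
  filtered <- stage("bioactivity", suppressMessages(
    filter_records(dataset$bioactivity, config$allowed_organisms)))
  report$bioactivity_records_kept <- nrow(filtered)
  evidence <- stage("bioactivity", aggregate_evidence(
    filtered, probability_threshold = config$probability_threshold,
    pchembl_threshold = config$pchembl_threshold,
    inhibition_threshold = config$inhibition_threshold,
    potency_threshold = config$potency_threshold))
  report$evidence_pairs <- nrow(evidence)
  report$interacting_pairs <- sum(evidence$interacting)

  interactions <- stage("interactions", build_interaction_table(
    dataset$plant_compounds, dataset$compounds, evidence, space = space,
    tc_threshold = config$tc_threshold, mw_window = config$mw_window))
  report$interaction_rows <- nrow(interactions)
  report$interaction_rows_similar <- sum(interactions$route == "similar")

  # -- interactome ----------------------------------------------------------
  m <- stage("interactome", build_matrix(interactions, dataset$plants))
  report$proteins_targeted <- sum(colSums(m$incidence) > 0)
  eff <- stage("interactome", efficacy(m))
  proj <- stage("interactome", plant_projection(m))
  report$plant_projection_edges <- nrow(proj)
  report$connectivity_ratio <- if (nrow(proj) > 0) connectivity_ratio(proj) else NA_real_

  # -- phi network ----------------------------------------------------------
  net <- stage("phi_network", build_phi_network(m, alpha = config$alpha))
  report$phi_pairs_tested <- net$m_tests
  report$phi_edges_significant <- nrow(net$edges)
  structure_info <- components_and_bridges(net)
  report$phi_components <- length(structure_info$components)

  # -- metabolic ------------------------------------------------------------
  network <- stage("metabolic", metabolic_network(dataset$reactions,
                                                  dataset$metabolites))
  matches <- stage("metabolic", match_metabolites(
    dataset$compounds, network, tc_threshold = config$tc_threshold,
    mw_window = config$mw_window))
  report$metabolite_matches_exact <- sum(matches$route == "exact")
  report$metabolite_matches_similar <- sum(matches$route == "similar")
  loads <- stage("metabolic", pathway_load(
    dataset$plant_compounds, matches, network,
    highlight_threshold = config$highlight_threshold))
  report$reactions_perturbed <- nrow(loads$reaction_load)

  # -- chemical space -------------------------------------------------------
  cmpd <- dataset$compounds
  if (nrow(cmpd) > config$max_mds_compounds) {
    cmpd <- cmpd[seq_len(config$max_mds_compounds), , drop = FALSE]
  }
  chem <- stage("chemspace", suppressWarnings(
    chemical_space(cmpd, k = config$mds_dimensions)))
  report$chemspace_points <- nrow(chem)

  run <- structure(list(
    dataset = dataset, space = space, evidence = evidence,
    interactions = interactions, matrix = m, efficacy = eff,
    projection = proj, phi_network = net, phi_structure = structure_info,
    metabolic_matches = matches, metabolic_loads = loads,
    chemspace = chem, report = report, config = config, manifest = NULL
  ), class = "pipeline_run")

  if (!is.null(config$outdir)) {
    run$manifest <- write_run(run, config$outdir)
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run report:\n")
  for (nm in names(x$report)) {
    val <- x$report[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.numeric(val)) format(val, digits = 6) else val))
  }
  invisible(x)
}

# Persist stage outputs as TSV plus a JSON sidecar of parameters.
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(df, name) {
    p <- file.path(outdir, name)
    write_table(df, p)
    files <<- c(files, name)
  }
  put(run$evidence, "evidence.tsv")
  put(run$interactions, "interactions.tsv")
  put(run$efficacy, "efficacy.tsv")
  put(run$projection, "plant_projection.tsv")
  put(run$phi_network$edges, "phi_edges.tsv")
  put(run$metabolic_loads$reaction_load, "reaction_load.tsv")
  put(run$metabolic_loads$pathway_summary, "pathway_summary.tsv")
  put(run$metabolic_loads$per_plant, "per_plant_reactions.tsv")
  put(run$chemspace, "chemspace.tsv")
  if (nrow(run$phi_network$edges) > 0) {
    write_graphml(run$phi_network$nodes,
                  run$phi_network$edges[, c("protein_a", "protein_b", "phi",
                                            "chi2", "p_adjusted")],
                  file.path(outdir, "phi_network.graphml"))
    files <- c(files, "phi_network.graphml")
  }
  cfg <- run$config
  cfg$generator <- unclass(cfg$generator)
  manifest <- list(files = files, report = run$report, config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
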