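# Metabolic-network perturbation: map compounds to network metabolites by
# exact InChIKey or fingerprint similarity, count reactions perturbed on the
# substrate side, aggregate pathway loads.

#' Construct a metabolic network from a flat reaction table
#'
#' @param reaction_table data.frame with one row per reaction-metabolite
#'   role: `reaction_id`, `metabolite_id`, `role` (`"substrate"` or
#'   `"product"`), `enzyme_id`, `pathway`.
#' @param metabolites optional data.frame (`metabolite_id`, `inchikey`,
#'   `mw`, `fingerprint`) enabling structure matching.
#' @return object of class `metabolic_network`.
#' @export
metabolic_network <- function(reaction_table, metabolites = NULL) {
  stopifnot(all(c("reaction_id", "metabolite_id", "role", "enzyme_id", "pathway") %in%
                  names(reaction_table)))
  bad_role <- !(reaction_table$role %in% c("substrate", "product"))
  if (any(bad_role)) stop("metabolic_network: role must be 'substrate' or 'product'")
  if (any(is.na(reaction_table$pathway) | reaction_table$pathway == "")) {
    stop("metabolic_network: empty pathway label")
  }
  has_sub <- tapply(reaction_table$role == "substrate", reaction_table$reaction_id, any)
  if (!all(has_sub)) {
    stop("metabolic_network: reaction(s) without substrates: ",
         paste(names(has_sub)[!has_sub], collapse = ", "))
  }
  structure(list(reaction_table = reaction_table, metabolites = metabolites),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  rt <- x$reaction_table
  cat(sprintf("metabolic_network: %d reactions, %d metabolites, %d enzymes, %d pathways\n",
              length(unique(rt$reaction_id)), length(unique(rt$metabolite_id)),
              length(unique(rt$enzyme_id)), length(unique(rt$pathway))))
  invisible(x)
}

#' Match compounds to metabolic-network metabolites
#'
#' Exact matches share the full InChIKey; similar matches follow the same
#' rule as compound matching (Tc >= `tc_threshold`, |deltaMW| <
#' `mw_window`), excluding exact matches. Compounds or metabolites without
#' structural data can only match exactly.
#'
#' @param compounds data.frame (`compound_id`, `inchikey`, optional
#'   `fingerprint`, `mw`).
#' @param network a [metabolic_network()] whose `metabolites` table carries
#'   `inchikey` (and `fingerprint`, `mw` for similarity).
#' @param tc_threshold,mw_window similarity rule parameters.
#' @param similarity also search similar matches, default TRUE.
#' @return data.frame (`compound_id`, `metabolite_id`, `route`) with route
#'   `"exact"` or `"similar"`.
#' @export
match_metabolites <- function(compounds, network, tc_threshold = 0.85,
                              mw_window = 50, similarity = TRUE) {
  stopifnot(inherits(network, "metabolic_network"))
  mets <- network$metabolites
  if (is.null(mets)) stop("match_metabolites: network has no metabolite structures")
  empty <- data.frame(compound_id = character(), metabolite_id = character(),
                      route = character(), stringsAsFactors = FALSE)

  exact <- merge(compounds[, c("compound_id", "inchikey")],
                 mets[, c("metabolite_id", "inchikey")], by = "inchikey")
  exact <- if (nrow(exact) > 0) {
    data.frame(compound_id = exact$compound_id, metabolite_id = exact$metabolite_id,
               route = "exact", stringsAsFactors = FALSE)
  } else empty

  similar <- empty
  can_sim <- similarity && all(c("fingerprint", "mw") %in% names(mets)) &&
    all(c("fingerprint", "mw") %in% names(compounds))
  if (can_sim && nrow(compounds) > 0 && nrow(mets) > 0) {
    nbits <- nchar(compounds$fingerprint[[1]])
    Q <- t(vapply(compounds$fingerprint, function(f) as.integer(as_fingerprint(f)),
                  integer(nbits), USE.NAMES = FALSE))
    R <- t(vapply(mets$fingerprint, function(f) as.integer(as_fingerprint(f)),
                  integer(nbits), USE.NAMES = FALSE))
    tc <- tanimoto_matrix(Q, R)
    dmw <- abs(outer(compounds$mw, mets$mw, `-`))
    same_key <- outer(compounds$inchikey, mets$inchikey, `==`)
    hits <- which(tc >= tc_threshold & dmw < mw_window & !same_key, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      similar <- data.frame(
        compound_id = compounds$compound_id[hits[, 1]],
        metabolite_id = mets$metabolite_id[hits[, 2]],
        route = "similar", stringsAsFactors = FALSE
      )
    }
  }
  out <- rbind(exact, similar)
  out <- out[order(out$compound_id, out$metabolite_id, out$route), , drop = FALSE]
  out <- out[!duplicated(out[, c("compound_id", "metabolite_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reactions perturbed by a set of compounds
#'
#' A reaction is perturbed only when a matched metabolite appears in its
#' substrate list; product-only occurrences never count.
#'
#' @param compound_ids the plant's compounds.
#' @param matches compound-metabolite matches from [match_metabolites()].
#' @param network a [metabolic_network()].
#' @return character vector of perturbed reaction ids, sorted.
#' @export
perturbed_reactions <- function(compound_ids, matches, network) {
  stopifnot(inherits(network, "metabolic_network"))
  mets <- unique(matches$metabolite_id[matches$compound_id %in% compound_ids])
  rt <- network$reaction_table
  hit <- rt$role == "substrate" & rt$metabolite_id %in% mets
  sort(unique(rt$reaction_id[hit]))
}

#' Per-reaction plant loads and pathway aggregation
#'
#' For every reaction, counts the distinct plants perturbing it (substrate
#' rule of [perturbed_reactions()]); a reaction is highlighted when that
#' count is strictly greater than `highlight_threshold`. Pathway summaries
#' and per-plant perturbed-reaction totals are reported alongside.
#'
#' @param plant_compounds data.frame (`plant_id`, `compound_id`).
#' @param matches compound-metabolite matches from [match_metabolites()].
#' @param network a [metabolic_network()].
#' @param highlight_threshold plant count above which a reaction is
#'   highlighted, default 20 (strict).
#' @return list: `reaction_load` (`reaction_id`, `pathway`, `n_plants`,
#'   `highlighted`), `pathway_summary` (`pathway`, `n_reactions_perturbed`,
#'   `max_plants`, `total_load`, `n_highlighted`), `per_plant`
#'   (`plant_id`, `n_reactions`).
#' @export
pathway_load <- function(plant_compounds, matches, network,
                         highlight_threshold = 20) {
  stopifnot(inherits(network, "metabolic_network"))
  rt <- network$reaction_table
  sub <- rt[rt$role == "substrate", c("reaction_id", "metabolite_id")]
  pathway_of <- unique(rt[, c("reaction_id", "pathway")])

  # plant -> metabolite (via compound matches) -> substrate reaction
  pm <- merge(plant_compounds, matches, by = "compound_id")
  pr <- unique(merge(pm[, c("plant_id", "metabolite_id")], sub,
                     by = "metabolite_id")[, c("plant_id", "reaction_id")])

  per_plant <- data.frame(
    plant_id = sort(unique(plant_compounds$plant_id)),
    stringsAsFactors = FALSE
  )
  counts <- table(pr$plant_id)
  per_plant$n_reactions <- as.integer(counts[per_plant$plant_id])
  per_plant$n_reactions[is.na(per_plant$n_reactions)] <- 0L

  rxn_counts <- table(pr$reaction_id)
  reaction_load <- data.frame(
    reaction_id = names(rxn_counts),
    n_plants = as.integer(rxn_counts),
    stringsAsFactors = FALSE
  )
  reaction_load <- merge(reaction_load, pathway_of, by = "reaction_id")
  reaction_load$highlighted <- reaction_load$n_plants > highlight_threshold
  reaction_load <- reaction_load[order(-reaction_load$n_plants, reaction_load$reaction_id), ,
                                 drop = FALSE]
  rownames(reaction_load) <- NULL

  if (nrow(reaction_load) > 0) {
    agg <- split(reaction_load, reaction_load$pathway)
    pathway_summary <- do.call(rbind, lapply(names(agg), function(p) {
      g <- agg[[p]]
      data.frame(pathway = p, n_reactions_perturbed = nrow(g),
                 max_plants = max(g$n_plants), total_load = sum(g$n_plants),
                 n_highlighted = sum(g$highlighted), stringsAsFactors = FALSE)
    }))
    pathway_summary <- pathway_summary[order(-pathway_summary$total_load,
                                             pathway_summary$pathway), , drop = FALSE]
    rownames(pathway_summary) <- NULL
  } else {
    pathway_summary <- data.frame(pathway = character(),
                                  n_reactions_perturbed = integer(),
                                  max_plants = integer(), total_load = integer(),
                                  n_highlighted = integer(), stringsAsFactors = FALSE)
  }
  list(reaction_load = reaction_load, pathway_summary = pathway_summary,
       per_plant = per_plant)
}
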