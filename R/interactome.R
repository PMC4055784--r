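# Plant-protein incidence matrices, plant efficacy scores, plant-plant
# shared-target projection and most-targeted protein rankings.

#' Construct a plant-protein matrix object
#'
#' @param incidence binary plant x protein matrix (row/col names required).
#' @param compound_counts integer matrix of the same shape: number of unique
#'   compounds of the plant interacting with the protein. Defaults to
#'   `incidence` (at most one compound per cell).
#' @param plants optional data.frame (`plant_id`, `edible`).
#' @param proteins optional data.frame (`protein_id`, `category`).
#' @return object of class `plant_protein_matrix`.
#' @export
plant_protein_matrix <- function(incidence, compound_counts = NULL,
                                 plants = NULL, proteins = NULL) {
  stopifnot(is.matrix(incidence), !is.null(rownames(incidence)),
            !is.null(colnames(incidence)))
  if (is.null(compound_counts)) compound_counts <- incidence
  stopifnot(identical(dim(incidence), dim(compound_counts)))
  if (!all((incidence == 1) == (compound_counts >= 1))) {
    stop("incidence and compound_counts disagree: incidence must be 1 exactly where counts >= 1")
  }
  if (is.null(plants)) {
    plants <- data.frame(plant_id = rownames(incidence), edible = NA,
                         stringsAsFactors = FALSE)
  }
  structure(list(incidence = incidence, compound_counts = compound_counts,
                 plants = plants, proteins = proteins),
            class = "plant_protein_matrix")
}

#' @export
print.plant_protein_matrix <- function(x, ...) {
  cat(sprintf("plant_protein_matrix: %d plants x %d proteins, %d targeted\n",
              nrow(x$incidence), ncol(x$incidence), sum(colSums(x$incidence) > 0)))
  invisible(x)
}

#' Build the plant-protein matrix from an interaction table
#'
#' @param interactions data.frame from [build_interaction_table()]
#'   (`plant_id`, `compound_id`, `protein_id`).
#' @param plants data.frame (`plant_id`, `edible`); rows define the plant
#'   universe (plants with no interactions get zero rows).
#' @param proteins optional character vector fixing the protein columns
#'   (e.g. the candidate space); defaults to the proteins present in
#'   `interactions`.
#' @return [plant_protein_matrix()] whose `compound_counts` cell (P, T) is
#'   the number of unique compounds of plant P interacting with protein T.
#' @export
build_matrix <- function(interactions, plants, proteins = NULL) {
  plant_ids <- as.character(plants$plant_id)
  if (is.null(proteins)) proteins <- sort(unique(interactions$protein_id))
  counts <- matrix(0L, length(plant_ids), length(proteins),
                   dimnames = list(plant_ids, proteins))
  if (nrow(interactions) > 0) {
    uniq <- unique(interactions[, c("plant_id", "compound_id", "protein_id")])
    uniq <- uniq[uniq$plant_id %in% plant_ids & uniq$protein_id %in% proteins, ,
                 drop = FALSE]
    tab <- table(factor(uniq$plant_id, levels = plant_ids),
                 factor(uniq$protein_id, levels = proteins))
    counts <- matrix(as.integer(tab), nrow = length(plant_ids),
                     dimnames = list(plant_ids, proteins))
  }
  plant_protein_matrix((counts >= 1L) + 0L, counts, plants = plants)
}

#' Plant efficacy against the targeted protein union
#'
#' The efficacy E of plant P is the number of candidate proteins targeted by
#' P divided by the size of the union of proteins targeted by any plant.
#' The weighted efficacy sums, over targeted proteins, the number of unique
#' compounds of the plant interacting with each protein, then scales by the
#' maximum over plants so the top plant scores 1 and relative differences
#' between plants are preserved.
#'
#' @param m a [plant_protein_matrix()].
#' @param digits rounding applied to the `efficacy_2dp` report column,
#'   default 2 (half-up).
#' @return data.frame per plant: `targeted_count`, `efficacy`,
#'   `efficacy_2dp`, `weighted_raw`, `weighted_scaled`.
#' @export
efficacy <- function(m, digits = 2) {
  stopifnot(inherits(m, "plant_protein_matrix"))
  inc <- m$incidence
  union_size <- sum(colSums(inc) > 0)
  if (union_size == 0) stop("efficacy: no plant targets any protein")
  targeted <- rowSums(inc)
  e <- targeted / union_size
  w_raw <- rowSums(m$compound_counts)
  w_scaled <- if (max(w_raw) > 0) w_raw / max(w_raw) else w_raw
  out <- data.frame(
    plant_id = rownames(inc),
    targeted_count = as.integer(targeted),
    efficacy = e,
    efficacy_2dp = round_half_up(e, digits),
    weighted_raw = w_raw,
    weighted_scaled = w_scaled,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(-out$efficacy, out$plant_id), ]
}

# round half away from zero at `digits` decimals (printed-table convention)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Plant-plant shared-target projection
#'
#' Edge weight between two plants is the number of candidate proteins both
#' target; zero-weight pairs and self-pairs are omitted.
#'
#' @param m a [plant_protein_matrix()].
#' @return data.frame (`plant_a`, `plant_b`, `weight`), `plant_a` < `plant_b`.
#' @export
plant_projection <- function(m) {
  stopifnot(inherits(m, "plant_protein_matrix"))
  inc <- m$incidence
  shared <- inc %*% t(inc)
  idx <- which(upper.tri(shared) & shared > 0, arr.ind = TRUE)
  out <- data.frame(
    plant_a = rownames(inc)[idx[, 1]],
    plant_b = rownames(inc)[idx[, 2]],
    weight = shared[idx],
    stringsAsFactors = FALSE
  )
  out[order(out$plant_a, out$plant_b), , drop = FALSE]
}

#' Mean connectivity ratio of a weighted edge set
#'
#' The sum of all edge weights divided by the number of edges, i.e. the
#' arithmetic mean edge weight of the plant-plant projection.
#'
#' @param edges data.frame with a `weight` column (see [plant_projection()]).
#' @return numeric scalar.
#' @export
connectivity_ratio <- function(edges) {
  if (nrow(edges) == 0) stop("connectivity_ratio: empty edge set")
  mean(edges$weight)
}

#' Most-targeted proteins
#'
#' Ranks proteins by the number of plants targeting them; ties break
#' lexicographically on protein id. The reported fraction divides by the
#' number of plants in scope (all plants, or edible plants only).
#'
#' @param m a [plant_protein_matrix()].
#' @param edible_only restrict to edible plants (requires `edible` flags).
#' @param k number of proteins to report; defaults to all targeted proteins.
#' @return data.frame (`protein_id`, `n_plants`, `fraction`), ranked.
#' @export
top_targeted <- function(m, edible_only = FALSE, k = Inf) {
  stopifnot(inherits(m, "plant_protein_matrix"))
  inc <- m$incidence
  if (edible_only) {
    if (all(is.na(m$plants$edible))) stop("top_targeted: no edible flags available")
    inc <- inc[m$plants$plant_id[m$plants$edible %in% TRUE], , drop = FALSE]
  }
  n <- colSums(inc)
  keep <- n > 0
  out <- data.frame(protein_id = colnames(inc)[keep], n_plants = as.integer(n[keep]),
                    fraction = n[keep] / nrow(inc), stringsAsFactors = FALSE)
  out <- out[order(-out$n_plants, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}
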