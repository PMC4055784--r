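# Candidate target space: three seed categories expanded by first-degree
# PPI neighbors above a confidence threshold, filtered by tissue expression
# and evidence organism.

#' Deduplicate an undirected scored PPI edge table
#'
#' (A,B) and (B,A) rows collapse to one undirected edge keeping the maximum
#' score. Self-edges are dropped.
#'
#' @param ppi data.frame with `protein_a`, `protein_b`, `score` and optional
#'   `organism`.
#' @return deduplicated edge table with `protein_a` <= `protein_b`.
#' @export
dedupe_ppi <- function(ppi) {
  if (nrow(ppi) == 0) return(ppi)
  ppi <- ppi[ppi$protein_a != ppi$protein_b, , drop = FALSE]
  a <- pmin(ppi$protein_a, ppi$protein_b)
  b <- pmax(ppi$protein_a, ppi$protein_b)
  ppi$protein_a <- a
  ppi$protein_b <- b
  ord <- order(a, b, -ppi$score)
  ppi <- ppi[ord, , drop = FALSE]
  ppi <- ppi[!duplicated(ppi[, c("protein_a", "protein_b")]), , drop = FALSE]
  rownames(ppi) <- NULL
  ppi
}

# Drop edges whose evidence organism is not allowed. Edges with no organism
# column or NA organism are kept with a warning.
filter_ppi_organism <- function(ppi, allowed_organisms) {
  if (is.null(allowed_organisms) || nrow(ppi) == 0) return(ppi)
  if (!("organism" %in% names(ppi))) {
    warning("PPI table has no organism column; all edges treated as allowed")
    return(ppi)
  }
  missing <- is.na(ppi$organism)
  if (any(missing)) {
    warning(sum(missing), " PPI edge(s) lack an organism label; treated as allowed")
  }
  ppi[missing | ppi$organism %in% allowed_organisms, , drop = FALSE]
}

#' First-degree neighbors of a seed set above a confidence threshold
#'
#' Returns proteins adjacent to any seed through an edge with score strictly
#' greater than `score_threshold` (the STRING medium-confidence convention,
#' score > 400). The graph is undirected; the seed set itself is excluded.
#'
#' @param seeds character vector of seed protein ids.
#' @param ppi scored PPI edge table (see [dedupe_ppi()]).
#' @param score_threshold confidence threshold, default 400 (strict).
#' @return character vector of neighbor protein ids.
#' @export
expand_neighbors <- function(seeds, ppi, score_threshold = 400) {
  if (nrow(ppi) == 0 || length(seeds) == 0) return(character())
  ppi <- dedupe_ppi(ppi)
  ppi <- ppi[ppi$score > score_threshold, , drop = FALSE]
  nb <- c(ppi$protein_b[ppi$protein_a %in% seeds],
          ppi$protein_a[ppi$protein_b %in% seeds])
  sort(setdiff(unique(nb), seeds))
}

#' Assemble the candidate target space
#'
#' For each seed category, expands first-degree neighbors over the
#' organism-filtered, deduplicated PPI graph, then removes proteins without
#' positive tissue expression from both seeds and neighbors.
#'
#' @param seeds named list of character vectors, one per category (e.g.
#'   `drug_target`, `kegg_pathway`, `prognostic_signature`).
#' @param ppi scored PPI edge table.
#' @param expression optional data.frame (`protein_id`, `positive` logical);
#'   `NULL` skips the expression filter.
#' @param allowed_organisms organisms whose PPI evidence is accepted;
#'   `NULL` skips the organism filter.
#' @param score_threshold PPI confidence threshold (strict), default 400.
#' @return object of class `target_space`: list with `seeds`, `neighbors`
#'   (per category, neighbors exclude own seeds), `ppi_edges` (retained
#'   high-confidence edges), `expression_positive`, `score_threshold`.
#' @export
target_space <- function(seeds, ppi, expression = NULL,
                         allowed_organisms = NULL, score_threshold = 400) {
  stopifnot(is.list(seeds), length(seeds) >= 1, !is.null(names(seeds)))
  ppi <- filter_ppi_organism(ppi, allowed_organisms)
  ppi <- dedupe_ppi(ppi)
  retained <- ppi[ppi$score > score_threshold, , drop = FALSE]

  neighbors <- lapply(seeds, expand_neighbors, ppi = ppi,
                      score_threshold = score_threshold)

  expression_positive <- NULL
  if (!is.null(expression)) {
    expression_positive <- expression$protein_id[as.logical(expression$positive)]
    seeds <- lapply(seeds, intersect, y = expression_positive)
    neighbors <- lapply(neighbors, intersect, y = expression_positive)
  }

  structure(
    list(seeds = seeds, neighbors = neighbors, ppi_edges = retained,
         expression_positive = expression_positive,
         score_threshold = score_threshold),
    class = "target_space"
  )
}

#' Re-apply expression and organism filters to a target space
#'
#' Rebuilds the space with the given filters: organism-disallowed edges are
#' removed before neighbor expansion, and proteins without positive
#' expression are removed from seeds and neighbors alike.
#'
#' @param space a [target_space()] object.
#' @param expression data.frame (`protein_id`, `positive`).
#' @param ppi the raw PPI table to refilter (defaults to the space's
#'   retained edges).
#' @param allowed_organisms accepted organisms for edge evidence.
#' @return filtered `target_space`.
#' @export
apply_filters <- function(space, expression = NULL, ppi = NULL,
                          allowed_organisms = NULL) {
  stopifnot(inherits(space, "target_space"))
  if (is.null(ppi)) ppi <- space$ppi_edges
  target_space(space$seeds, ppi, expression = expression,
               allowed_organisms = allowed_organisms,
               score_threshold = space$score_threshold)
}

#' @export
print.target_space <- function(x, ...) {
  cat("Candidate target space (PPI score >", x$score_threshold, ")\n")
  for (cat_name in names(x$seeds)) {
    cat(sprintf("  %s: %d seeds, %d neighbors\n", cat_name,
                length(x$seeds[[cat_name]]), length(x$neighbors[[cat_name]])))
  }
  ov <- category_overlap(x)
  cat(sprintf("  unique seeds: %d; unique neighbors: %d\n",
              ov$unique_seed_total, ov$unique_neighbor_total))
  invisible(x)
}

#' Venn-region counts of the seed categories
#'
#' @param space a [target_space()] object, or a named list of protein-id
#'   sets.
#' @return list with `regions` (named counts of each exclusive Venn region
#'   over the seed categories), `unique_seed_total` and (for a full space)
#'   `unique_neighbor_total`.
#' @export
category_overlap <- function(space) {
  if (inherits(space, "target_space")) {
    sets <- space$seeds
    neighbor_total <- length(unique(unlist(space$neighbors, use.names = FALSE)))
  } else {
    sets <- space
    neighbor_total <- NA_integer_
  }
  k <- length(sets)
  all_ids <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1L) membership <- matrix(membership, nrow = 1L)
  pattern <- apply(membership, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  regions <- table(pattern)
  out <- as.list(as.integer(regions))
  names(out) <- names(regions)
  list(regions = out,
       unique_seed_total = length(all_ids),
       unique_neighbor_total = neighbor_total)
}
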