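# Bioactivity evidence: filtering, thresholding, probability aggregation and
# compound matching by InChIKey / Tanimoto fingerprint similarity.

#' Measurement types accepted as bioactivity evidence
#'
#' Ki, IC50, EC50 and Kd are on the pChEMBL scale (-log10 molar), inhibition
#' is a percentage, potency a micromolar concentration.
#' @export
BIOACTIVITY_TYPES <- c("Ki", "IC50", "EC50", "Kd", "potency", "inhibition")

#' Default organisms whose assay evidence is accepted
#' @export
DEFAULT_ORGANISMS <- c("Homo sapiens", "Rattus norvegicus", "Mus musculus")

#' Filter raw bioactivity records
#'
#' Keeps records whose measurement type is one of [BIOACTIVITY_TYPES] and
#' whose assay organism is in `allowed_organisms`. Unknown measurement types
#' are dropped with a message (not an error). Inhibition percentages outside
#' \[0, 100\] are clamped with a warning; records with negative potency are
#' dropped.
#'
#' @param records data.frame with columns `compound_inchikey`, `protein_id`,
#'   `organism`, `type`, `value`.
#' @param allowed_organisms character vector of accepted assay organisms.
#' @return data.frame of retained records, input order preserved.
#' @export
filter_records <- function(records, allowed_organisms = DEFAULT_ORGANISMS) {
  stopifnot(is.data.frame(records))
  needed <- c("compound_inchikey", "protein_id", "organism", "type", "value")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("bioactivity records missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(records) == 0) return(records)

  unknown <- !(records$type %in% BIOACTIVITY_TYPES)
  if (any(unknown)) {
    message("Dropping ", sum(unknown), " record(s) with unknown measurement type")
  }
  keep <- !unknown & records$organism %in% allowed_organisms & is.finite(records$value)
  out <- records[keep, , drop = FALSE]

  bad_pot <- out$type == "potency" & out$value < 0
  if (any(bad_pot)) {
    message("Dropping ", sum(bad_pot), " record(s) with negative potency")
    out <- out[!bad_pot, , drop = FALSE]
  }
  inh <- out$type == "inhibition"
  oob <- inh & (out$value < 0 | out$value > 100)
  if (any(oob)) {
    warning(sum(oob), " inhibition value(s) outside [0, 100] clamped")
    out$value[oob] <- pmin(pmax(out$value[oob], 0), 100)
  }
  rownames(out) <- NULL
  out
}

#' Call a single bioactivity record positive or negative
#'
#' A record is positive evidence of interaction when: pChEMBL value > 5.5
#' (Ki, IC50, EC50, Kd); inhibition > 20 percent; potency < 500 micromolar.
#' All three comparisons are strict, so values exactly at a threshold are
#' negative.
#'
#' @param type measurement type(s), one of [BIOACTIVITY_TYPES]; vectorized.
#' @param value measurement value(s) on the scale implied by `type`.
#' @param pchembl_threshold,inhibition_threshold,potency_threshold threshold
#'   overrides; defaults 5.5, 20, 500.
#' @return logical vector.
#' @export
is_positive <- function(type, value,
                        pchembl_threshold = 5.5,
                        inhibition_threshold = 20,
                        potency_threshold = 500) {
  stopifnot(length(type) == length(value))
  pos <- rep(NA, length(type))
  pchembl <- type %in% c("Ki", "IC50", "EC50", "Kd")
  pos[pchembl] <- value[pchembl] > pchembl_threshold
  inh <- type == "inhibition"
  pos[inh] <- value[inh] > inhibition_threshold
  pot <- type == "potency"
  pos[pot] <- value[pot] < potency_threshold
  if (anyNA(pos)) stop("is_positive: unknown measurement type; run filter_records first")
  pos
}

#' Aggregate bioactivity records into per-pair interaction evidence
#'
#' Multiple measurements of the same compound on the same protein are
#' reduced to an interaction probability P = n_positive / n_total (the
#' positive-evidence frequency). A pair is called interacting when positive
#' evidence at least balances negative evidence, i.e. P >= 0.5.
#'
#' @param records filtered records (see [filter_records()]).
#' @param probability_threshold interaction call threshold on P; default 0.5,
#'   boundary inclusive.
#' @inheritParams is_positive
#' @return data.frame with one row per (compound_inchikey, protein_id):
#'   `n_positive`, `n_total`, `probability`, `interacting`.
#' @export
aggregate_evidence <- function(records, probability_threshold = 0.5,
                               pchembl_threshold = 5.5,
                               inhibition_threshold = 20,
                               potency_threshold = 500) {
  if (nrow(records) == 0) stop("aggregate_evidence: no records")
  pos <- is_positive(records$type, records$value,
                     pchembl_threshold, inhibition_threshold, potency_threshold)
  key <- paste(records$compound_inchikey, records$protein_id, sep = "\r")
  n_total <- as.vector(table(key)[unique(key)])
  n_positive <- as.vector(tapply(pos, key, sum)[unique(key)])
  parts <- strsplit(unique(key), "\r", fixed = TRUE)
  out <- data.frame(
    compound_inchikey = vapply(parts, `[[`, "", 1L),
    protein_id = vapply(parts, `[[`, "", 2L),
    n_positive = n_positive,
    n_total = n_total,
    stringsAsFactors = FALSE
  )
  out$probability <- out$n_positive / out$n_total
  out$interacting <- out$probability >= probability_threshold
  rownames(out) <- NULL
  out
}

#' Tanimoto coefficient between two fingerprint bit sets
#'
#' Tc = |A intersect B| / |A union B| over set bits. Two all-zero
#' fingerprints have Tc 0 (no evidence of similarity).
#'
#' @param a,b fingerprints: 0/1 numeric, logical vectors of equal length, or
#'   bit strings such as `"01101..."`.
#' @return Tanimoto coefficient in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- as_fingerprint(a)
  b <- as_fingerprint(b)
  if (length(a) != length(b)) {
    stop("tanimoto: fingerprint lengths differ (", length(a), " vs ", length(b), ")")
  }
  uni <- sum(a | b)
  if (uni == 0) return(0)
  sum(a & b) / uni
}

# Coerce a fingerprint to a logical vector; accepts bit strings.
as_fingerprint <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- as.integer(strsplit(x, "", fixed = TRUE)[[1]])
  }
  if (!all(x %in% c(0, 1))) stop("fingerprint must be binary")
  as.logical(x)
}

# Tanimoto of every row of Q against every row of R (0/1 matrices with the
# same number of columns). Returns |Q| x |R| matrix; all-zero vs all-zero = 0.
tanimoto_matrix <- function(Q, R) {
  stopifnot(ncol(Q) == ncol(R))
  inter <- Q %*% t(R)
  uni <- outer(rowSums(Q), rowSums(R), `+`) - inter
  tc <- ifelse(uni == 0, 0, inter / uni)
  tc
}

#' Match a query compound against a reference compound table
#'
#' Exact hits share the full 27-character InChIKey. Similar hits satisfy
#' Tc >= `tc_threshold` (inclusive) and |deltaMW| < `mw_window` (strict),
#' excluding exact hits.
#'
#' @param query list or one-row data.frame with `inchikey`, `fingerprint`
#'   (bit string or 0/1 vector; may be missing if only exact matching is
#'   needed) and `mw`.
#' @param reference data.frame with columns `compound_id`, `inchikey`,
#'   `fingerprint`, `mw`.
#' @param tc_threshold Tanimoto similarity threshold, default 0.85.
#' @param mw_window molecular-weight window in g/mol, default 50.
#' @param similarity compute similar hits (default TRUE); if TRUE the query
#'   must carry a fingerprint.
#' @return list with `exact` (reference rows with identical key) and
#'   `similar` (data.frame `query_key`, `hit_key`, `compound_id`, `tanimoto`,
#'   `delta_mw`).
#' @export
match_compound <- function(query, reference, tc_threshold = 0.85,
                           mw_window = 50, similarity = TRUE) {
  if (is.data.frame(query)) query <- as.list(query[1, ])
  exact_idx <- which(reference$inchikey == query$inchikey)
  exact <- reference[exact_idx, , drop = FALSE]

  similar <- data.frame(query_key = character(), hit_key = character(),
                        compound_id = character(), tanimoto = numeric(),
                        delta_mw = numeric(), stringsAsFactors = FALSE)
  if (similarity) {
    if (is.null(query$fingerprint)) stop("match_compound: query has no fingerprint")
    qfp <- as_fingerprint(query$fingerprint)
    cand <- setdiff(seq_len(nrow(reference)), exact_idx)
    if (length(cand) > 0) {
      dmw <- abs(reference$mw[cand] - query$mw)
      cand <- cand[dmw < mw_window]
      if (length(cand) > 0) {
        tcs <- vapply(reference$fingerprint[cand],
                      function(fp) tanimoto(qfp, fp), numeric(1), USE.NAMES = FALSE)
        hit <- tcs >= tc_threshold
        if (any(hit)) {
          idx <- cand[hit]
          similar <- data.frame(
            query_key = query$inchikey,
            hit_key = reference$inchikey[idx],
            compound_id = reference$compound_id[idx],
            tanimoto = tcs[hit],
            delta_mw = abs(reference$mw[idx] - query$mw),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  list(exact = exact, similar = similar)
}

#' Build the plant-compound-protein interaction table
#'
#' Combines two interaction routes. Direct: a plant's compound has
#' aggregated interacting evidence (P >= 0.5) on a protein. Similar: a
#' plant's compound without any bioactivity evidence of its own is
#' structurally similar (Tc >= 0.85, |deltaMW| < 50) to a compound with
#' interacting evidence, and inherits that compound's targets. When a target
#' space is supplied the direct route is restricted to seed plus neighbor
#' proteins and the similar route to seed proteins only.
#'
#' @param plant_compounds data.frame (`plant_id`, `compound_id`).
#' @param compounds compound table (`compound_id`, `inchikey`, `fingerprint`,
#'   `mw`).
#' @param evidence output of [aggregate_evidence()].
#' @param space optional [target_space()] restricting eligible proteins.
#' @param tc_threshold,mw_window similarity rule parameters.
#' @return data.frame (`plant_id`, `compound_id`, `protein_id`, `route`,
#'   `probability`) with route `"direct"` or `"similar"`.
#' @export
build_interaction_table <- function(plant_compounds, compounds, evidence,
                                    space = NULL, tc_threshold = 0.85,
                                    mw_window = 50) {
  interacting <- evidence[evidence$interacting, , drop = FALSE]
  seeds_union <- neighbors_union <- NULL
  if (!is.null(space)) {
    seeds_union <- unique(unlist(space$seeds, use.names = FALSE))
    neighbors_union <- unique(unlist(space$neighbors, use.names = FALSE))
  }

  empty <- data.frame(plant_id = character(), compound_id = character(),
                      protein_id = character(), route = character(),
                      probability = numeric(), stringsAsFactors = FALSE)
  if (nrow(interacting) == 0) return(empty)

  # direct route: compound's own key has interacting evidence
  comp <- compounds[, c("compound_id", "inchikey", "mw")]
  direct_ev <- merge(comp, interacting,
                     by.x = "inchikey", by.y = "compound_inchikey")
  if (!is.null(space)) {
    direct_ev <- direct_ev[direct_ev$protein_id %in% c(seeds_union, neighbors_union), ,
                           drop = FALSE]
  }
  direct <- merge(plant_compounds, direct_ev[, c("compound_id", "protein_id", "probability")],
                  by = "compound_id")
  if (nrow(direct) > 0) direct$route <- "direct"

  # similar route: compounds with no evidence records at all, matched to
  # evidenced compounds by fingerprint similarity
  evidenced_keys <- unique(evidence$compound_inchikey)
  orphan <- compounds[!(compounds$inchikey %in% evidenced_keys), , drop = FALSE]
  reference <- compounds[compounds$inchikey %in% unique(interacting$compound_inchikey), ,
                         drop = FALSE]
  similar <- empty
  if (nrow(orphan) > 0 && nrow(reference) > 0) {
    Q <- t(vapply(orphan$fingerprint, function(f) as.integer(as_fingerprint(f)),
                  integer(fp_length(compounds)), USE.NAMES = FALSE))
    R <- t(vapply(reference$fingerprint, function(f) as.integer(as_fingerprint(f)),
                  integer(fp_length(compounds)), USE.NAMES = FALSE))
    tc <- tanimoto_matrix(Q, R)
    dmw <- abs(outer(orphan$mw, reference$mw, `-`))
    hits <- which(tc >= tc_threshold & dmw < mw_window, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      link <- data.frame(
        compound_id = orphan$compound_id[hits[, 1]],
        hit_key = reference$inchikey[hits[, 2]],
        stringsAsFactors = FALSE
      )
      sim_ev <- interacting
      if (!is.null(space)) {
        sim_ev <- sim_ev[sim_ev$protein_id %in% seeds_union, , drop = FALSE]
      }
      inherited <- merge(link, sim_ev,
                         by.x = "hit_key", by.y = "compound_inchikey")
      similar <- merge(plant_compounds,
                       unique(inherited[, c("compound_id", "protein_id", "probability")]),
                       by = "compound_id")
      if (nrow(similar) > 0) similar$route <- "similar"
    }
  }

  cols <- c("plant_id", "compound_id", "protein_id", "route", "probability")
  out <- rbind(if (nrow(direct) > 0) direct[, cols] else NULL,
               if (nrow(similar) > 0) similar[, cols] else NULL)
  if (is.null(out) || nrow(out) == 0) return(empty)
  # a (plant, compound, protein) triple supported by both routes keeps direct
  out <- out[order(out$plant_id, out$compound_id, out$protein_id,
                   match(out$route, c("direct", "similar"))), , drop = FALSE]
  dup <- duplicated(out[, c("plant_id", "compound_id", "protein_id")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# fingerprint length used in a compound table
fp_length <- function(compounds) {
  nchar(compounds$fingerprint[[1]])
}
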