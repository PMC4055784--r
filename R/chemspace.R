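# Chemical-space embedding: 1027-column descriptor matrix (1024 fingerprint
# bits + MW, TPSA, SlogP), column standardization, Euclidean distances and
# classical multidimensional scaling.

#' Assemble the compound descriptor matrix
#'
#' Binds the unpacked fingerprint bits with the three physicochemical
#' descriptors MW, TPSA and SlogP into one numeric matrix (1027 columns for
#' 1024-bit fingerprints). Group labels (phytochemical / drug /
#' anticancer-drug / metabolite) are carried as an attribute for downstream
#' annotation; they play no role in the embedding.
#'
#' @param compounds data.frame with `compound_id`, `fingerprint` (bit
#'   string), `mw`, `tpsa`, `slogp` and optional `group`.
#' @return numeric matrix, rownames = compound ids, attribute `group`.
#' @export
descriptor_matrix <- function(compounds) {
  stopifnot(all(c("compound_id", "fingerprint", "mw", "tpsa", "slogp") %in%
                  names(compounds)))
  nbits <- nchar(compounds$fingerprint[[1]])
  fp <- t(vapply(compounds$fingerprint,
                 function(f) as.integer(as_fingerprint(f)),
                 integer(nbits), USE.NAMES = FALSE))
  m <- cbind(fp, MW = compounds$mw, TPSA = compounds$tpsa, SlogP = compounds$slogp)
  colnames(m) <- c(paste0("fp", seq_len(nbits)), "MW", "TPSA", "SlogP")
  rownames(m) <- compounds$compound_id
  if (anyNA(m)) stop("descriptor_matrix: missing values in descriptors")
  attr(m, "group") <- if ("group" %in% names(compounds)) compounds$group else NULL
  m
}

#' Standardize descriptor columns
#'
#' Each column is centered to mean 0 and scaled to sample (n - 1) standard
#' deviation 1. Constant columns (e.g. a fingerprint bit set in no
#' compound) become all zeros rather than being dropped, preserving the
#' column count.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape.
#' @export
standardize_columns <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  out <- sweep(m, 2, mu, `-`)
  scale_by <- ifelse(is.na(sd) | sd == 0, 1, sd)
  out <- sweep(out, 2, scale_by, `/`)
  out[, sd == 0 | is.na(sd)] <- 0
  attr(out, "group") <- attr(m, "group")
  out
}

#' Pairwise Euclidean distance matrix
#'
#' @param m numeric matrix (rows = compounds), typically standardized.
#' @return symmetric distance matrix with zero diagonal.
#' @export
euclidean_distances <- function(m) {
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centers -D^2/2 and eigendecomposes it, placing objects in a
#' `k`-dimensional space that preserves pairwise distances as closely as
#' possible (exactly, for configurations embeddable in `k` dimensions).
#' Negative eigenvalues (non-Euclidean distances) are truncated to zero; if
#' fewer than `k` positive eigenvalues exist the remaining coordinates are
#' zero-filled with a warning.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param k embedding dimension, default 2.
#' @return list of class `mds_embedding`: `coordinates` (n x k matrix),
#'   `eigenvalues` (non-increasing), `stress_proxy` (normalized residual
#'   distance error, 0 = perfect).
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("classical_mds: distance matrix not symmetric")
  if (any(abs(diag(d)) > 1e-8)) stop("classical_mds: nonzero diagonal")
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(d, k = min(k, n - 1), eig = TRUE))
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {
    have <- if (is.null(pts)) 0L else ncol(pts)
    warning("classical_mds: only ", have, " positive dimension(s); padding to ",
            k, " with zeros")
    pad <- matrix(0, n, k - have)
    pts <- if (have > 0) cbind(pts, pad) else pad
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("dim", seq_len(k))
  eig <- sort(pmax(fit$eig, 0), decreasing = TRUE)
  dhat <- as.matrix(stats::dist(pts))
  denom <- sum(d^2)
  stress <- if (denom > 0) sqrt(sum((dhat - d)^2) / denom) else 0
  structure(list(coordinates = pts, eigenvalues = eig, stress_proxy = stress),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("mds_embedding: %d points in %d dimensions, stress proxy %.3g\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress_proxy))
  invisible(x)
}

#' Embed a compound table into chemical space
#'
#' Convenience wrapper: descriptor matrix, joint standardization across all
#' groups, Euclidean distances, classical MDS.
#'
#' @inheritParams descriptor_matrix
#' @param k embedding dimension, default 2.
#' @return data.frame (`compound_id`, `group`, `dim1`, ..., `dimk`) with the
#'   [classical_mds()] result in attribute `embedding`.
#' @export
chemical_space <- function(compounds, k = 2) {
  m <- standardize_columns(descriptor_matrix(compounds))
  emb <- classical_mds(euclidean_distances(m), k = k)
  out <- data.frame(compound_id = rownames(emb$coordinates),
                    stringsAsFactors = FALSE)
  grp <- attr(m, "group")
  out$group <- if (is.null(grp)) NA_character_ else grp
  out <- cbind(out, as.data.frame(emb$coordinates, row.names = NULL))
  attr(out, "embedding") <- emb
  out
}
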