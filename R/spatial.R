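#' Expected cells per capture spot from manual nuclei counts
#'
#' The expected cell abundance per spatial location is estimated as the
#' arithmetic mean of nuclei counted manually in a handful of randomly
#' chosen capture spots on the matched H&E image (ten spots in practice).
#'
#' @param nuclei_counts Non-negative numeric vector of per-spot counts.
#' @return The mean, a single number.
#' @examples
#' estimate_cells_per_spot(c(5, 5, 5))  # 5
#' @export
estimate_cells_per_spot <- function(nuclei_counts) {
  if (!length(nuclei_counts)) stop("empty nuclei count list")
  stopifnot(all(nuclei_counts >= 0))
  mean(nuclei_counts)
}

#' Build reference cell-type expression signatures
#'
#' A deterministic surrogate for regression-based signature estimation:
#' each cell is library-size normalized (counts / total * `scale`) and the
#' signature of a type is the mean normalized expression over its cells.
#' Types with fewer than `min_cells` cells are flagged low-confidence.
#'
#' @param mat Tagged count matrix (genes x cells) of the reference
#'   dataset.
#' @param labels Cell-type label per cell (length = ncol); every cell must
#'   be labeled (no `NA`).
#' @param scale Library-size normalization target (default 10000).
#' @param min_cells Low-confidence threshold (default 10).
#' @return List of class `signature_matrix`: `signatures` (types x genes),
#'   `n_cells` (named counts), `low_confidence` (type names).
#' @export
build_signatures <- function(mat, labels, scale = 10000, min_cells = 10) {
  stopifnot(length(labels) == ncol(mat))
  if (anyNA(labels)) stop("unlabeled cells present")
  totals <- Matrix::colSums(mat)
  if (any(totals == 0)) stop("cells with zero counts present")
  norm <- mat %*% Matrix::Diagonal(x = scale / totals)
  types <- sort(unique(as.character(labels)))
  sig <- t(vapply(types, function(tt) {
    Matrix::rowMeans(norm[, as.character(labels) == tt, drop = FALSE])
  }, numeric(nrow(mat))))
  colnames(sig) <- rownames(mat)
  n_cells <- table(as.character(labels))[types]
  structure(list(signatures = sig,
                 n_cells = stats::setNames(as.integer(n_cells), types),
                 low_confidence = types[n_cells < min_cells]),
            class = "signature_matrix")
}

#' Deconvolve spatial spots against reference signatures (NNLS surrogate)
#'
#' A deterministic convex surrogate for Bayesian spot deconvolution:
#' per spot, the library-size-normalized count vector (restricted to genes
#' shared with the signatures, mitochondrial genes removed) is regressed
#' on the signature rows by non-negative least squares, and the
#' coefficients are rescaled so that each spot's total estimated abundance
#' equals `cells_per_spot` whenever any coefficient is nonzero. An
#' all-zero spot yields an all-zero abundance row. The returned abundances
#' are surrogate estimates — relative type composition per spot scaled to
#' the expected cell count — not posterior cell counts.
#'
#' @param spots Spot count matrix (tagged genes x spots).
#' @param signatures A `signature_matrix` from [build_signatures()] (or a
#'   plain types x genes matrix).
#' @param cells_per_spot Expected cells per location, e.g. from
#'   [estimate_cells_per_spot()]. `NULL` leaves coefficients unscaled.
#' @param drop_mito Remove mitochondrial genes before fitting
#'   (default TRUE).
#' @param scale Library-size normalization target (default 10000).
#' @return List of class `abundance_map`: `abundance` (spots x types,
#'   non-negative), `residual_norm` (per spot), `shared_genes`.
#' @export
deconvolve_spots <- function(spots, signatures, cells_per_spot = NULL,
                             drop_mito = TRUE, scale = 10000) {
  sig <- if (inherits(signatures, "signature_matrix"))
    signatures$signatures else as.matrix(signatures)
  shared <- intersect(colnames(sig), rownames(spots))
  if (drop_mito) {
    shared <- shared[!grepl("^(hg38|ss11)-MT-", shared)]
  }
  if (!length(shared)) stop("no shared genes between spots and signatures")
  a <- t(sig[, shared, drop = FALSE])           # genes x types
  n_types <- ncol(a)
  ab <- matrix(0, nrow = ncol(spots), ncol = n_types,
               dimnames = list(colnames(spots), colnames(a)))
  resid <- numeric(ncol(spots))
  sub <- as.matrix(spots[shared, , drop = FALSE])
  for (s in seq_len(ncol(spots))) {
    y <- sub[, s]
    tot <- sum(y)
    if (tot == 0) next
    y <- y / tot * scale
    fit <- pracma::lsqnonneg(a, y)
    coefs <- pmax(0, fit$x)
    if (sum(coefs) > 0 && !is.null(cells_per_spot)) {
      coefs <- coefs / sum(coefs) * cells_per_spot
    }
    ab[s, ] <- coefs
    resid[s] <- sqrt(sum((y - as.vector(a %*% fit$x))^2))
  }
  structure(list(abundance = ab, residual_norm = resid,
                 shared_genes = shared,
                 cells_per_spot = cells_per_spot),
            class = "abundance_map")
}

#' @export
print.abundance_map <- function(x, ...) {
  cat(sprintf(
    "abundance_map (NNLS surrogate): %d spots x %d types over %d shared genes\n",
    nrow(x$abundance), ncol(x$abundance), length(x$shared_genes)))
  invisible(x)
}

#' Impute cell-type presence from individual species-tagged markers
#'
#' For cell types too sparse to appear in reference signatures (human T
#' and B cells under effective depletion), presence is read directly off
#' individual species-tagged marker genes (e.g. `hg38-CD3E`, `ss11-CD19`,
#' `hg38-CD19`): per spot, the raw count of each marker and a detection
#' flag (count >= `threshold`).
#'
#' @param spots Spot count matrix (tagged genes x spots).
#' @param markers Tagged marker gene names; markers absent from the panel
#'   are reported in the `missing` attribute, not fatal.
#' @param threshold Detection threshold on the raw count (default 1).
#' @return data.frame, one row per spot: `barcode`, then per marker a
#'   count column (`count.<marker>`) and flag column
#'   (`detected.<marker>`); attribute `missing` lists absent markers.
#' @export
impute_marker_abundance <- function(spots, markers, threshold = 1) {
  present <- intersect(markers, rownames(spots))
  missing <- setdiff(markers, present)
  out <- data.frame(barcode = colnames(spots), stringsAsFactors = FALSE)
  for (m in present) {
    cnt <- as.numeric(spots[m, ])
    out[[paste0("count.", m)]] <- cnt
    out[[paste0("detected.", m)]] <- cnt >= threshold
  }
  attr(out, "missing") <- missing
  out
}
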