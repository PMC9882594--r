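#' Per-cell species evidence from a tagged count matrix
#'
#' For every barcode, sums transcripts and detected genes (count >= 1) by
#' species tag, computes the species purity (fraction of transcripts from
#' the majority species) and calls the majority species by argmax, with
#' `"tie"` on exact equality. Barcodes with zero total counts get `NA`
#' purity and majority and are flagged so summaries can exclude them.
#'
#' @param mat Tagged count matrix, genes x cells, with rownames carrying
#'   species tags (`"hg38-*"` / `"ss11-*"`).
#' @return data.frame (one row per barcode): `barcode`,
#'   `transcripts_human`, `transcripts_pig`, `genes_detected_human`,
#'   `genes_detected_pig`, `purity`, `majority_species`, `zero_total`.
#' @export
compute_species_profiles <- function(mat) {
  tags <- species_tag_of(rownames(mat))
  h <- tags == SPECIES_TAGS[["human"]]
  th <- Matrix::colSums(mat[h, , drop = FALSE])
  tp <- Matrix::colSums(mat[!h, , drop = FALSE])
  gh <- Matrix::colSums(mat[h, , drop = FALSE] > 0)
  gp <- Matrix::colSums(mat[!h, , drop = FALSE] > 0)
  total <- th + tp
  purity <- ifelse(total > 0, pmax(th, tp) / total, NA_real_)
  majority <- ifelse(total == 0, NA_character_,
                     ifelse(th > tp, "human",
                            ifelse(tp > th, "pig", "tie")))
  data.frame(
    barcode = colnames(mat),
    transcripts_human = unname(th),
    transcripts_pig = unname(tp),
    genes_detected_human = unname(gh),
    genes_detected_pig = unname(gp),
    purity = unname(purity),
    majority_species = unname(majority),
    zero_total = unname(total == 0),
    stringsAsFactors = FALSE
  )
}

#' Transcript-level and cell-level species purity summary
#'
#' `single_species_transcript_fraction` is the share of all transcripts
#' that belong to their cell's majority species (cells at an exact 50/50
#' tie contribute nothing to the numerator: a tied cell's transcripts are
#' not associated with a single species). `cells_above_purity_threshold`
#' is the fraction of cells whose purity strictly exceeds the threshold
#' (default 0.90, i.e. ">90\% of transcripts from a single species").
#' Zero-total barcodes are excluded from both.
#'
#' @param profiles Output of [compute_species_profiles()].
#' @param purity_threshold Strict purity cutoff (default 0.90).
#' @return List of class `purity_summary`: `total_transcripts`, `n_cells`,
#'   `single_species_transcript_fraction`,
#'   `cells_above_purity_threshold_fraction`, `purity_threshold`.
#' @export
summarize_purity <- function(profiles, purity_threshold = 0.90) {
  keep <- !profiles$zero_total
  if (!any(keep)) stop("no cells with nonzero counts")
  p <- profiles[keep, , drop = FALSE]
  totals <- p$transcripts_human + p$transcripts_pig
  majority_counts <- ifelse(
    p$majority_species == "tie", 0,
    pmax(p$transcripts_human, p$transcripts_pig))
  structure(list(
    total_transcripts = sum(totals),
    n_cells = nrow(p),
    single_species_transcript_fraction = sum(majority_counts) / sum(totals),
    cells_above_purity_threshold_fraction =
      mean(p$purity > purity_threshold),
    purity_threshold = purity_threshold
  ), class = "purity_summary")
}

#' @export
print.purity_summary <- function(x, ...) {
  cat(sprintf(
    paste0("purity_summary: %.1f%% of %s transcripts from %s cells",
           " associated with a single species;\n",
           "  %.1f%% of cells possessed >%g%% of transcripts from a single species\n"),
    100 * x$single_species_transcript_fraction,
    format(x$total_transcripts, big.mark = ","),
    format(x$n_cells, big.mark = ","),
    100 * x$cells_above_purity_threshold_fraction,
    100 * x$purity_threshold))
  invisible(x)
}

#' Species call from the modified-reference gene ratio
#'
#' Classifies each cell by the ratio of human to porcine detected genes
#' under the two modified species-specific references: porcine if
#' ratio < `low` (default 0.75), human if ratio > `high` (default 1.33),
#' ambiguous in between. A zero porcine denominator with human genes
#' present gives ratio `+Inf` (human); zero human genes with porcine genes
#' present gives 0 (porcine); both zero is ambiguous and flagged
#' unassignable.
#'
#' @param genes_detected_human,genes_detected_pig Integer vectors: genes
#'   with count >= 1 under the human / pig modified reference, per cell.
#' @param low,high Ratio thresholds (defaults 0.75 and 1.33).
#' @param barcode Optional barcode labels.
#' @return data.frame: `barcode`, `ratio`, `label` (`"porcine"`, `"human"`,
#'   `"ambiguous"`), `unassignable`.
#' @export
classify_by_ratio <- function(genes_detected_human, genes_detected_pig,
                              low = 0.75, high = 1.33, barcode = NULL) {
  stopifnot(length(genes_detected_human) == length(genes_detected_pig),
            low <= high)
  h <- as.numeric(genes_detected_human)
  p <- as.numeric(genes_detected_pig)
  ratio <- ifelse(p == 0, ifelse(h > 0, Inf, NaN), h / p)
  label <- ifelse(is.nan(ratio), "ambiguous",
                  ifelse(ratio < low, "porcine",
                         ifelse(ratio > high, "human", "ambiguous")))
  if (is.null(barcode)) barcode <- as.character(seq_along(h))
  data.frame(barcode = barcode, ratio = ratio, label = label,
             unassignable = h == 0 & p == 0, stringsAsFactors = FALSE)
}

#' Run the gene-ratio species classification on a matrix
#'
#' Detected-gene counts are taken per cell under each species' modified
#' reference (genes retained by the cross-mapping removal rule), then
#' passed to [classify_by_ratio()].
#'
#' @param mat Tagged count matrix (genes x cells).
#' @param modref_human,modref_pig `modified_reference` objects from
#'   [build_modified_reference()].
#' @inheritParams classify_by_ratio
#' @return As [classify_by_ratio()].
#' @export
ratio_calls <- function(mat, modref_human, modref_pig,
                        low = 0.75, high = 1.33) {
  gh <- Matrix::colSums(
    mat[intersect(rownames(mat), modref_human$retained_names), ,
        drop = FALSE] > 0)
  gp <- Matrix::colSums(
    mat[intersect(rownames(mat), modref_pig$retained_names), ,
        drop = FALSE] > 0)
  classify_by_ratio(gh, gp, low = low, high = high, barcode = colnames(mat))
}

#' Agreement between two species-call tables
#'
#' Joins the two call tables on barcode and reports the agreement fraction
#' on barcodes called unambiguously by both methods, together with the
#' full human/pig/ambiguous confusion matrix; per-cluster agreement is
#' added when cluster labels are supplied. Agreement is symmetric in the
#' two arguments.
#'
#' @param calls_a,calls_b data.frames with `barcode` and `label` columns
#'   (labels in `human`/`porcine`/`pig`/`ambiguous`/`tie`; `pig` and
#'   `porcine` are treated as the same call, `tie` as ambiguous).
#' @param clusters Optional named vector (names = barcodes) of cluster ids.
#' @return List of class `concordance_report`: `agreement` (fraction on
#'   jointly unambiguous calls), `n_compared`, `n_shared`,
#'   `confusion` (3x3 table), and optionally `per_cluster`.
#' @export
concordance <- function(calls_a, calls_b, clusters = NULL) {
  canon <- function(x) {
    x <- ifelse(x %in% c("pig", "porcine"), "porcine",
                ifelse(x == "human", "human", "ambiguous"))
    factor(x, levels = c("human", "porcine", "ambiguous"))
  }
  shared <- intersect(calls_a$barcode, calls_b$barcode)
  if (!length(shared)) stop("no shared barcodes between call tables")
  a <- canon(calls_a$label[match(shared, calls_a$barcode)])
  b <- canon(calls_b$label[match(shared, calls_b$barcode)])
  confusion <- table(method_a = a, method_b = b)
  ok <- a != "ambiguous" & b != "ambiguous"
  agreement <- if (any(ok)) mean(a[ok] == b[ok]) else NA_real_
  out <- list(agreement = agreement, n_compared = sum(ok),
              n_shared = length(shared), confusion = confusion)
  if (!is.null(clusters)) {
    cl <- clusters[shared]
    per <- vapply(split(seq_along(shared), cl), function(idx) {
      okx <- ok[idx]
      if (any(okx)) mean(a[idx][okx] == b[idx][okx]) else NA_real_
    }, numeric(1))
    out$per_cluster <- per
  }
  structure(out, class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "concordance: %.1f%% agreement on %d jointly unambiguous barcodes (of %d shared)\n",
    100 * x$agreement, x$n_compared, x$n_shared))
  print(x$confusion)
  invisible(x)
}

#' Per-cluster cross-mapping diagnostics
#'
#' For each cluster with an assigned species, reports the fraction of its
#' transcripts carried by opposite-species genes and ranks those
#' "offending" genes by descending count with the cumulative fraction of
#' opposite-species signal they explain. Two gene-inclusion summaries are
#' returned: all opposite-species genes with nonzero counts
#' (`panel_fraction`), and the minimal top set explaining
#' `cum_cutoff` of the opposite-species counts (`top_genes`,
#' `top_panel_fraction`).
#'
#' @param mat Tagged count matrix (genes x cells).
#' @param cluster_labels Vector (length = ncol) of cluster ids.
#' @param cluster_species Named vector mapping cluster id to `"human"` or
#'   `"pig"`; clusters missing from it are skipped with a warning.
#' @param cum_cutoff Cumulative-fraction cutoff for the top-gene summary
#'   (default 0.9).
#' @return Named list (one entry per reported cluster) of class
#'   `crossmap_report`; each entry has `cluster_id`, `assigned_species`,
#'   `opposite_fraction`, `offending_genes` (data.frame `gene`, `count`,
#'   `cumulative_fraction`), `panel_fraction`, `top_genes`,
#'   `top_panel_fraction`, `opposite_panel_size`.
#' @export
cluster_crossmap_report <- function(mat, cluster_labels, cluster_species,
                                    cum_cutoff = 0.9) {
  stopifnot(length(cluster_labels) == ncol(mat))
  tags <- species_tag_of(rownames(mat))
  out <- list()
  for (cl in unique(as.character(cluster_labels))) {
    sp <- if (cl %in% names(cluster_species)) cluster_species[[cl]]
          else NA_character_
    if (is.null(sp) || is.na(sp)) {
      warning("cluster ", cl, " has no assigned species: skipped")
      next
    }
    own_tag <- SPECIES_TAGS[[sp]]
    opp <- tags != own_tag
    sub <- mat[, as.character(cluster_labels) == cl, drop = FALSE]
    totals <- Matrix::rowSums(sub)
    total_all <- sum(totals)
    opp_counts <- totals[opp]
    opp_total <- sum(opp_counts)
    nz <- sort(opp_counts[opp_counts > 0], decreasing = TRUE)
    genes <- data.frame(
      gene = names(nz), count = unname(nz),
      cumulative_fraction = if (length(nz)) cumsum(nz) / opp_total
                            else numeric(0),
      stringsAsFactors = FALSE
    )
    n_top <- if (nrow(genes)) which(genes$cumulative_fraction >=
                                      cum_cutoff)[1L] else 0L
    out[[cl]] <- list(
      cluster_id = cl,
      assigned_species = sp,
      opposite_fraction = if (total_all > 0) opp_total / total_all else 0,
      offending_genes = genes,
      panel_fraction = nrow(genes) / sum(opp),
      top_genes = utils::head(genes$gene, n_top),
      top_panel_fraction = n_top / sum(opp),
      opposite_panel_size = sum(opp)
    )
  }
  structure(out, class = "crossmap_report")
}

#' @export
print.crossmap_report <- function(x, ...) {
  for (cl in x) {
    cat(sprintf(
      "cluster %s [%s]: %.2f%% of counts on %d opposite-species genes (%.2f%% of panel)\n",
      cl$cluster_id, cl$assigned_species, 100 * cl$opposite_fraction,
      nrow(cl$offending_genes), 100 * cl$panel_fraction))
  }
  invisible(x)
}
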