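#' Default M1/M2 macrophage polarization gene sets
#'
#' Canonical pro-inflammatory (M1) and anti-inflammatory (M2) macrophage
#' markers from the polarization literature, returned untagged; prepend a
#' species tag with [tag_gene_set()] before scoring one species'
#' macrophages. The lists are configurable — any two-column
#' (set name, gene) table read by [read_gene_sets()] can replace them.
#'
#' @return Named list of two character vectors, `M1` and `M2`.
#' @export
default_polarization_sets <- function() {
  list(
    M1 = c("IL1B", "TNF", "IL6", "CXCL9", "CXCL10", "CXCL11", "NOS2",
           "CD80", "CD86", "FCGR1A", "SOCS3", "IL12B"),
    M2 = c("MRC1", "CD163", "MSR1", "IL10", "CCL22", "TGFB1", "ARG1",
           "CD209", "STAB1", "MAF", "MERTK", "F13A1")
  )
}

#' Tag a gene set with a species prefix
#'
#' @param genes Character vector of untagged symbols.
#' @param species `"human"` or `"pig"` (or a raw tag `"hg38"`/`"ss11"`).
#' @return Tagged names `"<tag>-<symbol>"`.
#' @export
tag_gene_set <- function(genes, species) {
  tag <- if (species %in% names(SPECIES_TAGS)) SPECIES_TAGS[[species]]
         else match.arg(species, unname(SPECIES_TAGS))
  paste0(tag, "-", genes)
}

#' Read gene sets from a two-column text file
#'
#' @param path Whitespace- or tab-separated file with columns
#'   `set_name`, `gene` (no header required).
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names =
                             c("set_name", "gene"),
                           stringsAsFactors = FALSE)
  split(tab$gene, tab$set_name)
}

#' Module score with expression-bin-matched control genes
#'
#' Scores each cell for a gene set against the background of control genes
#' drawn from the same average-expression strata: all genes are binned
#' into `n_bins` equal-frequency bins by their mean normalized expression
#' across cells; for each set gene, `n_ctrl` control genes are sampled
#' (with replacement) from its bin; the score is the mean expression of
#' the set genes minus the mean expression of the pooled control draws,
#' per cell. A set whose genes all track their bins' average therefore
#' scores ~0, and adding a constant to every gene of every cell leaves the
#' score unchanged.
#'
#' @param norm Normalized matrix (genes x cells).
#' @param genes Tagged gene names of the set; genes absent from the matrix
#'   are dropped (error if none remain, naming the missing genes).
#' @param n_bins Expression bins (default 24).
#' @param n_ctrl Control genes sampled per set gene (default 100).
#' @param seed Integer seed for the control draws.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(norm, genes, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  present <- intersect(genes, rownames(norm))
  if (!length(present)) {
    stop("no gene of the set is present in the matrix; missing: ",
         paste(genes, collapse = ", "))
  }
  avg <- Matrix::rowMeans(norm)
  n_bins_eff <- min(n_bins, length(avg))
  # equal-frequency strata of the data-average, random-free tie handling
  bin <- cut(rank(avg, ties.method = "first"),
             breaks = n_bins_eff, labels = FALSE, include.lowest = TRUE)
  names(bin) <- rownames(norm)
  set.seed(seed)
  ctrl <- character(0)
  for (g in present) {
    pool <- names(bin)[bin == bin[[g]]]
    ctrl <- c(ctrl, sample(pool, n_ctrl, replace = TRUE))
  }
  set_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  # control mean over draws (duplicates weighted as drawn)
  ctrl_tab <- table(ctrl)
  w <- as.numeric(ctrl_tab) / length(ctrl)
  ctrl_mean <- as.numeric(
    w %*% as.matrix(norm[names(ctrl_tab), , drop = FALSE]))
  score <- set_mean - ctrl_mean
  names(score) <- colnames(norm)
  score
}

#' Score M1 and M2 polarization per cell
#'
#' Runs [module_score()] for both gene sets, species-stratified: each
#' species' cells are scored against its own tagged gene lists (the two
#' species' gene spaces are disjoint under the hybrid namespace, so scores
#' are computed per species and concatenated).
#'
#' @param norm Normalized matrix (genes x cells).
#' @param species Named character vector (names = barcodes, values
#'   `"human"`/`"pig"`) restricting each cell to its species' lists; if
#'   `NULL` the untagged sets are matched against the full matrix as-is.
#' @param sets Named list with `M1` and `M2` untagged gene vectors
#'   (default [default_polarization_sets()]).
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return data.frame: `barcode`, `score_m1`, `score_m2`.
#' @export
polarization_scores <- function(norm, species = NULL,
                                sets = default_polarization_sets(),
                                n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(all(c("M1", "M2") %in% names(sets)))
  if (is.null(species)) {
    m1 <- module_score(norm, sets$M1, n_bins, n_ctrl, seed)
    m2 <- module_score(norm, sets$M2, n_bins, n_ctrl, seed + 1L)
    return(data.frame(barcode = colnames(norm), score_m1 = unname(m1),
                      score_m2 = unname(m2), stringsAsFactors = FALSE))
  }
  out <- NULL
  for (sp in unique(species)) {
    cells <- names(species)[species == sp]
    cells <- intersect(cells, colnames(norm))
    if (!length(cells)) next
    sub <- norm[, cells, drop = FALSE]
    # restrict to the species' own gene space so bins are species-matched
    own <- species_tag_of(rownames(sub)) == SPECIES_TAGS[[sp]]
    sub <- sub[own, , drop = FALSE]
    m1 <- module_score(sub, tag_gene_set(sets$M1, sp), n_bins, n_ctrl,
                       seed)
    m2 <- module_score(sub, tag_gene_set(sets$M2, sp), n_bins, n_ctrl,
                       seed + 1L)
    out <- rbind(out, data.frame(barcode = cells, species = sp,
                                 score_m1 = unname(m1),
                                 score_m2 = unname(m2),
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) stop("no cells matched the species vector")
  out
}

#' Compare M2 vs M1 polarization between groups
#'
#' Per group: mean M1 and M2 scores, the fraction of cells with
#' `score_m2 > score_m1`, and a Wilcoxon signed-rank test of the per-cell
#' M2 - M1 difference against zero.
#'
#' @param scores data.frame with `score_m1`, `score_m2` (e.g. from
#'   [polarization_scores()]).
#' @param groups Vector of group labels (length = nrow(scores)), e.g.
#'   species.
#' @return data.frame, one row per group: `group`, `n`, `mean_m1`,
#'   `mean_m2`, `fraction_m2_gt_m1`, `p_value`.
#' @export
compare_polarization <- function(scores, groups) {
  stopifnot(length(groups) == nrow(scores))
  out <- NULL
  for (g in unique(groups)) {
    sel <- groups == g
    if (!any(sel)) stop("empty group: ", g)
    d <- scores$score_m2[sel] - scores$score_m1[sel]
    p <- if (all(d == 0)) 1 else
      suppressWarnings(stats::wilcox.test(d, mu = 0)$p.value)
    out <- rbind(out, data.frame(
      group = g, n = sum(sel),
      mean_m1 = mean(scores$score_m1[sel]),
      mean_m2 = mean(scores$score_m2[sel]),
      fraction_m2_gt_m1 = mean(d > 0),
      p_value = p, stringsAsFactors = FALSE))
  }
  out
}
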