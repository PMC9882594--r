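#' QC thresholds for droplet filtering
#'
#' The scRNA-seq defaults drop cells with fewer than 200 or more than 3000
#' unique features, more than 12\% mitochondrial expression, or a doublet
#' score above 0.3, then drop genes expressed in fewer than 5 retained
#' cells. All comparisons are strict, so a cell at exactly 12\%
#' mitochondrial expression or a doublet score of exactly 0.3 is retained.
#' The `"snrna"` profile uses the single-nucleus variant (feature cap 2500,
#' mitochondrial cap 15\%).
#'
#' @param min_features,max_features Unique-feature bounds.
#' @param max_mito_fraction Mitochondrial expression cap.
#' @param min_cells_per_gene Gene-level floor on expressing cells.
#' @param max_doublet_score Doublet-score cap.
#' @param profile `"scrna"` (default) or `"snrna"`.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features = 200, max_features = 3000,
                          max_mito_fraction = 0.12,
                          min_cells_per_gene = 5,
                          max_doublet_score = 0.3,
                          profile = c("scrna", "snrna")) {
  profile <- match.arg(profile)
  if (profile == "snrna") {
    if (missing(max_features)) max_features <- 2500
    if (missing(max_mito_fraction)) max_mito_fraction <- 0.15
  }
  stopifnot(min_features < max_features,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_features = min_features, max_features = max_features,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene,
                 max_doublet_score = max_doublet_score, profile = profile),
            class = "qc_thresholds")
}

#' Filter cells and genes by standard droplet QC rules
#'
#' Cells are removed iff (strictly) features < `min_features`,
#' features > `max_features`, mitochondrial fraction > `max_mito_fraction`,
#' or doublet score > `max_doublet_score`; genes expressed in fewer than
#' `min_cells_per_gene` retained cells are then removed. The report lists
#' every removed barcode with its (first matching) reason and satisfies
#' removed + retained = input.
#'
#' @param mat Tagged count matrix (genes x cells).
#' @param doublet_scores Numeric vector (length = ncol) or data.frame with
#'   `barcode` and `doublet_score`; `NULL` disables the doublet rule.
#' @param thresholds A [qc_thresholds()].
#' @param is_mito Logical vector over rows flagging mitochondrial genes;
#'   defaults to symbols starting `MT-` after the species tag.
#' @return List of class `qc_result`: `matrix` (filtered), `report`
#'   (data.frame `barcode`, `reason`), `n_input_cells`, `n_retained_cells`,
#'   `genes_removed`, `thresholds`, and per-cell `stats` (features, mito
#'   fraction) for the retained cells.
#' @export
qc_filter <- function(mat, doublet_scores = NULL,
                      thresholds = qc_thresholds(), is_mito = NULL) {
  if (is.null(is_mito)) {
    is_mito <- grepl("^(hg38|ss11)-MT-", rownames(mat))
  }
  stopifnot(length(is_mito) == nrow(mat))
  if (is.data.frame(doublet_scores)) {
    doublet_scores <- doublet_scores$doublet_score[
      match(colnames(mat), doublet_scores$barcode)]
  }
  feats <- Matrix::colSums(mat > 0)
  totals <- Matrix::colSums(mat)
  mito_frac <- ifelse(totals > 0,
                      Matrix::colSums(mat[is_mito, , drop = FALSE]) /
                        pmax(totals, 1), 0)
  reason <- rep(NA_character_, ncol(mat))
  reason[is.na(reason) & feats < thresholds$min_features] <- "min_features"
  reason[is.na(reason) & feats > thresholds$max_features] <- "max_features"
  reason[is.na(reason) & mito_frac > thresholds$max_mito_fraction] <-
    "mito_fraction"
  if (!is.null(doublet_scores)) {
    reason[is.na(reason) &
             doublet_scores > thresholds$max_doublet_score] <- "doublet"
  }
  keep <- is.na(reason)
  if (!any(keep)) stop("QC removed all cells; see report")
  filtered <- mat[, keep, drop = FALSE]
  cells_per_gene <- Matrix::rowSums(filtered > 0)
  gene_keep <- cells_per_gene >= thresholds$min_cells_per_gene
  report <- data.frame(barcode = colnames(mat)[!keep],
                       reason = reason[!keep], stringsAsFactors = FALSE)
  structure(list(
    matrix = filtered[gene_keep, , drop = FALSE],
    report = report,
    n_input_cells = ncol(mat),
    n_retained_cells = sum(keep),
    genes_removed = rownames(filtered)[!gene_keep],
    stats = data.frame(barcode = colnames(filtered),
                       n_features = unname(feats[keep]),
                       mito_fraction = unname(mito_frac[keep]),
                       stringsAsFactors = FALSE),
    thresholds = thresholds
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "qc_result: %d/%d cells retained (%d removed), %d genes removed (< %d cells)\n",
    x$n_retained_cells, x$n_input_cells, nrow(x$report),
    length(x$genes_removed), x$thresholds$min_cells_per_gene))
  if (nrow(x$report)) print(table(x$report$reason))
  invisible(x)
}

#' Library-size normalization with log1p transform
#'
#' Per cell: `log(1 + scale * count / cell_total)` with the conventional
#' scale factor 10,000. Zero counts map exactly to zero and the sparsity
#' pattern is preserved. A cell with zero total counts is an error (it
#' should have been removed by QC).
#'
#' @param mat Count matrix (genes x cells), non-negative.
#' @param scale Scale factor (default 10000).
#' @return `dgCMatrix` of normalized values.
#' @export
normalize_log1p <- function(mat, scale = 10000) {
  totals <- Matrix::colSums(mat)
  if (any(totals == 0)) {
    stop("cells with zero total counts: ",
         paste(utils::head(colnames(mat)[totals == 0], 5), collapse = ", "))
  }
  m <- methods::as(methods::as(mat, "generalMatrix"), "CsparseMatrix")
  # column of each nonzero entry, from the CSC pointer vector
  j <- rep.int(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(scale * m@x / totals[j])
  m
}

#' Select highly variable genes by coefficient of variation
#'
#' Ranks genes by the coefficient of variation (sd/mean) of their
#' normalized expression across cells, descending, and returns the top
#' `n` (default 3000). Genes with zero mean have undefined CV and sort
#' last; ties break deterministically by gene name.
#'
#' @param norm Normalized matrix (genes x cells), e.g. from
#'   [normalize_log1p()].
#' @param n Number of genes to return (default 3000); if fewer genes are
#'   available all are returned with a warning.
#' @return Character vector of gene names, ranked.
#' @export
select_hvg <- function(norm, n = 3000) {
  mu <- Matrix::rowMeans(norm)
  # E[x^2] via the sparse entries; sd with the n-1 denominator
  ex2 <- Matrix::rowSums(norm^2) / ncol(norm)
  v <- (ex2 - mu^2) * ncol(norm) / max(1, ncol(norm) - 1)
  v[v < 0] <- 0
  cv <- ifelse(mu > 0, sqrt(v) / mu, -Inf)
  ord <- order(-cv, rownames(norm))
  if (nrow(norm) < n) {
    warning("only ", nrow(norm), " genes available (requested ", n, ")")
    n <- nrow(norm)
  }
  rownames(norm)[ord][seq_len(n)]
}

#' PCA embedding and shared-nearest-neighbor graph clustering
#'
#' Centers and scales the selected variable genes (values clipped at
#' +/- `clip`), computes `n_components` principal components across cells,
#' builds a k-nearest-neighbor graph in PC space, weights edges by the
#' Jaccard overlap of neighbor sets (shared nearest neighbors) and
#' partitions the graph by modularity optimization (Louvain). Labels are
#' deterministic given `seed`.
#'
#' @param norm Normalized matrix (genes x cells).
#' @param hvg Character vector of variable genes (nonempty).
#' @param n_components Principal components to keep (default 30; reduced
#'   with a warning when the data are smaller).
#' @param k_neighbors Neighbors for the KNN graph (default 20).
#' @param resolution Louvain resolution (default 0.8).
#' @param clip Absolute cap applied to scaled values (default 10).
#' @param prune Minimum SNN Jaccard weight for an edge to survive
#'   (default 1/15, the common single-cell toolchain default).
#' @param seed Integer seed for the community search.
#' @return List of class `census_embedding`: `embedding` (cells x PCs),
#'   `clusters` (named factor), `snn` (igraph), parameters.
#' @export
embed_and_cluster <- function(norm, hvg, n_components = 30,
                              k_neighbors = 20, resolution = 0.8,
                              clip = 10, prune = 1 / 15, seed = 1L) {
  stopifnot(length(hvg) > 0)
  hvg <- intersect(hvg, rownames(norm))
  x <- t(as.matrix(norm[hvg, , drop = FALSE]))   # cells x genes
  x <- scale(x)
  x[is.na(x)] <- 0                                # zero-variance genes
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  max_pc <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_pc) {
    warning("reducing n_components to ", max_pc)
    n_components <- max_pc
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE,
                      rank. = n_components)
  emb <- pc$x
  n <- nrow(emb)
  k <- min(k_neighbors, n - 1L)
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
  # SNN: Jaccard overlap of neighbor sets (self included, as is standard)
  inc <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k + 1L),
    j = as.integer(t(cbind(seq_len(n), nn))),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(inc)
  jac <- as.matrix(shared) / (2 * (k + 1L) - as.matrix(shared))
  diag(jac) <- 0
  jac[jac < prune] <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  clusters <- factor(igraph::membership(comm))
  names(clusters) <- colnames(norm)
  rownames(emb) <- colnames(norm)
  structure(list(embedding = emb, clusters = clusters, snn = g,
                 n_components = n_components, k_neighbors = k,
                 resolution = resolution, seed = seed),
            class = "census_embedding")
}

# Vectorized one-vs-rest Wilcoxon rank-sum (normal approximation with tie
# correction and continuity correction, matching wilcox.test(correct=TRUE)).
.ranksum_vs_rest <- function(xmat, in_group) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  apply_gene <- function(x) {
    r <- rank(x)
    w <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- table(x)
    tie_term <- sum(ties^3 - ties)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - tie_term / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) return(1)
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  }
  apply(xmat, 1L, apply_gene)
}

#' One-vs-rest Wilcoxon marker genes per cluster
#'
#' For every cluster with at least `min_cells` members, tests each gene's
#' normalized expression in the cluster against all other cells with the
#' Wilcoxon rank-sum test (normal approximation with tie and continuity
#' corrections), adjusts p-values by Benjamini-Hochberg within the
#' cluster, and reports the log fold-change
#' `log((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`. Tables are
#' sorted by adjusted p, then by decreasing effect size.
#'
#' @param norm Normalized matrix (genes x cells).
#' @param clusters Factor/vector of cluster labels (length = ncol).
#' @param min_cells Minimum cluster size to test (default 2); smaller
#'   clusters are skipped with a warning.
#' @return Named list (per cluster) of data.frames: `gene`, `p_value`,
#'   `p_adj`, `log_fc`, `pct_in`, `pct_out`.
#' @export
find_markers <- function(norm, clusters, min_cells = 2L) {
  clusters <- as.factor(clusters)
  if (nlevels(droplevels(clusters)) < 2L) {
    stop("need at least 2 clusters")
  }
  x <- as.matrix(norm)
  out <- list()
  for (cl in levels(droplevels(clusters))) {
    in_group <- clusters == cl
    if (sum(in_group) < min_cells) {
      warning("cluster ", cl, " has fewer than ", min_cells,
              " cells: skipped")
      next
    }
    p <- .ranksum_vs_rest(x, in_group)
    mean_in <- rowMeans(expm1(x[, in_group, drop = FALSE]))
    mean_out <- rowMeans(expm1(x[, !in_group, drop = FALSE]))
    tab <- data.frame(
      gene = rownames(x),
      p_value = unname(p),
      p_adj = stats::p.adjust(p, method = "BH"),
      log_fc = log((mean_in + 1) / (mean_out + 1)),
      pct_in = rowMeans(x[, in_group, drop = FALSE] > 0),
      pct_out = rowMeans(x[, !in_group, drop = FALSE] > 0),
      stringsAsFactors = FALSE
    )
    tab <- tab[order(tab$p_adj, -tab$log_fc), , drop = FALSE]
    rownames(tab) <- NULL
    out[[cl]] <- tab
  }
  out
}

#' Run the full census on a count matrix
#'
#' Convenience wrapper chaining [qc_filter()], [normalize_log1p()],
#' [select_hvg()], [embed_and_cluster()] and [find_markers()] with the
#' standard parameters.
#'
#' @param mat Tagged count matrix (genes x cells).
#' @param doublet_scores Passed to [qc_filter()].
#' @param thresholds A [qc_thresholds()].
#' @param n_hvg,n_components,k_neighbors,resolution,seed Stage parameters.
#' @param markers Whether to compute marker tables (default TRUE).
#' @return List of class `census_result`: `qc`, `normalized`, `hvg`,
#'   `embedding`, `clusters`, `markers`.
#' @export
run_census <- function(mat, doublet_scores = NULL,
                       thresholds = qc_thresholds(), n_hvg = 3000,
                       n_components = 30, k_neighbors = 20,
                       resolution = 0.8, seed = 1L, markers = TRUE) {
  qc <- qc_filter(mat, doublet_scores, thresholds)
  norm <- normalize_log1p(qc$matrix)
  hvg <- suppressWarnings(select_hvg(norm, n_hvg))
  emb <- embed_and_cluster(norm, hvg, n_components = n_components,
                           k_neighbors = k_neighbors,
                           resolution = resolution, seed = seed)
  mk <- if (isTRUE(markers) &&
            nlevels(droplevels(emb$clusters)) >= 2L) {
    suppressWarnings(find_markers(norm, emb$clusters))
  } else NULL
  structure(list(qc = qc, normalized = norm, hvg = hvg, embedding = emb,
                 clusters = emb$clusters, markers = mk),
            class = "census_result")
}
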