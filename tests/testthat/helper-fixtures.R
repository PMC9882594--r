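# Shared fixtures: tiny generator configs, hand-built matrices and
# independent dense oracles used across the suite.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes_per_species = 150, n_cells = 200, seed = 42L)
  do.call(generator_config, utils::modifyList(defaults, args))
}

# a small tagged matrix built by hand: genes x cells with dimnames
tagged_matrix <- function(counts, genes, barcodes = NULL) {
  m <- matrix(counts, nrow = length(genes))
  if (is.null(barcodes)) barcodes <- paste0("c", seq_len(ncol(m)))
  dimnames(m) <- list(genes, barcodes)
  methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                          "generalMatrix"), "CsparseMatrix")
}

# adjusted Rand index between two labelings (contingency-table form)
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# dense brute-force species profile oracle
dense_profile_oracle <- function(mat) {
  d <- as.matrix(mat)
  tags <- sub("-.*$", "", rownames(d))
  t(vapply(seq_len(ncol(d)), function(j) {
    h <- d[tags == "hg38", j]; p <- d[tags == "ss11", j]
    c(th = sum(h), tp = sum(p), gh = sum(h > 0), gp = sum(p > 0))
  }, numeric(4)))
}

# exhaustive active-set non-negative least squares for few types:
# tries every subset of columns with an unconstrained solve and keeps the
# best feasible (all-non-negative) solution
nnls_oracle <- function(a, y) {
  k <- ncol(a)
  best <- rep(0, k)
  best_rss <- sum(y^2)
  for (bits in seq_len(2^k - 1)) {
    idx <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
    coefs <- tryCatch(
      qr.solve(a[, idx, drop = FALSE], y),
      error = function(e) NULL)
    if (is.null(coefs) || any(coefs < -1e-10)) next
    coefs <- pmax(0, coefs)
    rss <- sum((y - a[, idx, drop = FALSE] %*% coefs)^2)
    if (rss < best_rss - 1e-10) {
      best_rss <- rss
      best <- rep(0, k)
      best[idx] <- coefs
    }
  }
  best
}
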