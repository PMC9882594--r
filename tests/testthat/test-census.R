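qc_toy <- function() {
  # 6 genes (1 mito) x 5 cells engineered around the QC boundaries
  genes <- c("hg38-MT-1", paste0("hg38-G", 1:5))
  counts <- cbind(
    c(0, 5, 5, 5, 5, 0),      # 4 features, below the floor of 5
    c(12, 22, 22, 22, 22, 0), # exactly 12% mito, 5 features
    c(50, 10, 10, 10, 10, 10),# 50% mito
    c(0, 8, 8, 8, 8, 8),      # clean
    c(0, 9, 9, 9, 9, 9)       # clean but doublet-scored
  )
  tagged_matrix(counts, genes, c("few", "mito_at_cap", "mito_high",
                                 "clean", "doublet"))
}

test_that("QC removes cells by each rule with strict boundaries", {
  m <- qc_toy()
  thr <- qc_thresholds(min_features = 5, max_features = 100,
                       min_cells_per_gene = 1)
  scores <- c(few = 0, mito_at_cap = 0.1, mito_high = 0,
              clean = 0.3, doublet = 0.31)
  qc <- qc_filter(m, scores, thr)
  expect_setequal(colnames(qc$matrix), c("mito_at_cap", "clean"))
  reasons <- setNames(qc$report$reason, qc$report$barcode)
  expect_identical(reasons[["few"]], "min_features")     # 4 < 5
  expect_identical(reasons[["mito_high"]], "mito_fraction")
  expect_identical(reasons[["doublet"]], "doublet")      # 0.31 > 0.3
  # exactly 12% mito and score exactly 0.3 both survive (strict rules)
  expect_true("mito_at_cap" %in% colnames(qc$matrix))
  expect_true("clean" %in% colnames(qc$matrix))
})

test_that("a cell with 150 features is removed at the default 200 floor", {
  genes <- paste0("hg38-G", 1:300)
  dense <- matrix(0, 300, 2, dimnames = list(genes, c("sparse", "rich")))
  dense[1:150, 1] <- 1
  dense[1:250, 2] <- 2
  m <- tagged_matrix(dense, genes, c("sparse", "rich"))
  qc <- qc_filter(m, NULL, qc_thresholds(min_cells_per_gene = 1))
  expect_identical(qc$report$barcode, "sparse")
  expect_identical(qc$report$reason, "min_features")
})

test_that("QC conserves cells and removes rarely expressed genes", {
  sim <- generate_barnyard(tiny_config())
  qc <- qc_filter(sim$matrix, sim$truth$doublet_score)
  expect_equal(nrow(qc$report) + qc$n_retained_cells, qc$n_input_cells)
  # every surviving gene is expressed in >= 5 retained cells
  expect_true(all(Matrix::rowSums(qc$matrix > 0) >= 5))
  # all-passing matrix is untouched
  clean <- tagged_matrix(matrix(5, 300, 8,
                                dimnames = list(paste0("hg38-G", 1:300),
                                                paste0("c", 1:8))),
                         paste0("hg38-G", 1:300))
  qc2 <- qc_filter(clean, rep(0, 8), qc_thresholds())
  expect_identical(dim(qc2$matrix), dim(clean))
  expect_equal(nrow(qc2$report), 0)
})

test_that("log-normalization has the closed form and its invariances", {
  genes <- c("hg38-A", "hg38-B")
  m <- tagged_matrix(c(10, 0, 3, 6), genes, c("single", "pair"))
  norm <- normalize_log1p(m)
  # one expressed gene, count 10 of total 10 -> log(1 + 10000)
  expect_equal(norm["hg38-A", "single"], log(1 + 10000),
               tolerance = 1e-12)
  expect_equal(norm["hg38-B", "single"], 0)   # zero entries stay zero
  # doubling a cell's counts leaves its normalized vector unchanged
  doubled <- normalize_log1p(tagged_matrix(c(6, 12), genes, "pair2"))
  expect_equal(as.numeric(doubled), as.numeric(norm[, "pair"]))
  # within-cell rank order of counts is preserved
  sim <- generate_barnyard(tiny_config(n_cells = 50))
  keep <- Matrix::colSums(sim$matrix) > 0
  n2 <- normalize_log1p(sim$matrix[, keep])
  j <- 1
  expect_equal(order(as.numeric(n2[, j])), order(as.numeric(sim$matrix[, keep][, j])))
  expect_error(normalize_log1p(tagged_matrix(c(0, 0), genes, "void")),
               "zero total")
})

test_that("variable-gene ranking matches a dense CV oracle", {
  sim <- generate_barnyard(tiny_config(n_cells = 120))
  norm <- normalize_log1p(sim$matrix)
  dense <- as.matrix(norm)
  cv <- apply(dense, 1, function(x) {
    if (mean(x) == 0) return(-Inf)
    stats::sd(x) / mean(x)
  })
  oracle <- rownames(dense)[order(-cv, rownames(dense))][1:50]
  expect_identical(select_hvg(norm, 50), oracle)
})

test_that("constant genes rank last and planted programs rank high", {
  genes <- paste0("hg38-G", 1:4)
  dense <- rbind(rep(4, 6),                  # constant -> CV 0
                 c(0, 0, 0, 9, 9, 9),       # variable
                 c(1, 1, 1, 1, 1, 9),       # variable
                 rep(2, 6))                 # constant
  m <- tagged_matrix(dense, genes)
  ranked <- suppressWarnings(select_hvg(normalize_log1p(m), 4))
  expect_setequal(ranked[3:4], c("hg38-G1", "hg38-G4"))
  # planted high-dispersion (spiky) genes land inside the top set
  set.seed(6)
  n_genes <- 100; n_cells <- 60
  base <- matrix(rpois(n_genes * n_cells, 5) + 1, n_genes, n_cells)
  spiky <- paste0("hg38-SPIKE", 1:5)
  for (i in 1:5) {
    base[i, ] <- 0
    base[i, i] <- 200   # expressed in exactly one cell
  }
  m2 <- tagged_matrix(base, c(spiky, paste0("hg38-G", 6:n_genes)))
  hvg <- select_hvg(normalize_log1p(m2), 5)
  expect_setequal(hvg, spiky)
})

test_that("two disjoint programs cluster perfectly and deterministically", {
  cfg <- tiny_config(
    n_cells = 150, species_mix = 0, soup_fraction = 0,
    cross_map_prob = 0, doublet_rate = 0, dying_rate = 0,
    cell_type_table = list(
      list(name = "pig_macrophage", species = "pig",
           program = 31:60, fold = 12, prop = 0.5),
      list(name = "pig_tubular", species = "pig",
           program = 61:90, fold = 12, prop = 0.5)))
  sim <- generate_barnyard(cfg)
  norm <- normalize_log1p(sim$matrix)
  hvg <- select_hvg(norm, 80)
  res <- embed_and_cluster(norm, hvg, n_components = 10, seed = 4L)
  expect_equal(nlevels(res$clusters), 2)
  expect_equal(ari(res$clusters, sim$truth$cell_type), 1)
  # fixed seed reproduces labels exactly
  res2 <- embed_and_cluster(norm, hvg, n_components = 10, seed = 4L)
  expect_identical(res$clusters, res2$clusters)
})

test_that("marker tables match wilcox.test and detect perfect separation", {
  set.seed(8)
  n_genes <- 50; n_cells <- 200
  genes <- paste0("hg38-G", seq_len(n_genes))
  dense <- matrix(rpois(n_genes * n_cells, 4), n_genes, n_cells,
                  dimnames = list(genes, paste0("c", seq_len(n_cells))))
  grp <- rep(c("a", "b"), each = n_cells / 2)
  dense[1, grp == "a"] <- dense[1, grp == "a"] + 30   # marker of a
  m <- tagged_matrix(dense, genes)
  norm <- normalize_log1p(m)
  markers <- find_markers(norm, grp)
  # oracle: stats::wilcox.test per gene on the normalized values
  dn <- as.matrix(norm)
  p_oracle <- apply(dn, 1, function(x) {
    suppressWarnings(stats::wilcox.test(x[grp == "a"],
                                        x[grp == "b"])$p.value)
  })
  got <- setNames(markers$a$p_value, markers$a$gene)[names(p_oracle)]
  expect_equal(unname(got), unname(p_oracle), tolerance = 1e-6)
  expect_equal(setNames(markers$a$p_adj, markers$a$gene)[names(p_oracle)][1],
               stats::p.adjust(p_oracle, "BH")[1], ignore_attr = TRUE)
  # the spiked gene tops cluster a with a vanishing adjusted p
  expect_identical(markers$a$gene[1], "hg38-G1")
  expect_lt(markers$a$p_adj[1], 1e-10)
  expect_gt(markers$a$log_fc[1], 0)
})

test_that("permuted labels give uniform marker p-values", {
  set.seed(21)
  n_genes <- 200; n_cells <- 120
  genes <- paste0("ss11-G", seq_len(n_genes))
  dense <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells)
  m <- tagged_matrix(dense, genes)
  norm <- normalize_log1p(m)
  grp <- sample(rep(c("a", "b"), each = n_cells / 2))
  p <- find_markers(norm, grp)$a$p_value
  # discreteness of count ties makes p slightly conservative; KS should
  # still not reject uniformity at alpha = 0.01
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("degenerate cluster inputs are handled", {
  genes <- paste0("hg38-G", 1:5)
  m <- tagged_matrix(matrix(rpois(50, 5), 5, 10), genes)
  norm <- normalize_log1p(m)
  expect_error(find_markers(norm, rep("one", 10)), "2 clusters")
  expect_warning(find_markers(norm, c(rep("a", 9), "b")), "skipped")
})
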