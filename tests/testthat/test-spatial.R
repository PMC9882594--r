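test_that("cells per spot is the plain mean of nuclei counts", {
  expect_equal(estimate_cells_per_spot(c(5, 5, 5)), 5)
  # ten manual counts summing to 66 give the 6.6 cells/spot estimate
  counts <- c(7, 6, 8, 5, 7, 6, 7, 6, 7, 7)
  expect_equal(sum(counts), 66)
  expect_equal(estimate_cells_per_spot(counts), 6.6)
  expect_equal(estimate_cells_per_spot(counts),
               sum(counts) / length(counts))
  expect_error(estimate_cells_per_spot(numeric(0)), "empty")
})

test_that("signatures equal dense per-type means of normalized cells", {
  sim <- generate_barnyard(tiny_config(n_cells = 150, doublet_rate = 0))
  labels <- sim$truth$cell_type
  sig <- build_signatures(sim$matrix, labels)
  dense <- as.matrix(sim$matrix)
  norm <- sweep(dense, 2, colSums(dense), "/") * 10000
  for (tt in rownames(sig$signatures)) {
    expect_equal(sig$signatures[tt, ],
                 rowMeans(norm[, labels == tt, drop = FALSE]),
                 tolerance = 1e-10)
  }
  expect_error(build_signatures(sim$matrix, replace(labels, 1, NA)),
               "unlabeled")
  # identical cells: signature equals any one cell's normalized vector
  one <- tagged_matrix(rep(c(4, 6), 3), c("hg38-A", "hg38-B"),
                       paste0("c", 1:3))
  s1 <- build_signatures(one, rep("t", 3))
  expect_equal(unname(s1$signatures["t", ]),
               c(4, 6) / 10 * 10000)
  expect_true("t" %in% s1$low_confidence)
})

test_that("signatures correlate with the generating programs", {
  sim <- generate_barnyard(generator_config(n_cells = 1200,
                                            doublet_rate = 0,
                                            soup_fraction = 0,
                                            cross_map_prob = 0,
                                            dying_rate = 0, seed = 2L))
  labels <- sim$truth$cell_type
  sig <- build_signatures(sim$matrix, labels)
  base <- xenocensus:::.program_baselines(sim$config)
  for (ct in sim$config$cell_type_table) {
    n_ct <- sum(labels == ct$name)
    if (n_ct < 200) next
    w <- if (ct$species == "human") base$human else base$pig
    w[ct$program] <- w[ct$program] * rep_len(ct$fold, length(ct$program))
    own <- sim$panels[[ct$species]]$name
    expect_gt(stats::cor(sig$signatures[ct$name, own], w), 0.95)
  }
})

test_that("a spot proportional to one signature gets all its mass", {
  sim <- generate_barnyard(tiny_config(n_cells = 200, doublet_rate = 0))
  sig <- build_signatures(sim$matrix, sim$truth$cell_type)
  y <- 2 * sig$signatures["pig_macrophage", ]
  spot <- tagged_matrix(round(y), colnames(sig$signatures), "s1")
  dec <- deconvolve_spots(spot, sig, cells_per_spot = 1)
  share <- dec$abundance[1, "pig_macrophage"] / sum(dec$abundance)
  expect_gte(share, 0.99)
  # abundance rescaled to the expected cells per spot
  expect_equal(sum(dec$abundance), 1, tolerance = 1e-8)
})

test_that("a 2:1 planted mixture is recovered within 20%", {
  sim <- generate_barnyard(generator_config(n_cells = 2000, seed = 7L))
  singl <- sim$truth$barcode[!sim$truth$is_doublet]
  sig <- build_signatures(
    sim$matrix[, singl],
    sim$truth$cell_type[match(singl, sim$truth$barcode)])
  ab <- matrix(0, 30, 2,
               dimnames = list(NULL,
                               c("pig_macrophage", "pig_neutrophil")))
  ab[, 1] <- 8; ab[, 2] <- 4
  vs <- generate_visium_like(generator_config(n_cells = 10, seed = 17L),
                             list(n_rows = 5, n_cols = 6), ab,
                             sampling = "exact")
  expect_gt(min(Matrix::colSums(vs$matrix)), 1000)
  dec <- deconvolve_spots(vs$matrix, sig, cells_per_spot = 12)
  est <- colSums(dec$abundance)
  ratio <- est[["pig_macrophage"]] / est[["pig_neutrophil"]]
  expect_lt(abs(ratio - 2) / 2, 0.2)
})

test_that("per-spot NNLS matches an exhaustive active-set oracle", {
  set.seed(12)
  n_genes <- 50
  genes <- paste0("ss11-G", seq_len(n_genes))
  sig <- matrix(rexp(3 * n_genes), nrow = 3,
                dimnames = list(c("t1", "t2", "t3"), genes))
  mix <- rbind(c(3, 1, 0), c(0, 2, 2), c(1, 1, 1), c(0, 0, 5))
  spots <- t(mix %*% sig) + matrix(rexp(4 * n_genes, 10), n_genes, 4)
  spots <- round(spots * 10)
  m <- tagged_matrix(spots, genes, paste0("s", 1:4))
  dec <- deconvolve_spots(m, sig, cells_per_spot = NULL)
  for (s in 1:4) {
    y <- spots[, s] / sum(spots[, s]) * 10000
    oracle <- nnls_oracle(t(sig[, dec$shared_genes]), y)
    expect_equal(unname(dec$abundance[s, ]), oracle, tolerance = 1e-6)
  }
})

test_that("deconvolution invariants hold", {
  sim <- generate_barnyard(tiny_config(n_cells = 150, doublet_rate = 0))
  sig <- build_signatures(sim$matrix, sim$truth$cell_type)
  ab <- matrix(2, 4, 2, dimnames = list(NULL, c("pig_macrophage",
                                                "human_monocyte")))
  vs <- generate_visium_like(tiny_config(n_cells = 10, seed = 3L),
                             list(n_rows = 2, n_cols = 2), ab,
                             sampling = "exact")
  dec <- deconvolve_spots(vs$matrix, sig, cells_per_spot = 4)
  expect_true(all(dec$abundance >= 0))
  # fitted residual never exceeds the zero-abundance residual
  y_norms <- apply(as.matrix(vs$matrix)[dec$shared_genes, ], 2,
                   function(y) sqrt(sum((y / sum(y) * 10000)^2)))
  expect_true(all(dec$residual_norm <= y_norms + 1e-8))
  # jointly permuting gene order changes nothing
  perm <- sample(nrow(vs$matrix))
  dec2 <- deconvolve_spots(vs$matrix[perm, ], sig, cells_per_spot = 4)
  expect_equal(dec$abundance, dec2$abundance, tolerance = 1e-8)
  expect_error(deconvolve_spots(
    tagged_matrix(1, "hg38-ZZZ", "s"), sig), "shared")
})

test_that("marker imputation reads tagged genes per spot", {
  sim <- generate_barnyard(tiny_config(n_cells = 300, cross_map_prob = 0,
                                       soup_fraction = 0,
                                       doublet_rate = 0))
  ab <- matrix(0, 6, 2, dimnames = list(NULL, c("human_T",
                                                "pig_macrophage")))
  ab[1:3, "human_T"] <- 2
  ab[, "pig_macrophage"] <- 3
  vs <- generate_visium_like(tiny_config(n_cells = 10, seed = 5L,
                                         cross_map_prob = 0,
                                         soup_fraction = 0),
                             list(n_rows = 2, n_cols = 3), ab,
                             sampling = "exact")
  # human_T program genes are hg38-tagged; pick one planted marker
  t_prog <- vs$config$cell_type_table[[1]]$program
  marker <- vs$panels$human$name[t_prog[1]]
  imp <- impute_marker_abundance(vs$matrix, c(marker, "hg38-ABSENT"))
  expect_identical(attr(imp, "missing"), "hg38-ABSENT")
  cnt <- imp[[paste0("count.", marker)]]
  expect_equal(cnt, as.numeric(vs$matrix[marker, ]))
  det <- imp[[paste0("detected.", marker)]]
  # detected exactly where human T cells were planted (no leakage paths)
  expect_true(all(det[1:3]))
  expect_false(any(det[4:6]))
})
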