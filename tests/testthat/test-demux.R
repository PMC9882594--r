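test_that("species profiles report purity and majority for simple cells", {
  genes <- c("hg38-A", "hg38-B", "ss11-A", "ss11-B")
  m <- tagged_matrix(c(60, 30, 10, 0,    # 90 human / 10 pig
                       25, 25, 25, 25,   # exact tie
                       0, 0, 0, 0),      # empty droplet
                     genes, c("mostly_human", "tied", "empty"))
  pr <- compute_species_profiles(m)
  expect_equal(pr$purity[1], 0.9)
  expect_identical(pr$majority_species[1], "human")
  expect_identical(pr$majority_species[2], "tie")
  expect_equal(pr$purity[2], 0.5)
  expect_true(pr$zero_total[3])
  expect_true(is.na(pr$purity[3]))
  expect_equal(pr$transcripts_human + pr$transcripts_pig,
               unname(Matrix::colSums(m)))
})

test_that("profiles match a dense brute-force recomputation", {
  sim <- generate_barnyard(tiny_config(cross_map_prob = 0.05))
  pr <- compute_species_profiles(sim$matrix)
  oracle <- dense_profile_oracle(sim$matrix)
  expect_equal(pr$transcripts_human, unname(oracle[, "th"]))
  expect_equal(pr$transcripts_pig, unname(oracle[, "tp"]))
  expect_equal(pr$genes_detected_human, unname(oracle[, "gh"]))
  expect_equal(pr$genes_detected_pig, unname(oracle[, "gp"]))
  expect_equal(pr$purity,
               pmax(oracle[, "th"], oracle[, "tp"]) /
                 (oracle[, "th"] + oracle[, "tp"]))
})

test_that("purity summary does forced arithmetic correctly", {
  genes <- c("hg38-A", "ss11-A")
  # nine pure cells and one at 85% purity, equal totals of 100
  counts <- cbind(matrix(rep(c(100, 0), 9), nrow = 2),
                  c(85, 15))
  m <- tagged_matrix(counts, genes, paste0("c", 1:10))
  s <- summarize_purity(compute_species_profiles(m))
  expect_equal(s$cells_above_purity_threshold_fraction, 0.9)
  expect_equal(s$single_species_transcript_fraction,
               (9 * 100 + 85) / 1000)
  # all pure: both fractions 1
  pure <- tagged_matrix(rep(c(50, 0), 4), genes, paste0("p", 1:4))
  s2 <- summarize_purity(compute_species_profiles(pure))
  expect_equal(s2$single_species_transcript_fraction, 1)
  expect_equal(s2$cells_above_purity_threshold_fraction, 1)
  expect_error(summarize_purity(compute_species_profiles(
    tagged_matrix(c(0, 0), genes, "z"))), "nonzero")
})

test_that("purity threshold is strict and ties are excluded from the numerator", {
  genes <- c("hg38-A", "ss11-A")
  m <- tagged_matrix(c(90, 10, 50, 50), genes, c("ninety", "tied"))
  s <- summarize_purity(compute_species_profiles(m), 0.90)
  # purity exactly 0.90 does not clear the strict > 0.90 bar
  expect_equal(s$cells_above_purity_threshold_fraction, 0)
  # tied cell contributes 0 to the single-species numerator
  expect_equal(s$single_species_transcript_fraction, 90 / 200)
})

test_that("ratio classifier respects the 0.75 / 1.33 band", {
  calls <- classify_by_ratio(
    genes_detected_human = c(74, 100, 10, 134, 0, 0),
    genes_detected_pig   = c(100, 100, 0, 100, 5, 0))
  expect_identical(calls$label,
                   c("porcine",     # 0.74 < 0.75
                     "ambiguous",   # 1.00 inside the band
                     "human",       # +Inf, degenerate denominator
                     "human",       # 1.34 > 1.33
                     "porcine",     # 0, zero human genes
                     "ambiguous")) # nothing detected
  expect_true(calls$unassignable[6])
  expect_false(any(calls$unassignable[1:5]))
  # boundaries themselves are ambiguous (strict inequalities)
  at_bounds <- classify_by_ratio(c(75, 133), c(100, 100))
  expect_identical(at_bounds$label, c("ambiguous", "ambiguous"))
})

test_that("every finite non-negative ratio receives exactly one label", {
  h <- c(0, 1, 3, 74, 75, 76, 100, 132, 133, 134, 500)
  calls <- classify_by_ratio(h, rep(100, length(h)))
  expect_true(all(calls$label %in% c("porcine", "human", "ambiguous")))
  expect_identical(calls$label,
                   ifelse(calls$ratio < 0.75, "porcine",
                          ifelse(calls$ratio > 1.33, "human",
                                 "ambiguous")))
})

test_that("concordance agrees with a brute-force barcode-wise comparison", {
  a <- data.frame(barcode = c("x", "y", "z", "w"),
                  label = c("human", "porcine", "ambiguous", "human"))
  b <- data.frame(barcode = c("x", "y", "z", "w"),
                  label = c("human", "human", "porcine", "human"))
  r <- concordance(a, b)
  expect_equal(r$agreement, 2 / 3)   # x, w agree; y disagrees; z skipped
  expect_equal(r$n_compared, 3)
  # identity and total disagreement
  expect_equal(concordance(a, a)$agreement, 1)
  flipped <- within(a, label <- ifelse(label == "human", "porcine",
                                       ifelse(label == "porcine", "human",
                                              label)))
  expect_equal(concordance(a, flipped)$agreement, 0)
  # symmetry
  expect_equal(concordance(a, b)$agreement, concordance(b, a)$agreement)
  expect_error(concordance(a, data.frame(barcode = "q", label = "human")),
               "shared")
})

test_that("two end-to-end species calls agree on generator data", {
  cfg <- tiny_config(n_cells = 400, seed = 13L)
  sim <- generate_barnyard(cfg)
  pure_p <- generate_barnyard(tiny_config(species_mix = 0,
                                          doublet_rate = 0, seed = 21L))
  pure_h <- generate_barnyard(tiny_config(species_mix = 1,
                                          doublet_rate = 0, seed = 22L))
  mr_h <- build_modified_reference(sim$panels$human, pure_p$matrix)
  mr_p <- build_modified_reference(sim$panels$pig, pure_h$matrix)
  rc <- ratio_calls(sim$matrix, mr_h, mr_p)
  pr <- compute_species_profiles(sim$matrix)
  majority <- data.frame(
    barcode = pr$barcode,
    label = ifelse(pr$majority_species == "pig", "porcine",
                   ifelse(pr$majority_species == "human", "human",
                          "ambiguous")))
  r <- concordance(majority, rc)
  # brute-force comparison over shared unambiguous barcodes
  joined <- merge(majority, rc, by = "barcode")
  ok <- joined$label.x != "ambiguous" & joined$label.y != "ambiguous"
  expect_equal(r$agreement, mean(joined$label.x[ok] == joined$label.y[ok]))
  expect_gt(r$agreement, 0.95)
})

test_that("cross-map report finds the planted offending genes", {
  # pure pig population, cross-mapping into exactly the homolog partners
  cfg <- tiny_config(species_mix = 0, doublet_rate = 0,
                     soup_fraction = 0, cross_map_prob = 0.1,
                     n_homolog_pairs = 20, n_cells = 300)
  sim <- generate_barnyard(cfg)
  rep <- cluster_crossmap_report(
    sim$matrix, rep("pigs", ncol(sim$matrix)), c(pigs = "pig"))
  offenders <- rep$pigs$offending_genes
  expect_true(all(offenders$gene %in% sim$homologs$human_name))
  # opposite fraction equals a dense recomputation
  dense <- as.matrix(sim$matrix)
  opp <- sum(dense[grepl("^hg38-", rownames(dense)), ])
  expect_equal(rep$pigs$opposite_fraction, opp / sum(dense))
  # cumulative fraction is non-decreasing and ends at 1
  expect_true(all(diff(offenders$cumulative_fraction) >= 0))
  expect_equal(utils::tail(offenders$cumulative_fraction, 1), 1)
  expect_equal(rep$pigs$panel_fraction,
               nrow(offenders) / sum(grepl("^hg38-", rownames(dense))))
})

test_that("cross-map report handles clean clusters and unknown species", {
  genes <- c("hg38-A", "ss11-A")
  m <- tagged_matrix(c(10, 0, 8, 0), genes, c("c1", "c2"))
  rep <- cluster_crossmap_report(m, c("k", "k"), c(k = "human"))
  expect_equal(rep$k$opposite_fraction, 0)
  expect_equal(nrow(rep$k$offending_genes), 0)
  expect_warning(
    r2 <- cluster_crossmap_report(m, c("k", "u"), c(k = "human")),
    "no assigned species")
  expect_null(r2$u)
})
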