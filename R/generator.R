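#' Configuration for the synthetic barnyard generator
#'
#' Builds the parameter set for [generate_barnyard()] and
#' [generate_visium_like()]. The generator emulates a mixed-species
#' (human/pig) droplet experiment aligned to a species-tagged hybrid
#' namespace: per-cell-type gamma-Poisson expression programs, homologous
#' gene pairs that cross-map between species with a fixed probability,
#' ambient ("soup") contamination drawn from the pooled singlet profile,
#' doublets formed by summing two cells, and an elevated-mitochondria
#' "dying" subpopulation so mitochondrial QC filtering has both pass and
#' fail cases.
#'
#' Defaults encode the study conditions the validation suite assumes:
#' 2,000 cells, 2\% ambient contamination, 2\% homolog cross-mapping
#' probability, 5\% doublet rate, an even human/pig mix and macrophage
#' programs skewed 4-fold towards the M2 (anti-inflammatory) gene set.
#'
#' @param n_genes_per_species Genes per species panel (default 300).
#' @param n_mito Mitochondrial genes at the head of each panel (default 10).
#' @param n_homolog_pairs Homologous gene pairs; pair i links the i-th
#'   non-mitochondrial human gene with its pig positional partner
#'   (default 40). Must not exceed `n_genes_per_species - n_mito`.
#' @param cross_map_prob Probability that a read emitted by one member of a
#'   homolog pair is assigned to its partner in the other species
#'   (default 0.02).
#' @param n_cells Total barcodes, doublets included (default 2000).
#' @param species_mix Fraction of human cells in `[0, 1]` (default 0.5).
#' @param cell_type_table List of cell-type programs; see
#'   [default_cell_types()]. Each entry has `name`, `species`
#'   (`"human"`/`"pig"`), `program` (gene indices into that species panel),
#'   `fold` (fold-change, recycled over `program`) and `prop`
#'   (within-species proportion).
#' @param library_size_log_mean,library_size_log_sd Lognormal parameters of
#'   the per-cell library size (defaults `log(5000)` and 0.35).
#' @param dispersion Gamma-Poisson overdispersion of per-gene rates
#'   (variance of the mean-1 gamma multiplier; default 0.3).
#' @param soup_fraction Expected fraction of each cell's counts replaced by
#'   draws from the pooled ambient profile (default 0.02).
#' @param doublet_rate Fraction of barcodes that are doublets (default 0.05).
#' @param doublet_score_noise_sd SD of the half-normal doublet score given
#'   to singlets (default 0.1); true doublets score 1.
#' @param mito_fraction,mito_fraction_dying Expected mitochondrial
#'   expression share for healthy (0.04) and dying (0.20) cells.
#' @param dying_rate Fraction of cells in the high-mitochondria dying
#'   subpopulation (default 0.05).
#' @param seed Integer seed; every draw is reproducible given it.
#' @param program_seed Integer seed for the per-gene baseline expression
#'   weights, separate from `seed` so that datasets generated with
#'   different sampling seeds (e.g. a dissociated reference and a spatial
#'   section) still share the same underlying expression programs, as two
#'   experiments on the same tissue would. Change it only to draw a
#'   different "organism".
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes_per_species = 300,
                             n_mito = 10,
                             n_homolog_pairs = 40,
                             cross_map_prob = 0.02,
                             n_cells = 2000,
                             species_mix = 0.5,
                             cell_type_table = NULL,
                             library_size_log_mean = log(5000),
                             library_size_log_sd = 0.35,
                             dispersion = 0.3,
                             soup_fraction = 0.02,
                             doublet_rate = 0.05,
                             doublet_score_noise_sd = 0.1,
                             mito_fraction = 0.04,
                             mito_fraction_dying = 0.20,
                             dying_rate = 0.05,
                             seed = 1L,
                             program_seed = 20230109L) {
  if (is.null(cell_type_table)) {
    cell_type_table <- default_cell_types(n_genes_per_species, n_mito)
  }
  cfg <- list(
    n_genes_per_species = as.integer(n_genes_per_species),
    n_mito = as.integer(n_mito),
    n_homolog_pairs = as.integer(n_homolog_pairs),
    cross_map_prob = cross_map_prob,
    n_cells = as.integer(n_cells),
    species_mix = species_mix,
    cell_type_table = cell_type_table,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    dispersion = dispersion,
    soup_fraction = soup_fraction,
    doublet_rate = doublet_rate,
    doublet_score_noise_sd = doublet_score_noise_sd,
    mito_fraction = mito_fraction,
    mito_fraction_dying = mito_fraction_dying,
    dying_rate = dying_rate,
    seed = as.integer(seed),
    program_seed = as.integer(program_seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  probs <- c(cross_map_prob = cfg$cross_map_prob,
             species_mix = cfg$species_mix,
             soup_fraction = cfg$soup_fraction,
             doublet_rate = cfg$doublet_rate,
             mito_fraction = cfg$mito_fraction,
             mito_fraction_dying = cfg$mito_fraction_dying,
             dying_rate = cfg$dying_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("configuration error: probabilities outside [0,1]: ",
         paste(names(probs)[bad], collapse = ", "))
  }
  if (cfg$n_cells < 1L || cfg$n_genes_per_species < 1L) {
    stop("configuration error: need at least one cell and one gene")
  }
  if (cfg$n_homolog_pairs > cfg$n_genes_per_species - cfg$n_mito) {
    stop("configuration error: n_homolog_pairs exceeds non-mitochondrial panel size")
  }
  if (cfg$doublet_score_noise_sd <= 0) {
    stop("configuration error: doublet_score_noise_sd must be positive")
  }
  for (ct in cfg$cell_type_table) {
    if (!ct$species %in% c("human", "pig")) {
      stop("configuration error: unknown species in cell type ", ct$name)
    }
    if (any(ct$program < 1L | ct$program > cfg$n_genes_per_species)) {
      stop("configuration error: cell type ", ct$name,
           " references genes outside its species panel")
    }
  }
  invisible(cfg)
}

#' Default cell-type expression programs
#'
#' A small immune census: human T, B, NK, monocyte and macrophage
#' populations plus pig resident macrophages, neutrophils and tubular
#' cells. Each type boosts a marker block 8-fold over baseline; both
#' macrophage programs additionally boost the M2 gene block 4-fold
#' (M1 stays at baseline), emulating the alternatively activated phenotype
#' of xenograft-resident and infiltrating macrophages.
#'
#' Panel layout per species (indices after `n_mito` mitochondrial genes):
#' M1 block (10 genes), M2 block (10), then marker blocks per type.
#'
#' @param n_genes Genes per species panel.
#' @param n_mito Mitochondrial genes at the head of the panel.
#' @return List of cell-type program entries (see [generator_config()]).
#' @export
default_cell_types <- function(n_genes = 300, n_mito = 10) {
  if (n_genes < n_mito + 120) {
    stop("default cell types need at least ", n_mito + 120,
         " genes per species")
  }
  b <- n_mito      # block offset: mito occupies 1:n_mito
  m1 <- (b + 1):(b + 10)
  m2 <- (b + 11):(b + 20)
  blk <- function(i) (b + 20 + (i - 1) * 15 + 1):(b + 20 + i * 15)
  # alternatively activated phenotype: M2 block elevated 4-fold,
  # pro-inflammatory M1 block diminished 2-fold
  macro_prog <- c(blk(4), m2, m1)
  macro_fold <- c(rep(8, 15), rep(4, 10), rep(0.5, 10))
  list(
    list(name = "human_T", species = "human", program = blk(1),
         fold = 8, prop = 0.12),
    list(name = "human_B", species = "human", program = blk(2),
         fold = 8, prop = 0.08),
    list(name = "human_NK", species = "human", program = blk(3),
         fold = 8, prop = 0.10),
    list(name = "human_monocyte", species = "human", program = blk(5),
         fold = 8, prop = 0.20),
    list(name = "human_macrophage", species = "human", program = macro_prog,
         fold = macro_fold, prop = 0.50),
    list(name = "pig_macrophage", species = "pig", program = macro_prog,
         fold = macro_fold, prop = 0.60),
    list(name = "pig_neutrophil", species = "pig", program = blk(6),
         fold = 8, prop = 0.25),
    list(name = "pig_tubular", species = "pig", program = blk(7),
         fold = 8, prop = 0.15)
  )
}

#' Gene panels implied by a generator configuration
#'
#' Symbols are structured: `MT-*` mitochondrial genes, then the first ten
#' canonical M1 and M2 polarization markers (see
#' [default_polarization_sets()]), then `GENE*` filler; the same symbol
#' list is used for both species so every gene has a positional homolog
#' partner.
#'
#' @param cfg A `generator_config`.
#' @return List with `human`, `pig` and merged `hybrid` panels, plus a
#'   `homologs` data.frame (`human_name`, `pig_name`) of the configured
#'   cross-mapping pairs.
#' @export
generator_panels <- function(cfg) {
  n <- cfg$n_genes_per_species
  nm <- cfg$n_mito
  sets <- default_polarization_sets()
  symbols <- c(sprintf("MT-%d", seq_len(nm)),
               sets$M1[1:10], sets$M2[1:10],
               sprintf("GENE%04d", seq_len(n - nm - 20)))
  # canonical lineage markers lead the T- and B-cell program blocks, so
  # marker-based imputation (CD3E / CD19) works on synthetic data
  if (n >= nm + 50) {
    symbols[nm + 21] <- "CD3E"
    symbols[nm + 36] <- "CD19"
  }
  human <- gene_panel(symbols, "hg38", is_mito = seq_len(n) <= nm)
  pig <- gene_panel(symbols, "ss11", is_mito = seq_len(n) <= nm)
  hybrid <- merge_namespaces(human, pig)
  hidx <- nm + seq_len(cfg$n_homolog_pairs)
  homologs <- data.frame(
    human_idx = hidx, pig_idx = hidx,
    human_name = human$name[hidx], pig_name = pig$name[hidx],
    stringsAsFactors = FALSE
  )
  list(human = human, pig = pig, hybrid = hybrid, homologs = homologs)
}

# Baseline per-gene expression weights (lognormal), drawn from the
# config's program_seed so every dataset sharing it shares its "organism";
# leaves the caller's RNG stream untouched.
.program_baselines <- function(cfg) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(cfg$program_seed)
  out <- list(
    human = stats::rlnorm(cfg$n_genes_per_species, meanlog = 0, sdlog = 1),
    pig = stats::rlnorm(cfg$n_genes_per_species, meanlog = 0, sdlog = 1))
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
  out
}

# Draw raw counts for a set of cells: gamma-Poisson programs realised as a
# per-cell multinomial over the own-species panel with lognormal totals.
# Returns a dense (2*n_genes) x n matrix in hybrid panel order
# (human genes first).
.sample_cells <- function(cfg, species, type_idx, dying, base_h, base_p) {
  n <- length(species)
  ng <- cfg$n_genes_per_species
  counts <- matrix(0, nrow = 2L * ng, ncol = n)
  mito <- seq_len(cfg$n_mito)
  libs <- pmax(50L, as.integer(round(stats::rlnorm(
    n, cfg$library_size_log_mean, cfg$library_size_log_sd))))
  shape <- 1 / cfg$dispersion
  for (i in seq_len(n)) {
    ct <- cfg$cell_type_table[[type_idx[i]]]
    base <- if (species[i] == "human") base_h else base_p
    w <- base
    w[ct$program] <- w[ct$program] * rep_len(ct$fold, length(ct$program))
    # pin expected mitochondrial share (elevated for dying cells)
    mf <- if (dying[i]) cfg$mito_fraction_dying else cfg$mito_fraction
    w[mito] <- base[mito] / sum(base[mito]) *
      (mf / (1 - mf)) * sum(w[-mito])
    # gamma multiplier (mean 1, variance = dispersion) => NB marginals
    w <- w * stats::rgamma(ng, shape = shape, rate = shape)
    p <- w / sum(w)
    cc <- stats::rmultinom(1L, libs[i], p)[, 1L]
    offset <- if (species[i] == "human") 0L else ng
    counts[offset + seq_len(ng), i] <- cc
  }
  counts
}

# Move counts between homolog partners with probability cross_map_prob.
# Count-conserving: every moved read lands on the partner gene.
.apply_crossmap <- function(counts, cfg, homologs) {
  p <- cfg$cross_map_prob
  if (p <= 0 || nrow(homologs) == 0L) return(counts)
  ng <- cfg$n_genes_per_species
  hrow <- homologs$human_idx
  prow <- ng + homologs$pig_idx
  ch <- counts[hrow, , drop = FALSE]
  cp <- counts[prow, , drop = FALSE]
  mh <- array(stats::rbinom(length(ch), as.vector(ch), p), dim = dim(ch))
  mp <- array(stats::rbinom(length(cp), as.vector(cp), p), dim = dim(cp))
  counts[hrow, ] <- ch - mh + mp
  counts[prow, ] <- cp - mp + mh
  counts
}

# Replace a binomial share of every cell's counts with draws from the
# pooled ambient profile. Per-cell totals are conserved exactly; returns
# the realised replaced fraction per cell.
.apply_soup <- function(counts, cfg) {
  s <- cfg$soup_fraction
  n <- ncol(counts)
  if (s <= 0) return(list(counts = counts, realized = numeric(n)))
  pooled <- rowSums(counts)
  pooled <- pooled / sum(pooled)
  realized <- numeric(n)
  for (i in seq_len(n)) {
    ci <- counts[, i]
    tot <- sum(ci)
    if (tot == 0) next
    keep <- stats::rbinom(length(ci), ci, 1 - s)
    n_soup <- tot - sum(keep)
    soup <- stats::rmultinom(1L, n_soup, pooled)[, 1L]
    counts[, i] <- keep + soup
    realized[i] <- n_soup / tot
  }
  list(counts = counts, realized = realized)
}

# Deterministic unique droplet barcodes (base-4 ACGT encoding of the index).
.make_barcodes <- function(n, width = 12L) {
  alphabet <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(width)
    for (j in seq_len(width)) {
      digits[j] <- i %% 4L
      i <- i %/% 4L
    }
    paste0(paste(alphabet[rev(digits) + 1L], collapse = ""), "-1")
  }, character(1))
}

#' Generate a synthetic barnyard (mixed-species) single-cell dataset
#'
#' Draws `n_cells` droplet profiles under the configured two-species
#' immune-census model and returns the species-tagged count matrix together
#' with a full ground-truth table, usable as the oracle for demultiplexing
#' and census validation. Stages, in order: (1) per-cell gamma-Poisson
#' program counts over the cell's own species panel with lognormal library
#' size; (2) homolog cross-mapping, moving each read of a homolog pair to
#' its partner with probability `cross_map_prob`; (3) ambient "soup"
#' replacement of a binomial `soup_fraction` share of each cell's counts
#' with draws from the pooled profile; (4) doublet formation by summing two
#' independently drawn cells. All stages conserve per-barcode totals from
#' stage 2 onwards, and the whole draw is reproducible from `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return A list of class `barnyard_sim`:
#'   \describe{
#'     \item{matrix}{`dgCMatrix`, tagged genes x barcodes, integer counts.}
#'     \item{truth}{data.frame: `barcode`, `species`, `cell_type`,
#'       `is_doublet`, `doublet_score`, `soup_fraction_realized`,
#'       `is_dying`. For doublets, `species` is the species of the member
#'       with the larger library and `cell_type` concatenates both types.}
#'     \item{panels}{gene panels as in [generator_panels()].}
#'     \item{homologs}{configured homolog pair table.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
generate_barnyard <- function(cfg) {
  validate_generator_config(cfg)
  pan <- generator_panels(cfg)
  base <- .program_baselines(cfg)
  base_h <- base$human
  base_p <- base$pig
  set.seed(cfg$seed)
  ng <- cfg$n_genes_per_species
  n <- cfg$n_cells
  n_dbl <- as.integer(round(cfg$doublet_rate * n))
  n_sgl <- n - n_dbl
  n_draw <- n_sgl + 2L * n_dbl

  # assign species / type / dying state for every drawn cell
  species <- ifelse(stats::runif(n_draw) < cfg$species_mix, "human", "pig")
  types <- cfg$cell_type_table
  type_idx <- integer(n_draw)
  for (sp in c("human", "pig")) {
    sel <- which(species == sp)
    if (!length(sel)) next
    avail <- which(vapply(types, function(x) x$species == sp, logical(1)))
    if (!length(avail)) {
      stop("configuration error: no cell types available for species ", sp)
    }
    props <- vapply(types[avail], function(x) x$prop, numeric(1))
    type_idx[sel] <- sample(avail, length(sel), replace = TRUE,
                            prob = props / sum(props))
  }
  dying <- stats::runif(n_draw) < cfg$dying_rate

  counts <- .sample_cells(cfg, species, type_idx, dying, base_h, base_p)
  counts <- .apply_crossmap(counts, cfg, pan$homologs)
  soup <- .apply_soup(counts, cfg)
  counts <- soup$counts

  # doublets: sum pairs from the tail of the drawn pool
  type_name <- vapply(types, function(x) x$name, character(1))[type_idx]
  out <- counts[, seq_len(n_sgl), drop = FALSE]
  bar_species <- species[seq_len(n_sgl)]
  bar_type <- type_name[seq_len(n_sgl)]
  bar_dying <- dying[seq_len(n_sgl)]
  bar_soup <- soup$realized[seq_len(n_sgl)]
  is_doublet <- rep(FALSE, n)
  if (n_dbl > 0L) {
    a <- n_sgl + seq_len(n_dbl)
    b <- n_sgl + n_dbl + seq_len(n_dbl)
    dcounts <- counts[, a, drop = FALSE] + counts[, b, drop = FALSE]
    la <- colSums(counts[, a, drop = FALSE])
    lb <- colSums(counts[, b, drop = FALSE])
    major <- ifelse(la >= lb, a, b)
    out <- cbind(out, dcounts)
    bar_species <- c(bar_species, species[major])
    bar_type <- c(bar_type, paste(type_name[a], type_name[b], sep = "+"))
    bar_dying <- c(bar_dying, dying[a] | dying[b])
    bar_soup <- c(bar_soup,
                  (soup$realized[a] * la + soup$realized[b] * lb) /
                    pmax(1, la + lb))
    is_doublet <- c(rep(FALSE, n_sgl), rep(TRUE, n_dbl))
  }

  score <- pmin(1, abs(stats::rnorm(n, 0, cfg$doublet_score_noise_sd)))
  score[is_doublet] <- 1
  barcodes <- .make_barcodes(n)
  dimnames(out) <- list(pan$hybrid$name, barcodes)
  mat <- methods::as(methods::as(Matrix::Matrix(out, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  truth <- data.frame(
    barcode = barcodes,
    species = bar_species,
    cell_type = bar_type,
    is_doublet = is_doublet,
    doublet_score = score,
    soup_fraction_realized = bar_soup,
    is_dying = bar_dying,
    stringsAsFactors = FALSE
  )
  structure(list(matrix = mat, truth = truth, panels = pan,
                 homologs = pan$homologs, config = cfg),
            class = "barnyard_sim")
}

#' @export
print.barnyard_sim <- function(x, ...) {
  cat(sprintf(
    "barnyard_sim: %d genes x %d cells (%d doublets, soup %.1f%%, cross-map %.1f%%)\n",
    nrow(x$matrix), ncol(x$matrix), sum(x$truth$is_doublet),
    100 * x$config$soup_fraction, 100 * x$config$cross_map_prob))
  invisible(x)
}

#' Generate a Visium-like spatial dataset with known type abundance
#'
#' Each capture spot receives a number of cells of each type drawn from
#' `abundance_truth` (Poisson around the expected abundance by default, or
#' exactly the given integer with `sampling = "exact"`); the spot's count
#' vector is the sum of those cells' profiles, drawn by the same machinery
#' as [generate_barnyard()] (cross-mapping and soup included, no doublets).
#'
#' @param cfg A [generator_config()]; `seed` governs all draws.
#' @param grid List with `n_rows` and `n_cols`; spots fill the grid
#'   row-major, so `n_rows * n_cols` must be at least `nrow(abundance_truth)`.
#' @param abundance_truth Non-negative spots x types matrix; column names
#'   must match cell-type names of `cfg$cell_type_table`.
#' @param sampling `"poisson"` (default) or `"exact"`.
#' @return A list of class `visium_sim`: `matrix` (tagged genes x spots),
#'   `positions` (tissue-positions data.frame: `barcode`, `in_tissue`,
#'   `array_row`, `array_col`, `pixel_row`, `pixel_col`),
#'   `abundance_truth` (realised cells per spot per type), `expected`
#'   (the input expectations), `panels`, `config`.
#' @export
generate_visium_like <- function(cfg, grid, abundance_truth,
                                 sampling = c("poisson", "exact")) {
  validate_generator_config(cfg)
  sampling <- match.arg(sampling)
  abundance_truth <- as.matrix(abundance_truth)
  if (any(abundance_truth < 0)) stop("negative abundance")
  n_spots <- nrow(abundance_truth)
  if (grid$n_rows * grid$n_cols < n_spots) {
    stop("grid too small for ", n_spots, " spots")
  }
  type_names <- vapply(cfg$cell_type_table, function(x) x$name, character(1))
  if (is.null(colnames(abundance_truth)) ||
      !all(colnames(abundance_truth) %in% type_names)) {
    stop("abundance_truth columns must name configured cell types")
  }
  pan <- generator_panels(cfg)
  base <- .program_baselines(cfg)
  base_h <- base$human
  base_p <- base$pig
  set.seed(cfg$seed)
  ng <- cfg$n_genes_per_species

  n_mat <- abundance_truth
  if (sampling == "poisson") {
    n_mat[] <- stats::rpois(length(abundance_truth),
                            as.vector(abundance_truth))
  } else {
    if (any(abundance_truth != round(abundance_truth))) {
      stop("sampling = \"exact\" requires integer abundances")
    }
    n_mat[] <- round(abundance_truth)
  }
  storage.mode(n_mat) <- "integer"

  # draw all member cells in one batch, grouped spot-major
  spot_of <- integer(0); tidx <- integer(0)
  for (s in seq_len(n_spots)) {
    for (tt in seq_len(ncol(n_mat))) {
      k <- n_mat[s, tt]
      if (k > 0L) {
        spot_of <- c(spot_of, rep.int(s, k))
        tidx <- c(tidx, rep.int(match(colnames(n_mat)[tt], type_names), k))
      }
    }
  }
  spots <- matrix(0, nrow = 2L * ng, ncol = n_spots)
  if (length(spot_of)) {
    sp <- vapply(cfg$cell_type_table[tidx], function(x) x$species,
                 character(1))
    dying <- stats::runif(length(tidx)) < cfg$dying_rate
    cells <- .sample_cells(cfg, sp, tidx, dying, base_h, base_p)
    cells <- .apply_crossmap(cells, cfg, pan$homologs)
    cells <- .apply_soup(cells, cfg)$counts
    for (j in seq_along(spot_of)) {
      spots[, spot_of[j]] <- spots[, spot_of[j]] + cells[, j]
    }
  }
  barcodes <- .make_barcodes(n_spots)
  dimnames(spots) <- list(pan$hybrid$name, barcodes)
  rows <- (seq_len(n_spots) - 1L) %/% grid$n_cols
  cols <- (seq_len(n_spots) - 1L) %% grid$n_cols
  positions <- data.frame(
    barcode = barcodes, in_tissue = 1L,
    array_row = rows, array_col = cols,
    pixel_row = 100L * rows + 50L, pixel_col = 100L * cols + 50L,
    stringsAsFactors = FALSE
  )
  mat <- methods::as(methods::as(Matrix::Matrix(spots, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  structure(list(matrix = mat, positions = positions,
                 abundance_truth = n_mat, expected = abundance_truth,
                 panels = pan, config = cfg),
            class = "visium_sim")
}
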