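#' Read a Cell Ranger-dialect tagged count matrix
#'
#' Reads `matrix.mtx` (Matrix Market coordinate), `barcodes.tsv` (one
#' barcode per line) and `features.tsv` (tab-separated id, name, feature
#' type) from a directory, validates dimensions against the Matrix Market
#' header, and checks that every feature name carries a parseable species
#' tag (prefix before the first hyphen), erroring with the offending names
#' otherwise.
#'
#' @param dir Directory containing the three files.
#' @return `dgCMatrix`, tagged genes x barcodes.
#' @export
read_tagged_matrix <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  if (!all(file.exists(paths))) {
    stop("missing file(s): ",
         paste(basename(paths)[!file.exists(paths)], collapse = ", "))
  }
  m <- methods::as(methods::as(Matrix::readMM(paths[1]), "CsparseMatrix"),
                   "generalMatrix")
  barcodes <- readLines(paths[2])
  features <- utils::read.table(paths[3], sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
  if (nrow(m) != nrow(features) || ncol(m) != length(barcodes)) {
    stop(sprintf(
      "format error: matrix is %d x %d but features.tsv has %d rows and barcodes.tsv %d lines",
      nrow(m), ncol(m), nrow(features), length(barcodes)))
  }
  names_col <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  species_tag_of(names_col)   # errors listing untagged features
  dimnames(m) <- list(names_col, barcodes)
  m
}

#' Write a tagged count matrix in the Cell Ranger dialect
#'
#' Writes `matrix.mtx` (Matrix Market coordinate, integer, general),
#' `barcodes.tsv` and `features.tsv` (id, name, "Gene Expression") into
#' `dir`. Feature ids default to the tagged names.
#'
#' @param mat Tagged count matrix (genes x cells), integer-valued.
#' @param dir Output directory (created if needed).
#' @param feature_ids Optional id column for features.tsv.
#' @return `dir`, invisibly.
#' @export
write_tagged_matrix <- function(mat, dir, feature_ids = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(mat, "CsparseMatrix"), "generalMatrix")
  tm <- methods::as(m, "TsparseMatrix")
  con <- file(file.path(dir, "matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(tm@x))), con)
  if (length(tm@x)) {
    writeLines(sprintf("%d %d %d", tm@i + 1L, tm@j + 1L,
                       as.integer(round(tm@x))), con)
  }
  close(con)
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  if (is.null(feature_ids)) feature_ids <- rownames(m)
  utils::write.table(
    data.frame(feature_ids, rownames(m), "Gene Expression"),
    file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Write a simulated barnyard dataset to disk
#'
#' Cell Ranger dialect plus `truth.csv` (the generator ground truth).
#'
#' @param sim A `barnyard_sim` from [generate_barnyard()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_barnyard <- function(sim, dir) {
  write_tagged_matrix(sim$matrix, dir,
                      feature_ids = sim$panels$hybrid$gene_id)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write a simulated Visium-like dataset to disk
#'
#' Cell Ranger dialect plus `tissue_positions.csv` (barcode, in_tissue,
#' array_row, array_col, pixel_row, pixel_col) and `abundance_truth.csv`.
#'
#' @param sim A `visium_sim` from [generate_visium_like()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_visium <- function(sim, dir) {
  write_tagged_matrix(sim$matrix, dir,
                      feature_ids = sim$panels$hybrid$gene_id)
  utils::write.csv(sim$positions, file.path(dir, "tissue_positions.csv"),
                   row.names = FALSE)
  truth <- data.frame(barcode = sim$positions$barcode,
                      sim$abundance_truth, check.names = FALSE)
  utils::write.csv(truth, file.path(dir, "abundance_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read tissue positions written by [write_visium()]
#'
#' @param path CSV path (or the dataset directory).
#' @return data.frame of spot positions.
#' @export
read_tissue_positions <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "tissue_positions.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Assemble a pipeline run configuration
#'
#' Bundles every stage's parameters into one serializable object. All
#' decision thresholds live here: the gene-removal count (3), the ratio
#' band (0.75 / 1.33), the purity threshold (0.90), the QC profile, and
#' the census, polarization and spatial parameters.
#'
#' @param generator A [generator_config()].
#' @param gene_removal_threshold Modified-reference removal rule
#'   (default 3).
#' @param ratio_low,ratio_high Gene-ratio classification band.
#' @param purity_threshold Purity summary cutoff (default 0.90).
#' @param qc A [qc_thresholds()].
#' @param n_hvg,n_components,k_neighbors,resolution Census parameters.
#' @param n_bins,n_ctrl Polarization module-score parameters.
#' @param stages Character vector of stages to run in [run_pipeline()]
#'   (subset of `c("demux", "census", "polarize")`).
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       gene_removal_threshold = 3,
                       ratio_low = 0.75, ratio_high = 1.33,
                       purity_threshold = 0.90,
                       qc = qc_thresholds(),
                       n_hvg = 3000, n_components = 30,
                       k_neighbors = 20, resolution = 0.8,
                       n_bins = 24, n_ctrl = 100,
                       stages = c("demux", "census", "polarize"),
                       seed = 1L) {
  stopifnot(ratio_low <= ratio_high,
            purity_threshold >= 0, purity_threshold <= 1)
  structure(list(generator = generator,
                 gene_removal_threshold = gene_removal_threshold,
                 ratio_low = ratio_low, ratio_high = ratio_high,
                 purity_threshold = purity_threshold, qc = qc,
                 n_hvg = n_hvg, n_components = n_components,
                 k_neighbors = k_neighbors, resolution = resolution,
                 n_bins = n_bins, n_ctrl = n_ctrl,
                 stages = stages, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / restore a run configuration (YAML)
#'
#' Round-trip stable: `read_run_config(write_run_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly / the restored `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  flat <- unclass(cfg)
  flat$generator <- unclass(flat$generator)
  flat$qc <- unclass(flat$qc)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  flat <- yaml::read_yaml(path)
  gen <- do.call(generator_config,
                 flat$generator[setdiff(names(flat$generator),
                                        "cell_type_table")])
  if (!is.null(flat$generator$cell_type_table)) {
    gen$cell_type_table <- lapply(flat$generator$cell_type_table,
                                  function(ct) {
                                    ct$program <- as.integer(unlist(ct$program))
                                    ct$fold <- as.numeric(unlist(ct$fold))
                                    ct
                                  })
    validate_generator_config(gen)
  }
  qc <- do.call(qc_thresholds,
                flat$qc[setdiff(names(flat$qc), "profile")])
  args <- flat[setdiff(names(flat), c("generator", "qc"))]
  args$generator <- gen
  args$qc <- qc
  do.call(run_config, args)
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a barnyard dataset, then runs the configured stages:
#' `demux` (pure-species calibration samples, modified references by the
#' cross-mapping removal rule, both species classifications, purity
#' summary, concordance), `census` (QC through markers) and `polarize`
#' (M1/M2 scoring of macrophage cells per species). Every stage logs its
#' parameters and input/output sizes into a provenance record; the whole
#' bundle is deterministic given the configuration's seeds.
#'
#' The modified references are calibrated exactly as in practice: a
#' pure-species sample per species (generated under the same conditions,
#' doublet-free) is mapped against the opposite species' panel and genes
#' receiving more than `gene_removal_threshold` counts are removed.
#'
#' @param cfg A [run_config()].
#' @return List of class `pipeline_result`: `sim`, `modref`, `profiles`,
#'   `ratio`, `purity`, `concord`, `accuracy` (majority-vs-truth),
#'   `census`, `polarization`, `provenance`.
#' @export
run_pipeline <- function(cfg) {
  prov <- list(seed = cfg$seed, stages = list())
  log_stage <- function(name, ...) {
    prov$stages[[name]] <<- c(list(...), time = format(Sys.time()))
  }
  gen <- cfg$generator
  gen$seed <- cfg$seed
  sim <- generate_barnyard(gen)
  log_stage("simulate", n_cells = ncol(sim$matrix),
            n_genes = nrow(sim$matrix),
            params = gen[c("soup_fraction", "cross_map_prob",
                           "doublet_rate", "species_mix")])
  out <- list(sim = sim, provenance = NULL)

  if ("demux" %in% cfg$stages) {
    # pure-species calibration samples for the modified references
    pure <- function(sp) {
      g <- gen
      g$species_mix <- if (sp == "human") 1 else 0
      g$doublet_rate <- 0
      g$n_cells <- max(200L, as.integer(gen$n_cells / 4L))
      g$seed <- cfg$seed + if (sp == "human") 101L else 102L
      generate_barnyard(g)
    }
    pure_h <- pure("human")
    pure_p <- pure("pig")
    modref_h <- build_modified_reference(
      sim$panels$human, pure_p$matrix, cfg$gene_removal_threshold)
    modref_p <- build_modified_reference(
      sim$panels$pig, pure_h$matrix, cfg$gene_removal_threshold)
    profiles <- compute_species_profiles(sim$matrix)
    purity <- summarize_purity(profiles, cfg$purity_threshold)
    ratio <- ratio_calls(sim$matrix, modref_h, modref_p,
                         low = cfg$ratio_low, high = cfg$ratio_high)
    majority_calls <- data.frame(
      barcode = profiles$barcode,
      label = ifelse(is.na(profiles$majority_species), "ambiguous",
                     ifelse(profiles$majority_species == "pig", "porcine",
                            profiles$majority_species)),
      stringsAsFactors = FALSE)
    concord <- concordance(majority_calls, ratio)
    acc <- mean(profiles$majority_species == sim$truth$species,
                na.rm = TRUE)
    out$modref <- list(human = modref_h, pig = modref_p)
    out$profiles <- profiles
    out$purity <- purity
    out$ratio <- ratio
    out$concord <- concord
    out$accuracy <- acc
    log_stage("demux", removed_human = nrow(modref_h$removed),
              removed_pig = nrow(modref_p$removed),
              accuracy = acc, agreement = concord$agreement,
              thresholds = cfg[c("gene_removal_threshold", "ratio_low",
                                 "ratio_high", "purity_threshold")])
  } else {
    prov$stages[["demux"]] <- list(skipped = TRUE)
  }

  if ("census" %in% cfg$stages) {
    cen <- run_census(sim$matrix, sim$truth$doublet_score,
                      thresholds = cfg$qc, n_hvg = cfg$n_hvg,
                      n_components = cfg$n_components,
                      k_neighbors = cfg$k_neighbors,
                      resolution = cfg$resolution, seed = cfg$seed,
                      markers = FALSE)
    out$census <- cen
    log_stage("census", n_retained = cen$qc$n_retained_cells,
              n_clusters = nlevels(cen$clusters))
  } else {
    prov$stages[["census"]] <- list(skipped = TRUE)
  }

  if ("polarize" %in% cfg$stages) {
    norm <- if (!is.null(out$census)) out$census$normalized else
      normalize_log1p(sim$matrix[, Matrix::colSums(sim$matrix) > 0,
                                 drop = FALSE])
    singlets <- intersect(
      sim$truth$barcode[!sim$truth$is_doublet], colnames(norm))
    macro <- intersect(
      sim$truth$barcode[grepl("macrophage", sim$truth$cell_type)],
      singlets)
    if (length(macro) >= 2L) {
      # score every singlet of each species so the expression bins span
      # the whole census, then summarize the macrophage subset
      sp <- stats::setNames(
        sim$truth$species[match(singlets, sim$truth$barcode)], singlets)
      pol <- polarization_scores(norm[, singlets, drop = FALSE],
                                 species = sp,
                                 n_bins = cfg$n_bins, n_ctrl = cfg$n_ctrl,
                                 seed = cfg$seed)
      pol_macro <- pol[pol$barcode %in% macro, , drop = FALSE]
      out$polarization <- list(
        scores = pol,
        macrophages = pol_macro,
        summary = compare_polarization(pol_macro, pol_macro$species))
      log_stage("polarize", n_scored = nrow(pol),
                n_macrophages = nrow(pol_macro))
    } else {
      prov$stages[["polarize"]] <- list(skipped = TRUE,
                                        reason = "too few macrophages")
    }
  } else {
    prov$stages[["polarize"]] <- list(skipped = TRUE)
  }

  out$provenance <- prov
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result with stages:",
      paste(names(x$provenance$stages), collapse = ", "), "\n")
  if (!is.null(x$accuracy)) {
    cat(sprintf("  majority-species accuracy vs truth: %.2f%%\n",
                100 * x$accuracy))
  }
  invisible(x)
}
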