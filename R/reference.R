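#' Species tags used by the hybrid gene namespace
#'
#' The hybrid human-pig namespace tags every gene with its genome of origin:
#' `"hg38"` for human and `"ss11"` for pig. Display names are
#' `"<tag>-<symbol>"`, e.g. `"hg38-CD3E"`, `"ss11-CD19"`.
#'
#' @format Character vector of length 2.
#' @export
SPECIES_TAGS <- c(human = "hg38", pig = "ss11")

#' Construct a species-tagged gene panel
#'
#' A gene panel is the namespace-level representation of one species' side
#' of the hybrid reference: one row per gene with a stable id, a symbol, a
#' species tag and a mitochondrial flag. Display names (`name`) are formed
#' as `"<species_tag>-<symbol>"` and must be unique within a panel.
#'
#' @param symbols Character vector of gene symbols.
#' @param species_tag Single tag, `"hg38"` or `"ss11"`.
#' @param is_mito Logical vector (recycled) flagging mitochondrial genes.
#' @param gene_id Optional ids; defaults to `"<tag>-G<Index>"`.
#' @return A `data.frame` with columns `gene_id`, `symbol`, `species_tag`,
#'   `is_mito`, `name`.
#' @examples
#' gene_panel(c("CD3E", "CD19"), "hg38")
#' @export
gene_panel <- function(symbols, species_tag, is_mito = FALSE,
                       gene_id = NULL) {
  stopifnot(is.character(symbols), length(symbols) > 0)
  species_tag <- match.arg(species_tag, unname(SPECIES_TAGS))
  if (is.null(gene_id)) {
    gene_id <- sprintf("%s-G%04d", species_tag, seq_along(symbols))
  }
  panel <- data.frame(
    gene_id = gene_id,
    symbol = symbols,
    species_tag = species_tag,
    is_mito = rep_len(as.logical(is_mito), length(symbols)),
    stringsAsFactors = FALSE
  )
  panel$name <- paste0(panel$species_tag, "-", panel$symbol)
  if (anyDuplicated(panel$name)) {
    stop("duplicate tagged names within panel: ",
         paste(unique(panel$name[duplicated(panel$name)]), collapse = ", "))
  }
  panel
}

#' Merge two species' gene panels into a hybrid namespace
#'
#' Concatenates the two panels, preserving species tags, so that the same
#' symbol present in both species yields two distinct entries (e.g.
#' `hg38-CD19` and `ss11-CD19`). A collision in tagged display names is a
#' namespace error.
#'
#' @param panel_a,panel_b Gene panels from [gene_panel()]. `panel_b` may be
#'   `NULL` or empty, in which case the result is `panel_a`.
#' @return Hybrid panel `data.frame` (same columns as [gene_panel()]).
#' @export
merge_namespaces <- function(panel_a, panel_b) {
  if (is.null(panel_b) || nrow(panel_b) == 0L) return(panel_a)
  if (is.null(panel_a) || nrow(panel_a) == 0L) return(panel_b)
  hybrid <- rbind(panel_a, panel_b)
  dup <- hybrid$name[duplicated(hybrid$name)]
  if (length(dup)) {
    stop("namespace error: duplicate tagged names after merge: ",
         paste(unique(dup), collapse = ", "))
  }
  rownames(hybrid) <- NULL
  hybrid
}

#' Parse species tags from tagged gene names
#'
#' The species tag is the prefix before the first hyphen of the display
#' name. Names without a recognisable tag raise an error listing the
#' offenders.
#'
#' @param names Character vector of tagged display names.
#' @return Character vector of tags (`"hg38"` / `"ss11"`).
#' @export
species_tag_of <- function(names) {
  tags <- sub("-.*$", "", names)
  bad <- !(tags %in% SPECIES_TAGS) | !grepl("-", names, fixed = TRUE)
  if (any(bad)) {
    stop("features without a parseable species tag: ",
         paste(utils::head(names[bad], 10L), collapse = ", "),
         if (sum(bad) > 10L) sprintf(" (and %d more)", sum(bad) - 10L))
  }
  tags
}

#' Build a modified species-specific reference by the cross-mapping rule
#'
#' Given one species' gene panel and a count matrix from a sample known to
#' contain only cells of the *opposite* species, sums counts assigned to
#' each own-panel gene across the whole sample and removes any gene whose
#' total exceeds `threshold` (strictly; the default 3 retains a gene with
#' exactly 3 cross-mapped counts and removes one with 4). Genes that an
#' opposite-species sample maps into are homology artifacts; removing them
#' yields a more species-specific reference.
#'
#' @param own_panel Gene panel ([gene_panel()]) of the species whose
#'   reference is being modified.
#' @param opposite_sample A tagged count matrix (genes x cells, see
#'   [read_tagged_matrix()]) of cells truly of the opposite species. Only
#'   rows matching `own_panel$name` contribute.
#' @param threshold Removal threshold on the summed cross-mapped counts
#'   (default 3; remove iff total > threshold).
#' @return An object of class `modified_reference`: a list with `species`
#'   (tag), `retained` (character gene ids), `removed` (`data.frame` with
#'   `gene_id`, `symbol`, `name`, `opposite_species_count`), `threshold`.
#' @export
build_modified_reference <- function(own_panel, opposite_sample,
                                     threshold = 3) {
  stopifnot(is.data.frame(own_panel), nrow(own_panel) > 0)
  if (is.null(opposite_sample) || ncol(opposite_sample) == 0L) {
    warning("empty opposite-species sample: all genes retained")
    cross <- stats::setNames(numeric(nrow(own_panel)), own_panel$name)
  } else {
    totals <- Matrix::rowSums(opposite_sample)
    cross <- stats::setNames(numeric(nrow(own_panel)), own_panel$name)
    hit <- intersect(own_panel$name, names(totals))
    cross[hit] <- totals[hit]
  }
  removed_idx <- which(cross > threshold)
  removed <- data.frame(
    gene_id = own_panel$gene_id[removed_idx],
    symbol = own_panel$symbol[removed_idx],
    name = own_panel$name[removed_idx],
    opposite_species_count = unname(cross[removed_idx]),
    stringsAsFactors = FALSE
  )
  removed <- removed[order(-removed$opposite_species_count,
                           removed$gene_id), , drop = FALSE]
  rownames(removed) <- NULL
  structure(
    list(
      species = own_panel$species_tag[1L],
      retained = own_panel$gene_id[setdiff(seq_len(nrow(own_panel)),
                                           removed_idx)],
      retained_names = own_panel$name[setdiff(seq_len(nrow(own_panel)),
                                              removed_idx)],
      removed = removed,
      threshold = threshold,
      panel_size = nrow(own_panel)
    ),
    class = "modified_reference"
  )
}

#' @export
print.modified_reference <- function(x, ...) {
  cat(sprintf(
    "modified_reference [%s]: %d/%d genes retained, %d removed (>%g cross-mapped counts)\n",
    x$species, length(x$retained), x$panel_size, nrow(x$removed),
    x$threshold))
  invisible(x)
}

#' Write the removed-gene report of a modified reference as CSV
#'
#' @param modref A `modified_reference` from [build_modified_reference()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_modified_reference_report <- function(modref, path) {
  rep <- modref$removed
  rep$species <- modref$species
  utils::write.csv(
    rep[, c("gene_id", "symbol", "species", "opposite_species_count")],
    path, row.names = FALSE)
  invisible(path)
}
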