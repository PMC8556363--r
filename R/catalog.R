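#' Read a driver-mutation catalog
#'
#' The catalog lists one row per *driver mutation type* — a (gene or locus,
#' mutation class) pair. Classes are `CNA_gain`, `CNA_loss`, `SNV` (coding),
#' `ncSNV` (non-coding) and `SV`. Each row carries the genomic footprint used
#' by the burden-weighted null: `snv_footprint_mbp` (coding footprint, Mbp)
#' for SNV classes and the gene span `start_bp`/`end_bp` (0-based half-open,
#' bp) for CNA/SV classes. Optional columns:
#'
#' * `pooled_loci` — auxiliary intervals (`"chrX:100-200;chr2:5-10"`) whose
#'   hits count toward the entry, e.g. an upstream enhancer pooled with the
#'   gene body.
#' * `sv_subtype_filter` — comma-separated SV subtypes the entry is
#'   restricted to (e.g. `"inversion"`); empty means any subtype counts.
#'
#' @param path Path to a tab-separated catalog file with a header row.
#' @return A tibble of validated catalog entries with one row per mutation
#'   type, a `mutation_type` id column (`"GENE:class"`), and
#'   `cna_footprint_bp = end_bp - start_bp`.
#' @export
#' @examples
#' path <- system.file("extdata", "driver_catalog_synthetic.tsv",
#'   package = "driverdelta"
#' )
#' read_driver_catalog(path)
read_driver_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("catalog file not found: ", path))
  raw <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    comment = "#"),
    error = function(e) abort(paste0("catalog parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  if (nrow(raw) == 0) abort(paste0("catalog file is empty: ", path))
  validate_driver_catalog(raw)
}

#' Validate a driver catalog tibble
#'
#' Applies the same checks as [read_driver_catalog()] to an in-memory table;
#' useful for synthetic catalogs built in code.
#'
#' @param catalog A data frame with at least `gene_id`, `class`,
#'   `chromosome`, `start_bp`, `end_bp`; `snv_footprint_mbp` is required for
#'   SNV/ncSNV rows.
#' @return A validated catalog tibble (see [read_driver_catalog()]).
#' @export
validate_driver_catalog <- function(catalog) {
  catalog <- as_tibble(catalog)
  required <- c("gene_id", "class", "chromosome", "start_bp", "end_bp")
  missing <- setdiff(required, names(catalog))
  if (length(missing) > 0) {
    abort(paste0("catalog is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"label" %in% names(catalog)) catalog$label <- catalog$gene_id
  if (!"snv_footprint_mbp" %in% names(catalog)) {
    catalog$snv_footprint_mbp <- NA_real_
  }
  if (!"pooled_loci" %in% names(catalog)) catalog$pooled_loci <- NA_character_
  if (!"sv_subtype_filter" %in% names(catalog)) {
    catalog$sv_subtype_filter <- NA_character_
  }

  bad_class <- setdiff(unique(catalog$class), mutation_classes())
  if (length(bad_class) > 0) {
    abort(paste0("unknown mutation class(es): ",
                 paste(bad_class, collapse = ", ")))
  }
  dup <- catalog %>%
    count(.data$gene_id, .data$class) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate gene_id x class entries: ",
                 paste(mutation_type_id(dup$gene_id, dup$class),
                       collapse = ", ")))
  }

  catalog <- catalog %>%
    mutate(
      start_bp = as.integer(.data$start_bp),
      end_bp = as.integer(.data$end_bp),
      cna_footprint_bp = .data$end_bp - .data$start_bp,
      mutation_type = mutation_type_id(.data$gene_id, .data$class)
    )

  cna_rows <- catalog$class %in% c("CNA_gain", "CNA_loss", "SV")
  if (any(cna_rows & (is.na(catalog$cna_footprint_bp) |
                        catalog$cna_footprint_bp <= 0))) {
    offenders <- catalog$mutation_type[cna_rows &
      (is.na(catalog$cna_footprint_bp) | catalog$cna_footprint_bp <= 0)]
    abort(paste0("non-positive genomic footprint for: ",
                 paste(offenders, collapse = ", ")))
  }
  snv_rows <- catalog$class %in% c("SNV", "ncSNV")
  if (any(snv_rows & (is.na(catalog$snv_footprint_mbp) |
                        catalog$snv_footprint_mbp <= 0))) {
    offenders <- catalog$mutation_type[snv_rows &
      (is.na(catalog$snv_footprint_mbp) | catalog$snv_footprint_mbp <= 0)]
    abort(paste0("missing or non-positive snv_footprint_mbp for: ",
                 paste(offenders, collapse = ", ")))
  }
  # parse pooled loci eagerly so malformed intervals fail at load time
  purrr::walk(catalog$pooled_loci, parse_loci)

  catalog %>%
    select(
      "mutation_type", "gene_id", "label", "class", "chromosome",
      "start_bp", "end_bp", "cna_footprint_bp", "snv_footprint_mbp",
      "pooled_loci", "sv_subtype_filter"
    )
}
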