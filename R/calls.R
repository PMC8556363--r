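# Reading and harmonizing raw somatic call tables: CNA segments (SEG),
# SNVs (MAF-like TSV), SVs (BEDPE-like TSV).

#' Normalize a copy-number call to gain / neutral / loss
#'
#' Harmonizes the two CNA call dialects the pipeline ingests:
#'
#' * categorical calls — `"deep deletion"` and `"shallow deletion"` pool to
#'   `loss`; `"gain"` and `"amplification"` pool to `gain`; `"neutral"` stays
#'   `neutral`;
#' * numeric log2 copy-number scores — thresholded with boundaries
#'   inclusive: autosomes call `gain` at score >= 3 and `loss` at <= 1.65;
#'   allosomes (chrX/chrY) call `gain` at >= 1.4 and `loss` at <= 0.6.
#'
#' `NaN`/`NA` scores return `NA` (not assayed). Unknown categories error.
#'
#' @param raw Character vector of categorical calls, or numeric vector of
#'   log2 copy-number scores.
#' @param chromosome_class `"autosome"` or `"allosome"`, recycled along
#'   `raw`. Only consulted for numeric input.
#' @return Character vector in `{"gain", "neutral", "loss"}` (or `NA`).
#' @export
#' @examples
#' normalize_cna_call(c("shallow deletion", "amplification", "neutral"))
#' normalize_cna_call(c(1.65, 3, 2.2), "autosome")
#' normalize_cna_call(1.0, "allosome")
normalize_cna_call <- function(raw, chromosome_class = "autosome") {
  if (is.numeric(raw)) {
    chromosome_class <- rep_len(chromosome_class, length(raw))
    bad <- !chromosome_class %in% c("autosome", "allosome")
    if (any(bad)) {
      abort(paste0("unknown chromosome_class: ",
                   paste(unique(chromosome_class[bad]), collapse = ", ")))
    }
    gain_at <- ifelse(chromosome_class == "allosome", 1.4, 3)
    loss_at <- ifelse(chromosome_class == "allosome", 0.6, 1.65)
    out <- dplyr::case_when(
      is.na(raw) | is.nan(raw) ~ NA_character_,
      raw >= gain_at ~ "gain",
      raw <= loss_at ~ "loss",
      TRUE ~ "neutral"
    )
    return(out)
  }
  raw_norm <- tolower(trimws(as.character(raw)))
  map <- c(
    "deep deletion" = "loss", "shallow deletion" = "loss",
    "homozygous deletion" = "loss", "hetloss" = "loss", "loss" = "loss",
    "neutral" = "neutral", "diploid" = "neutral",
    "gain" = "gain", "amplification" = "gain"
  )
  unknown <- !is.na(raw_norm) & !raw_norm %in% names(map)
  if (any(unknown)) {
    abort(paste0("unknown CNA call category: ",
                 paste(unique(raw_norm[unknown]), collapse = ", ")))
  }
  out <- unname(map[raw_norm])
  out[is.na(raw_norm)] <- NA_character_
  out
}

#' Decide whether a variant consequence counts as a driver coding SNV
#'
#' Keeps missense, nonsense (stop gained/lost) and splice donor/acceptor
#' variants; everything else — including frameshift indels and synonymous
#' changes — is excluded. Common MAF-dialect spellings
#' (`Missense_Mutation`, `Nonsense_Mutation`, `Nonstop_Mutation`,
#' `Splice_Site`) are recognized. Unrecognized terms are conservatively
#' excluded with a warning.
#'
#' @param consequence Character vector of consequence terms.
#' @return Logical vector: `TRUE` where the call should be retained.
#' @export
#' @examples
#' filter_snv_consequence(c("missense", "frameshift_variant", "Splice_Site"))
filter_snv_consequence <- function(consequence) {
  norm <- tolower(trimws(as.character(consequence)))
  include <- c(
    "missense", "missense_variant", "missense_mutation",
    "stop_gained", "nonsense", "nonsense_mutation",
    "stop_lost", "nonstop_mutation",
    "splice_donor", "splice_donor_variant",
    "splice_acceptor", "splice_acceptor_variant", "splice_site"
  )
  exclude <- c(
    "synonymous", "synonymous_variant", "silent",
    "frameshift", "frameshift_variant", "frameshift_indel",
    "frame_shift_del", "frame_shift_ins",
    "in_frame_del", "in_frame_ins", "inframe_deletion", "inframe_insertion",
    "intron_variant", "intron", "5'utr", "3'utr", "utr",
    "upstream_gene_variant", "downstream_gene_variant",
    "start_lost", "translation_start_site", "igr", "rna", "5'flank", "3'flank"
  )
  out <- norm %in% include
  unknown <- !is.na(norm) & !norm %in% c(include, exclude)
  if (any(unknown)) {
    warn(paste0(
      "unrecognized consequence term(s) excluded: ",
      paste(unique(norm[unknown]), collapse = ", ")
    ))
  }
  out[is.na(norm)] <- FALSE
  out
}

#' Read a SEG file of copy-number segments
#'
#' SEG coordinates are 1-based inclusive; they are converted to the
#' package's internal 0-based half-open convention on read. The value
#' column may be a log2 copy-number score (normalized via
#' [normalize_cna_call()] with allosome-aware thresholds) or a categorical
#' call column named `call`.
#'
#' @param path Path to a tab-separated SEG file with columns `sample_id`,
#'   `chrom`, `start`, `end` and either `log2` or `call`.
#' @return Tibble with `sample_id`, `chrom`, `start`, `end` (0-based
#'   half-open) and `call` in `{"gain","neutral","loss"}`.
#' @export
read_seg <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "chrom", "start", "end")
  missing <- setdiff(required, names(seg))
  if (length(missing) > 0) {
    abort(paste0("SEG file missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  seg <- seg %>%
    mutate(start = as.integer(.data$start) - 1L, end = as.integer(.data$end))
  if ("call" %in% names(seg)) {
    seg$call <- normalize_cna_call(seg$call)
  } else if ("log2" %in% names(seg)) {
    seg$call <- normalize_cna_call(seg$log2, chromosome_class(seg$chrom))
  } else {
    abort("SEG file needs a 'log2' or 'call' column")
  }
  seg %>% select("sample_id", "chrom", "start", "end", "call")
}

#' Read a MAF-like SNV table
#'
#' Expects tab-separated columns `sample_id`, `gene` (Hugo symbol or
#' catalog locus id) and `consequence`; applies the driver consequence
#' filter ([filter_snv_consequence()]).
#'
#' @param path Path to the TSV file.
#' @param apply_filter Apply the consequence filter (default `TRUE`).
#' @return Tibble of retained calls (`sample_id`, `gene`, `consequence`).
#' @export
read_snv_calls <- function(path, apply_filter = TRUE) {
  snv <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "gene", "consequence")
  missing <- setdiff(required, names(snv))
  if (length(missing) > 0) {
    abort(paste0("SNV file missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (apply_filter) snv <- snv[filter_snv_consequence(snv$consequence), ]
  as_tibble(snv)
}

#' Read a BEDPE-like structural-variant table
#'
#' Expects tab-separated columns `sample_id`, `chrom1`, `start1`, `end1`,
#' `chrom2`, `start2`, `end2`, `sv_type` (0-based half-open breakpoint
#' intervals, BEDPE convention).
#'
#' @param path Path to the TSV file.
#' @return Tibble of SV calls.
#' @export
read_sv_calls <- function(path) {
  sv <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "chrom1", "start1", "end1",
                "chrom2", "start2", "end2", "sv_type")
  missing <- setdiff(required, names(sv))
  if (length(missing) > 0) {
    abort(paste0("SV file missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  as_tibble(sv)
}

#' Read a clinical / sample table
#'
#' @param path TSV with at least `sample_id`, `cohort`, `state`
#'   (`localized` or `mCRPC`), `snv_burden_per_mbp`, `pga`,
#'   `assayed_classes` (comma-separated subset of `CNA,SNV,ncSNV,SV`);
#'   optional clinical covariates (`psa`, `isup_grade`, `ct_category`).
#' @return Validated sample tibble.
#' @export
read_samples <- function(path) {
  samples <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_samples(samples)
}

#' Validate a sample table built in code
#' @param samples Data frame of per-sample records (see [read_samples()]).
#' @return The validated tibble.
#' @export
validate_samples <- function(samples) {
  samples <- as_tibble(samples)
  required <- c("sample_id", "state", "snv_burden_per_mbp", "pga",
                "assayed_classes")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    abort(paste0("sample table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id values")
  if (!all(samples$state %in% c("localized", "mCRPC"))) {
    abort("state must be 'localized' or 'mCRPC'")
  }
  with_pga <- !is.na(samples$pga)
  if (any(samples$pga[with_pga] < 0 | samples$pga[with_pga] > 1)) {
    abort("pga must lie in [0, 1]")
  }
  with_burden <- !is.na(samples$snv_burden_per_mbp)
  if (any(samples$snv_burden_per_mbp[with_burden] < 0)) {
    abort("snv_burden_per_mbp must be non-negative")
  }
  samples
}
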