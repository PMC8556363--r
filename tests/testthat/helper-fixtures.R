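# Small fixtures built in code, shared across test files.

# a 3-sample, 2-gene sample table with full assay coverage
toy_samples <- function(n_loc = 2, n_met = 1,
                        assayed = "CNA,SNV,ncSNV,SV") {
  states <- c(rep("localized", n_loc), rep("mCRPC", n_met))
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_along(states)),
    cohort = "toy",
    state = states,
    snv_burden_per_mbp = 1,
    pga = 0.05,
    assayed_classes = assayed
  )
}

# minimal catalog: one gene per class plus an enhancer-pooled gain and a
# subtype-split SV pair
toy_catalog <- function() {
  validate_driver_catalog(tibble::tibble(
    gene_id = c("AR", "TSG", "ONC", "NC1", "PTEN_ITX", "PTEN_INV"),
    class = c("CNA_gain", "CNA_loss", "SNV", "ncSNV", "SV", "SV"),
    chromosome = c("chrX", "chr17", "chr8", "chr14", "chr10", "chr10"),
    start_bp = c(1000L, 5000L, 2000L, 7000L, 100000L, 100000L),
    end_bp = c(2000L, 6000L, 3000L, 8000L, 200000L, 200000L),
    snv_footprint_mbp = c(NA, NA, 0.002, 0.001, NA, NA),
    pooled_loci = c("chrX:500-600", NA, NA, NA, NA, NA),
    sv_subtype_filter = c(NA, NA, NA, NA, "translocation,deletion",
                          "inversion")
  ))
}

# build a mutation matrix directly from a wide tibble of cells
manual_matrix <- function(sample_id, ...) {
  tibble::tibble(sample_id = sample_id, ...)
}

# write a catalog tibble to a temp TSV, return the path
write_catalog_tsv <- function(catalog) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(catalog, path, na = "NA", progress = FALSE)
  path
}

# a catalog with the canonical class composition (31 + 43 + 6 + 33 rows)
full_size_catalog <- function() {
  counts <- c(CNA = 31L, SNV = 43L, ncSNV = 6L, SV = 33L)
  classes <- c(
    rep(c("CNA_gain", "CNA_loss"), length.out = counts["CNA"]),
    rep("SNV", counts["SNV"]), rep("ncSNV", counts["ncSNV"]),
    rep("SV", counts["SV"])
  )
  idx <- seq_along(classes)
  tibble::tibble(
    gene_id = sprintf("D%03d", idx),
    class = classes,
    chromosome = "chr1",
    start_bp = idx * 10000L,
    end_bp = idx * 10000L + 5000L,
    snv_footprint_mbp = ifelse(classes %in% c("SNV", "ncSNV"), 0.002,
                               NA_real_)
  )
}
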