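# Shared small helpers: assay-class bookkeeping, interval parsing, seeds.

# mutation classes carried in the catalog -> assay platform class that must
# be available on a sample for the cell to be scored at all
assay_class_of <- function(mclass) {
  unname(c(
    CNA_gain = "CNA", CNA_loss = "CNA",
    SNV = "SNV", ncSNV = "ncSNV", SV = "SV"
  )[mclass])
}

mutation_classes <- function() c("CNA_gain", "CNA_loss", "SNV", "ncSNV", "SV")

# class buckets used when combining a gene's mutation types (coding and
# non-coding SNVs share the SNV bucket for per-gene union prevalence)
class_bucket_of <- function(mclass) {
  unname(c(
    CNA_gain = "CNA", CNA_loss = "CNA",
    SNV = "SNV", ncSNV = "SNV", SV = "SV"
  )[mclass])
}

#' @noRd
has_assay_class <- function(assayed_classes, class) {
  vapply(
    strsplit(assayed_classes, ",", fixed = TRUE),
    function(x) class %in% trimws(x),
    logical(1)
  )
}

mutation_type_id <- function(gene_id, mclass) paste(gene_id, mclass, sep = ":")

split_mutation_type <- function(mutation_type) {
  parts <- stringr::str_split_fixed(mutation_type, stringr::fixed(":"), 2)
  tibble(gene_id = parts[, 1], class = parts[, 2])
}

# "chr1:100-200;chr2:5-10" -> tibble(chrom, start, end), 0-based half-open
parse_loci <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  pieces <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  m <- stringr::str_match(pieces, "^([^:]+):(\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) {
    abort(paste0("malformed locus specification: ", pieces[is.na(m[, 1])][1]))
  }
  tibble(
    chrom = m[, 2],
    start = as.integer(m[, 3]),
    end = as.integer(m[, 4])
  )
}

# half-open interval overlap of >= 1 bp
intervals_overlap <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}

# deterministic, order-independent substream seed for the i-th (sorted)
# mutation type under a base seed; kept below 2^31
substream_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) + 7919 * as.numeric(index)) %% 2147483647)
}

chromosome_class <- function(chrom) {
  ifelse(sub("^chr", "", chrom) %in% c("X", "Y"), "allosome", "autosome")
}
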