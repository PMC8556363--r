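# Per-sample burden and prognostic scores: percent genome altered (PGA),
# the six-feature clinico-genomic signature, the cell-cycle-progression
# (CCP) expression score, Youden-J dichotomization, RNA stratification.

#' Percent of the genome altered by copy-number aberrations
#'
#' Sum of bases covered by the union of altered segments divided by the
#' genome size. With `exclude_chromosome`, both numerator and denominator
#' omit that chromosome (the denominator drops its length from
#' `chrom_sizes`), keeping the adjusted PGA a true proportion — the form
#' used when testing a CNA against PGA without counting the gene's own
#' chromosome.
#'
#' Overlapping segments are merged internally, so splitting or reordering
#' segments never changes the result.
#'
#' @param segments Tibble with `chrom`, `start`, `end` (0-based half-open
#'   bp) of altered segments for one sample.
#' @param genome_size_bp Total genome size in bp (default 3e9).
#' @param exclude_chromosome Optional chromosome name to omit.
#' @param chrom_sizes Named vector of chromosome lengths in bp; required
#'   when `exclude_chromosome` is given.
#' @return PGA as a real in `[0, 1]`.
#' @export
#' @examples
#' segs <- tibble::tibble(chrom = "chr1", start = c(0, 50), end = c(100, 150))
#' pga(segs, genome_size_bp = 1000) # union is 150 bp -> 0.15
pga <- function(segments, genome_size_bp = 3e9, exclude_chromosome = NULL,
                chrom_sizes = NULL) {
  segments <- as_tibble(segments)
  if (nrow(segments) > 0 && any(segments$end < segments$start)) {
    abort("negative-length segment")
  }
  denom <- genome_size_bp
  if (!is.null(exclude_chromosome)) {
    if (is.null(chrom_sizes) || !exclude_chromosome %in% names(chrom_sizes)) {
      abort("chrom_sizes with the excluded chromosome is required")
    }
    denom <- genome_size_bp - unname(chrom_sizes[exclude_chromosome])
    segments <- segments %>% filter(.data$chrom != exclude_chromosome)
  }
  if (denom <= 0) abort("non-positive genome size after exclusion")
  if (nrow(segments) == 0) return(0)
  altered <- sum(vapply(
    split(segments, segments$chrom),
    function(s) interval_union_width(s$start, s$end),
    numeric(1)
  ))
  altered / denom
}

# total width of the union of half-open intervals: sorted sweep
interval_union_width <- function(start, end) {
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  total <- 0
  cur_start <- start[1]
  cur_end <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_end) {
      cur_end <- max(cur_end, end[i])
    } else {
      total <- total + (cur_end - cur_start)
      cur_start <- start[i]
      cur_end <- end[i]
    }
  }
  total + (cur_end - cur_start)
}

#' Six-feature clinico-genomic signature score
#'
#' Scores each sample on six adverse features: MYC gain, ATM SNV, an
#' inter-chromosomal translocation at the chr7:61 Mbp locus, TCERGL1
#' promoter hypomethylation (below the cohort median beta), ACTL6B
#' hypermethylation (above the cohort median beta), and clinical T
#' category (cT2c scores 1; cT1 and cT2a/b score 0). The score is the
#' integer sum 0–6, used as such in regression; a median-dichotomized
#' `bin` (high/low) is provided for display. Samples missing any feature
#' are flagged non-informative and receive `NA` scores.
#'
#' @param features Tibble with columns `sample_id`, `myc_gain`, `atm_snv`,
#'   `chr7_sv` (0/1), `tcergl1_beta`, `actl6b_beta` (methylation beta
#'   values), `ct_category` (`"cT1"`, `"cT2a/b"`, `"cT2c"`).
#' @return Tibble: `sample_id`, the six 0/1 flags, `score`, `bin`,
#'   `informative`.
#' @export
fraser_signature <- function(features) {
  features <- as_tibble(features)
  required <- c("sample_id", "myc_gain", "atm_snv", "chr7_sv",
                "tcergl1_beta", "actl6b_beta", "ct_category")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0) {
    abort(paste0("features missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_ct <- !is.na(features$ct_category) &
    !features$ct_category %in% c("cT1", "cT2a/b", "cT2c")
  if (any(bad_ct)) abort("ct_category must be cT1, cT2a/b or cT2c")

  informative <- complete.cases(features[required])
  med_tcergl1 <- median(features$tcergl1_beta[informative])
  med_actl6b <- median(features$actl6b_beta[informative])

  out <- features %>%
    mutate(
      f_myc_gain = as.integer(.data$myc_gain == 1),
      f_atm_snv = as.integer(.data$atm_snv == 1),
      f_chr7_sv = as.integer(.data$chr7_sv == 1),
      f_tcergl1_hypo = as.integer(.data$tcergl1_beta < med_tcergl1),
      f_actl6b_hyper = as.integer(.data$actl6b_beta > med_actl6b),
      f_ct2c = as.integer(.data$ct_category == "cT2c"),
      informative = informative
    ) %>%
    mutate(score = .data$f_myc_gain + .data$f_atm_snv + .data$f_chr7_sv +
             .data$f_tcergl1_hypo + .data$f_actl6b_hyper + .data$f_ct2c)
  out$score[!out$informative] <- NA_integer_
  med_score <- median(out$score[out$informative])
  out %>%
    mutate(bin = case_when(
      !.data$informative ~ NA_character_,
      .data$score > med_score ~ "high",
      TRUE ~ "low"
    )) %>%
    select("sample_id", dplyr::starts_with("f_"), "score", "bin",
           "informative")
}

#' Cell-cycle-progression (CCP) expression score
#'
#' Mean log2 abundance of the CCP gene set minus the mean log2 abundance
#' of the housekeeping set, per sample. Invariant under adding a constant
#' to every gene's abundance.
#'
#' @param expression Long tibble: `sample_id`, `gene`, `log2_abundance`.
#' @param ccp_genes Character vector of CCP gene ids (canonically 31).
#' @param housekeeping_genes Character vector of housekeeping gene ids
#'   (canonically 15).
#' @return Tibble: `sample_id`, `ccp_score`.
#' @export
ccp_score <- function(expression, ccp_genes, housekeeping_genes) {
  expression <- as_tibble(expression)
  per_sample <- expression %>%
    filter(.data$gene %in% c(ccp_genes, housekeeping_genes)) %>%
    group_by(.data$sample_id)
  check <- per_sample %>%
    summarise(missing = list(setdiff(c(ccp_genes, housekeeping_genes),
                                     .data$gene)), .groups = "drop") %>%
    filter(lengths(.data$missing) > 0)
  if (nrow(check) > 0) {
    abort(paste0("sample ", check$sample_id[1], " is missing gene(s): ",
                 paste(head(check$missing[[1]], 5), collapse = ", ")))
  }
  per_sample %>%
    summarise(
      ccp_score = mean(.data$log2_abundance[.data$gene %in% ccp_genes]) -
        mean(.data$log2_abundance[.data$gene %in% housekeeping_genes]),
      .groups = "drop"
    )
}

#' Optimal dichotomization threshold by Youden's J
#'
#' Scans every observed value as a candidate threshold and returns the one
#' maximizing `J = sensitivity + specificity - 1`. Both orientations are
#' considered (cases above or below the threshold); ties are broken toward
#' the lower threshold.
#'
#' @param values Numeric vector.
#' @param outcome Binary vector (0/1 or logical) of the same length; both
#'   classes must be present.
#' @param direction `">"` (cases are high), `"<"` (cases are low) or
#'   `"auto"` (pick the orientation with the larger J).
#' @return List with `threshold` (classify as positive strictly beyond
#'   it), `j`, and `direction`.
#' @export
youden_cutpoint <- function(values, outcome, direction = "auto") {
  outcome <- as.integer(as.logical(outcome))
  if (length(unique(outcome)) < 2) abort("both outcome classes required")
  if (length(unique(values)) < 2) abort("values are constant")
  candidates <- sort(unique(values))
  n_pos <- sum(outcome == 1)
  n_neg <- sum(outcome == 0)

  j_for <- function(dir) {
    vapply(candidates, function(t) {
      pred <- if (dir == ">") values > t else values < t
      sum(pred & outcome == 1) / n_pos + sum(!pred & outcome == 0) / n_neg - 1
    }, numeric(1))
  }
  dirs <- if (direction == "auto") c(">", "<") else direction
  best <- purrr::map(dirs, function(d) {
    j <- j_for(d)
    k <- which(j == max(j))[1] # ties toward the lower threshold
    list(threshold = candidates[k], j = j[k], direction = d)
  })
  best[[which.max(purrr::map_dbl(best, "j"))]]
}

#' Stratify samples by expression level
#'
#' Median dichotomization (`low`/`high`, values equal to the median go to
#' `low`) or quartile stratification (`Q1`–`Q4`, boundary ties to the
#' lower bin).
#'
#' @param values Numeric vector of (log2) abundances.
#' @param scheme `"median"` or `"quartile"`.
#' @return Factor of bin labels aligned with `values`.
#' @export
stratify_abundance <- function(values, scheme = c("median", "quartile")) {
  scheme <- match.arg(scheme)
  if (length(unique(values)) == 1) {
    warn("all values tied; single stratum returned")
    lab <- if (scheme == "median") "low" else "Q1"
    return(factor(rep(lab, length(values)),
                  levels = if (scheme == "median") c("low", "high")
                           else paste0("Q", 1:4)))
  }
  if (scheme == "median") {
    med <- median(values)
    factor(if_else(values <= med, "low", "high"), levels = c("low", "high"))
  } else {
    if (length(values) < 4) abort("quartile scheme needs n >= 4")
    breaks <- unique(quantile(values, probs = c(0, 0.25, 0.5, 0.75, 1)))
    cut(values, breaks = breaks, include.lowest = TRUE, right = TRUE,
        labels = paste0("Q", seq_len(length(breaks) - 1)))
  }
}
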