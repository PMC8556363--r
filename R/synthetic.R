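# Synthetic cohorts with the statistical structure the analysis assumes:
# two disease states with distinct SNV-burden and PGA distributions, a
# driver catalog with genomic footprints, planted enrichment effects
# beyond the burden null, and outcome times whose hazards depend on
# planted mutations. The planted truth is stored alongside the data and
# never consumed by the pipeline under test.

#' Synthetic cohort configuration
#'
#' Defaults emulate the field's observed structure: localized tumors
#' around 1 SNV/Mbp and ~5% PGA, metastatic castration-resistant (mCRPC)
#' tumors around 4 SNVs/Mbp and ~25% PGA, with log-normal burden and Beta
#' PGA distributions.
#'
#' @param n_localized,n_mcrpc Cohort sizes (defaults 200 / 100).
#' @param seed Global seed; every sub-generator derives a deterministic
#'   substream from it.
#' @param burden_meanlog Named vector (`localized`, `mCRPC`) of log-normal
#'   mean-log SNV burdens per Mbp.
#' @param burden_sdlog Log-normal sd-log, shared across states.
#' @param pga_shape1,pga_shape2 Named vectors of Beta shape parameters per
#'   state.
#' @param censoring_rate Target fraction of censored localized samples.
#' @param baseline_rate Baseline exponential event rate per month.
#' @param null A [null_model_config()] supplying the burden-null
#'   parameters the generator shares with the analysis.
#' @return List of class `drv_synth_config`.
#' @export
synthetic_config <- function(n_localized = 200L, n_mcrpc = 100L, seed = 1L,
                             burden_meanlog = c(localized = log(1.0),
                                                mCRPC = log(4.0)),
                             burden_sdlog = 0.5,
                             pga_shape1 = c(localized = 2, mCRPC = 5),
                             pga_shape2 = c(localized = 38, mCRPC = 15),
                             censoring_rate = 0.6,
                             baseline_rate = 0.01,
                             null = null_model_config()) {
  if (n_localized <= 0 || n_mcrpc <= 0) {
    abort("cohort sizes must be positive")
  }
  structure(
    list(
      n_localized = as.integer(n_localized), n_mcrpc = as.integer(n_mcrpc),
      seed = as.integer(seed), burden_meanlog = burden_meanlog,
      burden_sdlog = burden_sdlog, pga_shape1 = pga_shape1,
      pga_shape2 = pga_shape2, censoring_rate = censoring_rate,
      baseline_rate = baseline_rate, null = null
    ),
    class = "drv_synth_config"
  )
}

#' A small synthetic driver catalog
#'
#' Builds a validated catalog of `n_genes` loci cycling through the five
#' mutation classes, with realistic footprints (coding footprints of a few
#' kbp, gene spans of 0.05-2 Mbp). Gene ids are `G001`, `G002`, ... and
#' coordinates are deterministic bookkeeping, not real genome positions.
#'
#' @param n_genes Number of entries (default 12).
#' @param classes Classes to cycle through.
#' @return A validated driver catalog tibble.
#' @export
synthetic_driver_catalog <- function(n_genes = 12L,
                                     classes = mutation_classes()) {
  idx <- seq_len(n_genes)
  cls <- classes[((idx - 1) %% length(classes)) + 1]
  span <- as.integer(5e4 + (idx %% 7) * 3e5) # 0.05 - 1.85 Mbp
  start <- as.integer(1e6 + (idx - 1) * 5e6)
  validate_driver_catalog(tibble(
    gene_id = sprintf("G%03d", idx),
    label = sprintf("G%03d", idx),
    class = cls,
    chromosome = paste0("chr", ((idx - 1) %% 5) + 1),
    start_bp = start,
    end_bp = start + span,
    snv_footprint_mbp = ifelse(cls %in% c("SNV", "ncSNV"),
                               0.002 + (idx %% 4) * 0.002, NA_real_),
    pooled_loci = NA_character_,
    sv_subtype_filter = NA_character_
  ))
}

#' Planted truth for a synthetic catalog
#'
#' One row per catalog mutation type: `delta` is the excess per-sample hit
#' probability planted in mCRPC beyond the burden null (additive on the
#' probability scale, so a planted `delta` is directly comparable to an
#' adjusted prevalence difference), and `log_hr` the planted log hazard
#' ratio for the metastasis endpoint. Genes with `delta = 0` form the
#' null-calibration set.
#'
#' @param catalog A driver catalog.
#' @param delta Named vector of excess probabilities keyed by
#'   `mutation_type` (unnamed entries default to 0).
#' @param log_hr Named vector of log hazard ratios keyed by
#'   `mutation_type` (default 0).
#' @return Tibble: `mutation_type`, `delta`, `log_hr`.
#' @export
synthetic_truth <- function(catalog, delta = NULL, log_hr = NULL) {
  truth <- tibble(
    mutation_type = catalog$mutation_type,
    delta = 0, log_hr = 0
  )
  if (!is.null(delta)) {
    stopifnot(all(names(delta) %in% truth$mutation_type))
    truth$delta[match(names(delta), truth$mutation_type)] <- delta
  }
  if (!is.null(log_hr)) {
    stopifnot(all(names(log_hr) %in% truth$mutation_type))
    truth$log_hr[match(names(log_hr), truth$mutation_type)] <- log_hr
  }
  truth
}

#' Generate per-sample records
#'
#' Draws per-sample SNV burden (log-normal) and PGA (Beta) from
#' state-specific distributions, plus simple clinical covariates (PSA,
#' ISUP grade, clinical T category). All classes are marked assayed by
#' default.
#'
#' @param config A [synthetic_config()].
#' @param assayed_classes Comma-separated assay classes given to every
#'   sample (restrict to emulate partial assay availability).
#' @return Validated sample tibble.
#' @export
generate_samples <- function(config, assayed_classes = "CNA,SNV,ncSNV,SV") {
  set.seed(substream_seed(config$seed, 1))
  states <- c(rep("localized", config$n_localized),
              rep("mCRPC", config$n_mcrpc))
  n <- length(states)
  burden <- rlnorm(n, meanlog = config$burden_meanlog[states],
                   sdlog = config$burden_sdlog)
  pga <- rbeta(n, config$pga_shape1[states], config$pga_shape2[states])
  validate_samples(tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    cohort = ifelse(states == "localized", "SYN-LOC", "SYN-MET"),
    state = states,
    snv_burden_per_mbp = burden,
    pga = pga,
    assayed_classes = assayed_classes,
    psa = round(rlnorm(n, log(8), 0.6), 1),
    isup_grade = sample(1:5, n, replace = TRUE,
                        prob = c(0.25, 0.35, 0.2, 0.12, 0.08)),
    ct_category = sample(c("cT1", "cT2a/b", "cT2c"), n, replace = TRUE,
                         prob = c(0.45, 0.4, 0.15))
  ))
}

#' Plant mutations into a cohort
#'
#' Each sample-by-mutation-type cell is present with probability
#' `min(1, p_null + delta * [state == mCRPC])`, where `p_null` is the
#' burden-null hit probability ([per_sample_hit_probability()]) under
#' `config$null` and `delta` the planted excess. Cells of unassayed
#' classes are `NA`. Probabilities exceeding 1 after planting are clipped
#' with a warning.
#'
#' @param samples Sample tibble ([generate_samples()]).
#' @param catalog Driver catalog.
#' @param truth Planted truth ([synthetic_truth()]).
#' @param config A [synthetic_config()].
#' @return A mutation matrix tibble.
#' @export
plant_mutations <- function(samples, catalog, truth, config) {
  if (!all(catalog$mutation_type %in% truth$mutation_type)) {
    abort("truth must cover every catalog mutation type")
  }
  set.seed(substream_seed(config$seed, 2))
  if (nrow(catalog) == 0) return(tibble(sample_id = samples$sample_id))
  cells <- base::matrix(
    NA_integer_, nrow = nrow(samples), ncol = nrow(catalog),
    dimnames = list(samples$sample_id, catalog$mutation_type)
  )
  clipped <- FALSE
  for (j in seq_len(nrow(catalog))) {
    entry <- catalog[j, ]
    assayed <- has_assay_class(samples$assayed_classes,
                               assay_class_of(entry$class))
    p_null <- per_sample_hit_probability(samples, entry, entry$class,
                                         config$null)
    delta <- truth$delta[truth$mutation_type == entry$mutation_type]
    p <- p_null + delta * (samples$state == "mCRPC")
    if (any(p > 1)) clipped <- TRUE
    p <- pmin(1, p)
    draws <- as.integer(runif(nrow(samples)) < p)
    cells[assayed, j] <- draws[assayed]
  }
  if (clipped) warn("planted probabilities exceeded 1 and were clipped")
  bind_cols(tibble(sample_id = samples$sample_id), as_tibble(cells))
}

#' Generate survival outcomes with planted hazards
#'
#' Event times are exponential with per-sample rate
#' `baseline_rate * exp(sum of planted log hazard ratios over carried
#' mutations)`; censoring times are independent Uniform(0, b), with `b`
#' solved so the marginal censoring fraction under the baseline rate
#' matches `config$censoring_rate` (approximate when planted hazards
#' shift the event-time distribution).
#'
#' @param samples Sample tibble (outcomes are generated for the localized
#'   stratum).
#' @param matrix Mutation matrix covering the localized samples.
#' @param truth Planted truth with `log_hr` per mutation type.
#' @param config A [synthetic_config()].
#' @param endpoint Endpoint label for the records.
#' @return Tibble: `sample_id`, `endpoint`, `time_months`, `event`.
#' @export
generate_outcomes <- function(samples, matrix, truth, config,
                              endpoint = "metastasis") {
  set.seed(substream_seed(config$seed, 3))
  loc <- samples %>% filter(.data$state == "localized")
  mat <- matrix[match(loc$sample_id, matrix$sample_id), , drop = FALSE]

  hr_types <- truth$mutation_type[truth$log_hr != 0]
  loghr <- rep(0, nrow(loc))
  for (mt in intersect(hr_types, names(mat))) {
    carrier <- dplyr::coalesce(mat[[mt]], 0L)
    loghr <- loghr + truth$log_hr[truth$mutation_type == mt] * carrier
  }
  rate <- config$baseline_rate * exp(loghr)
  t_event <- rexp(nrow(loc), rate = rate)

  cens <- config$censoring_rate
  if (cens >= 1) {
    return(tibble(sample_id = loc$sample_id, endpoint = endpoint,
                  time_months = runif(nrow(loc), 1, 120), event = 0L))
  }
  if (cens <= 0) {
    time <- t_event
    event <- rep(1L, nrow(loc))
  } else {
    lam <- config$baseline_rate
    b <- uniroot(
      function(b) (1 - exp(-lam * b)) / (lam * b) - cens,
      lower = 1e-6, upper = 1e6, tol = 1e-9
    )$root
    t_cens <- runif(nrow(loc), 0, b)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  tibble(sample_id = loc$sample_id, endpoint = endpoint,
         time_months = pmax(time, 1e-6), event = event)
}

#' Generate coupled RNA abundance and promoter methylation
#'
#' For a designated target mutation type (a copy-number loss), log2 RNA
#' abundance is `baseline - shift * carrier - beta * M + noise` where `M`
#' is the promoter methylation M-value (standard normal, shifted up by
#' `meth_shift` in carriers). With the defaults the realized Spearman
#' correlation between RNA and methylation is approximately -0.4.
#'
#' @param samples Sample tibble.
#' @param matrix Mutation matrix containing `target`.
#' @param config A [synthetic_config()].
#' @param target Mutation-type column carrying the loss.
#' @param baseline Baseline log2 abundance (default 6.6).
#' @param shift Carrier RNA down-shift (default 0.3).
#' @param beta Methylation coefficient (default 0.4).
#' @param noise_sd Residual sd (default `sqrt(1 - 0.4^2)`, targeting
#'   rho ~= -0.4 for unit-variance methylation).
#' @param meth_shift Carrier methylation up-shift (default 0.5).
#' @return List with `expression` (`sample_id`, `gene`, `log2_abundance`)
#'   and `methylation` (`sample_id`, `m_value`).
#' @export
generate_expression_methylation <- function(samples, matrix, config,
                                            target,
                                            baseline = 6.6, shift = 0.3,
                                            beta = 0.4,
                                            noise_sd = sqrt(1 - 0.16),
                                            meth_shift = 0.5) {
  if (!target %in% names(matrix)) {
    abort(paste0("target mutation type not in matrix: ", target))
  }
  set.seed(substream_seed(config$seed, 4))
  mat <- matrix[match(samples$sample_id, matrix$sample_id), ]
  carrier <- dplyr::coalesce(mat[[target]], 0L)
  n <- nrow(samples)
  m_value <- rnorm(n) + meth_shift * carrier
  rna <- baseline - shift * carrier - beta * m_value + rnorm(n, 0, noise_sd)
  gene <- split_mutation_type(target)$gene_id
  list(
    expression = tibble(sample_id = samples$sample_id, gene = gene,
                        log2_abundance = rna),
    methylation = tibble(sample_id = samples$sample_id, m_value = m_value)
  )
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper running [generate_samples()], [plant_mutations()]
#' and [generate_outcomes()] under one seed.
#'
#' @param config A [synthetic_config()].
#' @param catalog Driver catalog (default [synthetic_driver_catalog()]).
#' @param truth Planted truth (default all-null [synthetic_truth()]).
#' @return List: `samples`, `matrix`, `outcomes`, `catalog`, `truth`.
#' @export
generate_cohort <- function(config = synthetic_config(),
                            catalog = synthetic_driver_catalog(),
                            truth = synthetic_truth(catalog)) {
  samples <- generate_samples(config)
  matrix <- plant_mutations(samples, catalog, truth, config)
  outcomes <- generate_outcomes(samples, matrix, truth, config)
  list(samples = samples, matrix = matrix, outcomes = outcomes,
       catalog = catalog, truth = truth)
}

#' Materialize raw call files from a planted matrix
#'
#' Emits the same file shapes the ingestion stage reads — SEG segments,
#' MAF-like SNV rows, BEDPE SV rows — such that rebuilding the matrix
#' from them reproduces the planted matrix exactly. Present CNA cells
#' become one segment covering the gene span; SNVs become missense calls;
#' SVs become a breakpoint pair at the locus.
#'
#' @param matrix A mutation matrix.
#' @param catalog The catalog it was planted from.
#' @return List of tibbles `cna`, `snv`, `sv` (the `calls` argument of
#'   [build_mutation_matrix()]).
#' @export
synthetic_calls_from_matrix <- function(matrix, catalog) {
  long <- matrix %>%
    tidyr::pivot_longer(-"sample_id", names_to = "mutation_type",
                        values_to = "cell") %>%
    filter(.data$cell == 1L) %>%
    inner_join(catalog, by = "mutation_type")

  cna <- long %>%
    filter(.data$class %in% c("CNA_gain", "CNA_loss")) %>%
    mutate(call = if_else(.data$class == "CNA_gain", "gain", "loss")) %>%
    select("sample_id", chrom = "chromosome", start = "start_bp",
           end = "end_bp", "call")
  snv <- long %>%
    filter(.data$class %in% c("SNV", "ncSNV")) %>%
    mutate(consequence = "missense") %>%
    select("sample_id", gene = "gene_id", "consequence", class = "class")
  sv <- long %>%
    filter(.data$class == "SV") %>%
    mutate(
      sv_type = purrr::map_chr(.data$sv_subtype_filter, function(f) {
        if (is.na(f) || !nzchar(f)) "translocation"
        else trimws(strsplit(f, ",")[[1]][1])
      }),
      chrom2 = "chrUn", start2 = 0L, end2 = 1000L
    ) %>%
    select("sample_id", chrom1 = "chromosome", start1 = "start_bp",
           end1 = "end_bp", "chrom2", "start2", "end2", "sv_type")
  list(cna = cna, snv = snv, sv = sv)
}

#' Write a synthetic cohort to disk
#'
#' Emits `segments.seg` (1-based inclusive SEG), `snv_calls.tsv`,
#' `sv_calls.tsv` (BEDPE-like), `clinical.tsv`, `outcomes.tsv`,
#' `catalog.tsv` and `truth.json` under `dir`.
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  calls <- synthetic_calls_from_matrix(cohort$matrix, cohort$catalog)
  seg_out <- calls$cna %>% mutate(start = .data$start + 1L) # SEG is 1-based
  readr::write_tsv(seg_out, file.path(dir, "segments.seg"), progress = FALSE)
  readr::write_tsv(calls$snv, file.path(dir, "snv_calls.tsv"),
                   progress = FALSE)
  readr::write_tsv(calls$sv, file.path(dir, "sv_calls.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$samples, file.path(dir, "clinical.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$outcomes, file.path(dir, "outcomes.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$catalog, file.path(dir, "catalog.tsv"),
                   progress = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
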