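# Burden-adjusted differential prevalence between mCRPC and localized
# disease: a per-sample binomial null weighted by global mutational burden
# (SNVs/Mbp or PGA), Monte-Carlo simulation of the expected prevalence
# difference, empirical p-values and BH-FDR.

#' Configuration for the burden-weighted binomial null
#'
#' @param n_iter Number of Monte-Carlo iterations (default 100000).
#' @param seed Base seed; each mutation type derives an independent,
#'   order-independent substream from it.
#' @param genome_mbp Genome size in Mbp used for whole-genome burdens and
#'   the CNA segment model (default 3000, i.e. 3 Gbp).
#' @param exome_mbp Coding-target size in Mbp for samples whose SNV burden
#'   was estimated from exome sequencing (default 45).
#' @param cna_segment_mbp Mean CNA segment length lambda in Mbp for the
#'   segment-process null (default 10): a sample with a given PGA is
#'   modelled as `M = max(1, round(pga * genome_mbp / lambda))` independent
#'   segments, each hitting a gene of span `g` bp with probability
#'   `(g / 1e6 + lambda) / genome_mbp`.
#' @return A list of class `drv_null_config`.
#' @export
null_model_config <- function(n_iter = 100000L, seed = 20211029L,
                              genome_mbp = 3000, exome_mbp = 45,
                              cna_segment_mbp = 10) {
  if (n_iter < 100) abort("n_iter must be >= 100")
  if (cna_segment_mbp <= 0) abort("cna_segment_mbp must be > 0")
  structure(
    list(
      n_iter = as.integer(n_iter), seed = as.integer(seed),
      genome_mbp = genome_mbp, exome_mbp = exome_mbp,
      cna_segment_mbp = cna_segment_mbp,
      p_floor = 1 / n_iter
    ),
    class = "drv_null_config"
  )
}

#' Per-sample probability of carrying a driver mutation under the null
#'
#' The probability that a sample's global mutational burden alone produces
#' at least one hit in the entry's footprint.
#'
#' For SNV classes: with burden `b` SNVs/Mbp over reference size `G` Mbp,
#' the sample carries `N = round(b * G)` variants, each landing in the
#' coding footprint `g` Mbp with probability `g / G`, so
#' `P_MUT = 1 - (1 - g/G)^N`. `G` is `config$genome_mbp` unless the sample
#' table carries a per-sample `snv_ref_mbp` column (e.g. `exome_mbp` for
#' exome-derived burdens).
#'
#' For CNA classes: the sample's PGA is converted to
#' `M = max(1, round(pga * genome_mbp / lambda))` segments of mean length
#' `lambda = config$cna_segment_mbp`; each segment hits the gene span `g`
#' bp with probability `(g/1e6 + lambda) / genome_mbp`, so
#' `P_MUT = 1 - (1 - p_seg)^M` (zero when PGA is zero).
#'
#' Computed in log space, vectorized over samples.
#'
#' @param samples Sample tibble (needs `snv_burden_per_mbp` and/or `pga`).
#' @param entry One catalog row (tibble with `snv_footprint_mbp`,
#'   `cna_footprint_bp`).
#' @param mclass Mutation class of the entry.
#' @param config A [null_model_config()].
#' @return Numeric vector of per-sample hit probabilities in `[0, 1]`.
#' @export
per_sample_hit_probability <- function(samples, entry, mclass,
                                       config = null_model_config()) {
  if (mclass %in% c("SNV", "ncSNV")) {
    g <- entry$snv_footprint_mbp[1]
    ref <- if ("snv_ref_mbp" %in% names(samples)) {
      dplyr::coalesce(samples$snv_ref_mbp, config$genome_mbp)
    } else {
      rep(config$genome_mbp, nrow(samples))
    }
    if (any(g > ref)) abort("SNV footprint exceeds reference size")
    burden <- samples$snv_burden_per_mbp
    n_var <- round(burden * ref)
    p_hit <- g / ref
    p_mut <- 1 - exp(n_var * log1p(-p_hit))
    p_mut[n_var == 0] <- 0
  } else if (mclass %in% c("CNA_gain", "CNA_loss", "SV")) {
    g_mbp <- entry$cna_footprint_bp[1] / 1e6
    lambda <- config$cna_segment_mbp
    if (g_mbp + lambda > config$genome_mbp) {
      abort("CNA footprint plus segment length exceeds genome size")
    }
    pga <- samples$pga
    m_seg <- pmax(1, round(pga * config$genome_mbp / lambda))
    p_seg <- (g_mbp + lambda) / config$genome_mbp
    p_mut <- 1 - exp(m_seg * log1p(-p_seg))
    p_mut[pga == 0] <- 0
  } else {
    abort(paste0("unknown mutation class: ", mclass))
  }
  pmin(pmax(p_mut, 0), 1)
}

#' Simulate the null distribution of the prevalence difference
#'
#' Each iteration draws one Bernoulli(`p_mut[i]`) indicator per sample and
#' records the simulated prevalence difference
#' (mCRPC minus localized). The mean over iterations is the expected
#' difference under burden alone.
#'
#' @param p_mut Per-sample hit probabilities, aligned with `states`.
#' @param states Character vector in `{"localized", "mCRPC"}`.
#' @param config A [null_model_config()]; `config$seed` (when non-NULL) is
#'   applied for reproducibility.
#' @return List with `expected_delta` and the vector `sim_deltas`.
#' @export
simulate_null <- function(p_mut, states, config = null_model_config()) {
  if (any(p_mut < 0 | p_mut > 1)) abort("p_mut values must lie in [0, 1]")
  is_met <- states == "mCRPC"
  m <- sum(is_met)
  n <- sum(!is_met)
  if (m == 0 || n == 0) abort("both disease states must be non-empty")
  if (!is.null(config$seed)) set.seed(config$seed)

  n_iter <- config$n_iter
  n_samp <- length(p_mut)
  sim_deltas <- numeric(n_iter)
  # chunked so memory stays ~ a few million doubles regardless of n_iter;
  # uniforms are drawn per sample in cohort order so that swapping the
  # state labels under the same seed negates every simulated delta exactly
  block <- max(1L, min(n_iter, as.integer(2^21 %/% max(1L, n_samp))))
  done <- 0L
  while (done < n_iter) {
    b <- min(block, n_iter - done)
    hits <- matrix(runif(b * n_samp), nrow = b) <
      matrix(p_mut, b, n_samp, byrow = TRUE)
    cnt_met <- rowSums(hits[, is_met, drop = FALSE])
    cnt_loc <- rowSums(hits[, !is_met, drop = FALSE])
    sim_deltas[(done + 1L):(done + b)] <- cnt_met / m - cnt_loc / n
    done <- done + b
  }
  list(expected_delta = mean(sim_deltas), sim_deltas = sim_deltas)
}

#' Empirical p-value against the simulated null
#'
#' Two-sided exceedance about the null mean: the fraction of simulated
#' differences at least as far from the null mean as the observed
#' difference. For CNA classes the exceedance is halved (a CNA can be
#' either a gain or a loss, and each direction is tested as its own
#' mutation type). The result is floored at `p_floor` (default
#' `1/n_iter`; an empirical p of exactly zero is never reported) and
#' capped at 1; the floor is applied after the halving.
#'
#' @param observed_delta Observed prevalence difference.
#' @param sim_deltas Simulated null differences ([simulate_null()]).
#' @param mclass Mutation class (halving applies to `CNA_gain`/`CNA_loss`).
#' @param p_floor Minimum reportable p (default `1 / length(sim_deltas)`).
#' @return A single p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed_delta, sim_deltas, mclass,
                             p_floor = 1 / length(sim_deltas)) {
  if (length(sim_deltas) == 0) abort("sim_deltas must be non-empty")
  center <- mean(sim_deltas)
  exceed <- mean(abs(sim_deltas - center) >= abs(observed_delta - center))
  p <- if (mclass %in% c("CNA_gain", "CNA_loss")) exceed / 2 else exceed
  min(max(p, p_floor), 1)
}

#' Benjamini-Hochberg q-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, applied jointly
#' across all tested mutation types.
#'
#' @param p_values Vector of p-values in `(0, 1]`.
#' @return Vector of q-values, monotone in `p_values`.
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  p.adjust(p_values, method = "BH")
}

#' Yates-corrected confidence interval for a difference in proportions
#'
#' `p1 - p2 +/- (1.96 * sqrt(p1(1-p1)/m + p2(1-p2)/n) + (1/m + 1/n)/2)`,
#' clipped to `[-1, 1]`.
#'
#' @param p1,m Proportion and denominator in the first group (mCRPC).
#' @param p2,n Proportion and denominator in the second group (localized).
#' @return One-row tibble with `ci_low`, `ci_high`.
#' @export
delta_ci_yates <- function(p1, m, p2, n) {
  if (any(m < 1) || any(n < 1)) abort("denominators must be >= 1")
  half <- 1.96 * sqrt(p1 * (1 - p1) / m + p2 * (1 - p2) / n) +
    0.5 * (1 / m + 1 / n)
  tibble(
    ci_low = pmax(-1, (p1 - p2) - half),
    ci_high = pmin(1, (p1 - p2) + half)
  )
}

#' Burden-adjusted differential prevalence for every mutation type
#'
#' For each catalog mutation type: observed prevalence difference between
#' mCRPC and localized samples, the expected difference under the
#' burden-weighted binomial null, their difference (the *adjusted*
#' difference), a Yates-corrected CI for the observed difference, the
#' empirical simulation p-value, a plain Fisher exact p-value on the
#' observed counts, BH q-values across all tested types, and the direction
#' call (`enriched_mCRPC` / `depleted_mCRPC` at `q < alpha` by the sign of
#' the adjusted difference, else `null`).
#'
#' Mutation types with no assayed samples in one state are flagged
#' (`flagged = TRUE`) and carry `NA` statistics rather than being dropped.
#' Each mutation type uses a deterministic substream of `config$seed`
#' keyed by its alphabetical rank, so results do not depend on catalog
#' order.
#'
#' @param matrix Mutation matrix tibble ([build_mutation_matrix()]).
#' @param samples Sample table with `state`, `snv_burden_per_mbp`, `pga`.
#' @param catalog Validated driver catalog.
#' @param config A [null_model_config()].
#' @param alpha Significance level for the direction call (default 0.05).
#' @return A tibble of class `drv_differential`, one row per mutation type.
#' @export
differential_table <- function(matrix, samples, catalog,
                               config = null_model_config(), alpha = 0.05) {
  if (nrow(catalog) == 0) {
    return(structure(
      tibble(
        mutation_type = character(), gene_id = character(),
        class = character(), n_mcrpc = integer(), n_localized = integer(),
        x_mcrpc = integer(), x_localized = integer(),
        p_mcrpc = double(), p_localized = double(),
        observed_delta = double(), expected_delta = double(),
        adjusted_delta = double(), ci_low = double(), ci_high = double(),
        p_value = double(), fisher_p = double(), q_value = double(),
        direction = character(), flagged = logical()
      ),
      class = c("drv_differential", class(tibble())), alpha = alpha
    ))
  }
  samples <- validate_samples(samples)
  matrix <- matrix[match(samples$sample_id, matrix$sample_id), ]

  order_rank <- rank(catalog$mutation_type, ties.method = "first")
  rows <- purrr::map_dfr(seq_len(nrow(catalog)), function(j) {
    entry <- catalog[j, ]
    mt <- entry$mutation_type
    col <- matrix[[mt]]
    if (is.null(col)) abort(paste0("matrix lacks catalog column: ", mt))
    assayed <- !is.na(col)
    is_met <- samples$state == "mCRPC"
    m <- sum(assayed & is_met)
    n <- sum(assayed & !is_met)
    if (m == 0 || n == 0) {
      return(tibble(
        mutation_type = mt, gene_id = entry$gene_id, class = entry$class,
        n_mcrpc = m, n_localized = n,
        x_mcrpc = NA_integer_, x_localized = NA_integer_,
        p_mcrpc = NA_real_, p_localized = NA_real_,
        observed_delta = NA_real_, expected_delta = NA_real_,
        adjusted_delta = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_value = NA_real_, fisher_p = NA_real_, flagged = TRUE
      ))
    }
    x1 <- sum(col == 1L & is_met, na.rm = TRUE)
    x2 <- sum(col == 1L & !is_met, na.rm = TRUE)
    p1 <- x1 / m
    p2 <- x2 / n
    observed <- p1 - p2

    sub <- samples[assayed, ]
    p_mut <- per_sample_hit_probability(sub, entry, entry$class, config)
    sub_config <- config
    sub_config$seed <- substream_seed(config$seed %||% 1L, order_rank[j])
    sim <- simulate_null(p_mut, sub$state, sub_config)
    p_val <- empirical_pvalue(observed, sim$sim_deltas, entry$class,
                              p_floor = config$p_floor)
    fisher_p <- fisher.test(base::matrix(c(x1, m - x1, x2, n - x2), 2))$p.value
    ci <- delta_ci_yates(p1, m, p2, n)

    tibble(
      mutation_type = mt, gene_id = entry$gene_id, class = entry$class,
      n_mcrpc = m, n_localized = n, x_mcrpc = x1, x_localized = x2,
      p_mcrpc = p1, p_localized = p2,
      observed_delta = observed, expected_delta = sim$expected_delta,
      adjusted_delta = observed - sim$expected_delta,
      ci_low = ci$ci_low, ci_high = ci$ci_high,
      p_value = p_val, fisher_p = fisher_p, flagged = FALSE
    )
  })

  rows$q_value <- NA_real_
  ok <- !rows$flagged
  rows$q_value[ok] <- adjust_fdr(rows$p_value[ok])
  rows <- rows %>%
    mutate(
      direction = case_when(
        .data$flagged | is.na(.data$q_value) ~ NA_character_,
        .data$q_value < alpha & .data$adjusted_delta > 0 ~ "enriched_mCRPC",
        .data$q_value < alpha & .data$adjusted_delta < 0 ~ "depleted_mCRPC",
        TRUE ~ "null"
      )
    ) %>%
    select("mutation_type", "gene_id", "class", "n_mcrpc", "n_localized",
           "x_mcrpc", "x_localized", "p_mcrpc", "p_localized",
           "observed_delta", "expected_delta", "adjusted_delta",
           "ci_low", "ci_high", "p_value", "fisher_p", "q_value",
           "direction", "flagged")
  structure(rows, class = c("drv_differential", class(rows)),
            alpha = alpha)
}
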