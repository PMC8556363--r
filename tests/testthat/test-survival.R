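test_that("KM curve equals the empirical survival function without censoring", {
  d <- tibble::tibble(time_months = c(2, 4, 6, 8), event = 1, grp = "a")
  km <- km_logrank(d, time_months, event, grp)
  expect_equal(km$curves$survival, c(0.75, 0.5, 0.25, 0))
  expect_true(all(diff(km$curves$survival) <= 0)) # non-increasing
  expect_true(is.na(km$chi2))

  expect_error(km_logrank(dplyr::mutate(d, time_months = c(0, 4, 6, 8)),
                          time_months, event, grp), "times")
})

test_that("log-rank statistic matches the hand hypergeometric computation", {
  # two identical groups -> chi2 = 0, p = 1
  d0 <- tibble::tibble(time_months = rep(c(1, 2, 3), 2), event = 1,
                       grp = rep(c("a", "b"), each = 3))
  km0 <- km_logrank(d0, time_months, event, grp)
  expect_equal(km0$chi2, 0, tolerance = 1e-12)
  expect_equal(km0$p, 1, tolerance = 1e-12)

  # 8-patient toy with censoring: observed-minus-expected tallies by hand
  d <- tibble::tibble(
    time_months = c(1, 2, 3, 4, 5, 6, 7, 8),
    event = c(1, 1, 0, 1, 1, 0, 1, 1),
    grp = c("a", "b", "a", "a", "b", "b", "a", "b")
  )
  o_minus_e <- 0
  var_sum <- 0
  for (t in sort(unique(d$time_months[d$event == 1]))) {
    at_risk <- d$time_months >= t
    n_t <- sum(at_risk)
    n_a <- sum(at_risk & d$grp == "a")
    d_t <- sum(d$time_months == t & d$event == 1)
    d_a <- sum(d$time_months == t & d$event == 1 & d$grp == "a")
    o_minus_e <- o_minus_e + (d_a - d_t * n_a / n_t)
    if (n_t > 1) {
      var_sum <- var_sum +
        d_t * (n_a / n_t) * (1 - n_a / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  expected_chi2 <- o_minus_e^2 / var_sum
  km <- km_logrank(d, time_months, event, grp)
  expect_equal(km$chi2, expected_chi2, tolerance = 1e-9)
  expect_equal(km$df, 1)

  expect_error(
    km_logrank(dplyr::mutate(d, grp = factor(grp, levels = c("a", "b", "c"))),
               time_months, event, grp),
    "at least one member"
  )
})

test_that("Cox estimate matches a 1-D grid search of the partial likelihood", {
  d <- tibble::tibble(
    time_months = c(3, 5, 7, 9, 11, 13, 15, 17, 19, 21),
    event = c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1),
    x = c(1, 1, 0, 1, 0, 1, 0, 0, 0, 0)
  )
  # Breslow partial log-likelihood on a fine grid (unique event times here,
  # so tie handling is irrelevant)
  pll <- function(beta) {
    ll <- 0
    for (i in which(d$event == 1)) {
      risk <- d$time_months >= d$time_months[i]
      ll <- ll + beta * d$x[i] - log(sum(exp(beta * d$x[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-3)
  beta_grid <- grid[which.max(vapply(grid, pll, numeric(1)))]
  fit <- cox_fit(d, "x")
  expect_equal(log(fit$hr), beta_grid, tolerance = 2e-3)
  expect_equal(fit$n_events, 8)
})

test_that("Cox under the null gives HR near 1; separation errors", {
  set.seed(7)
  d <- tibble::tibble(
    time_months = rexp(200, 0.02), event = rbinom(200, 1, 0.5),
    x = rbinom(200, 1, 0.4)
  )
  fit <- cox_fit(d, "x")
  expect_gt(fit$ci_high, 1)
  expect_lt(fit$ci_low, 1)

  # monotone likelihood: every carrier relapses first
  sep <- tibble::tibble(
    time_months = c(1:18, 100 + 1:18),
    event = c(rep(1, 18), rep(0, 18)),
    x = c(rep(1, 18), rep(0, 18))
  )
  expect_error(cox_fit(sep, "x"), "separation|converge")

  expect_error(cox_fit(dplyr::mutate(d, x = 1), "x"), "constant")
  expect_error(cox_fit(dplyr::mutate(d, event = 0), "x"), "no events")
})

test_that("Cox estimates are invariant to time rescaling and label swap", {
  set.seed(12)
  d <- tibble::tibble(
    x = rbinom(120, 1, 0.3),
    time_months = rexp(120, 0.02 * exp(0.8 * x)),
    event = rbinom(120, 1, 0.7)
  )
  f1 <- cox_fit(d, "x")
  f2 <- cox_fit(dplyr::mutate(d, time_months = time_months * 12), "x")
  expect_equal(f1$hr, f2$hr, tolerance = 1e-6)
  f3 <- cox_fit(dplyr::mutate(d, x = 1 - x), "x")
  expect_equal(log(f3$hr), -log(f1$hr), tolerance = 1e-6)
})

test_that("candidate screen applies the q and prevalence gates", {
  # synthetic differential table: 3 candidates with controlled gates
  diff_tbl <- structure(
    tibble::tibble(
      mutation_type = c("A:CNA_gain", "B:CNA_loss", "C:SNV", "D:SV"),
      gene_id = c("A", "B", "C", "D"),
      class = c("CNA_gain", "CNA_loss", "SNV", "SV"),
      n_mcrpc = 100L, n_localized = 400L,
      x_mcrpc = c(40L, 30L, 20L, 10L),
      x_localized = c(32L, 16L, 80L, 40L), # 8%, 4%, 20%, 10% localized
      p_mcrpc = NA_real_, p_localized = NA_real_,
      observed_delta = 0.1, expected_delta = 0, adjusted_delta = 0.1,
      ci_low = 0, ci_high = 0.2,
      p_value = c(0.001, 0.001, 0.001, 0.9),
      fisher_p = NA_real_,
      q_value = c(0.004, 0.004, 0.004, 0.9), # D fails the q gate
      direction = "enriched_mCRPC", flagged = FALSE
    ),
    class = c("drv_differential", class(tibble::tibble())), alpha = 0.05
  )
  set.seed(41)
  n <- 400
  samples <- tibble::tibble(
    sample_id = sprintf("L%03d", 1:n), state = "localized",
    snv_burden_per_mbp = 1, pga = 0.05, assayed_classes = "CNA,SNV,ncSNV,SV"
  )
  carrier_a <- rbinom(n, 1, 0.08)
  mat <- tibble::tibble(
    sample_id = samples$sample_id,
    `A:CNA_gain` = as.integer(carrier_a),
    `B:CNA_loss` = rbinom(n, 1, 0.04),
    `C:SNV` = rbinom(n, 1, 0.20),
    `D:SV` = rbinom(n, 1, 0.10)
  )
  # planted hazard on A only
  rate <- 0.01 * exp(log(4) * carrier_a)
  outcomes <- tibble::tibble(
    sample_id = samples$sample_id, endpoint = "metastasis",
    time_months = rexp(n, rate), event = rbinom(n, 1, 0.6)
  )
  rep <- screen_candidates(diff_tbl, mat, samples, outcomes)
  expect_false("B:CNA_loss" %in% rep$mutation_type) # 4% < 5% gate
  expect_false("D:SV" %in% rep$mutation_type) # q gate
  expect_true(all(c("A:CNA_gain", "C:SNV") %in% rep$mutation_type))
  expect_true(rep$selected[rep$mutation_type == "A:CNA_gain"])
  expect_gt(rep$hr[rep$mutation_type == "A:CNA_gain"], 2)

  expect_error(
    screen_candidates(diff_tbl, mat, samples,
                      dplyr::mutate(outcomes, endpoint = "bcr")),
    "endpoint"
  )
  empty <- diff_tbl[0, ]
  expect_equal(nrow(screen_candidates(empty, mat, samples, outcomes)), 0)
})

test_that("2x2 odds ratios reproduce the worked examples and brute force", {
  res <- two_by_two(9, 27, 18, 323)
  expect_equal(round(res$odds_ratio, 2), 5.98)
  expect_equal(round(res$ci_low, 2), 2.45)
  expect_equal(round(res$ci_high, 1), 14.6)
  expect_lt(res$fisher_p, 0.001)

  expect_equal(round(two_by_two(20, 71, 38, 360)$odds_ratio, 2), 2.67)

  flat <- two_by_two(10, 10, 10, 10)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$fisher_p, 1)

  expect_error(two_by_two(0, 0, 5, 5), "margins")

  # zero cell: Haldane-Anscombe for OR/CI only
  z <- two_by_two(0, 10, 5, 5)
  expect_equal(z$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))

  set.seed(17)
  for (i in 1:300) {
    tab <- base::matrix(rpois(4, 20) + 1, 2)
    res <- two_by_two(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(res$odds_ratio,
                 tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
    # invariance under simultaneous row and column swap
    sw <- two_by_two(tab[2, 2], tab[2, 1], tab[1, 2], tab[1, 1])
    expect_equal(sw$odds_ratio, res$odds_ratio)
    expect_equal(sw$fisher_p, res$fisher_p)
  }
})
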