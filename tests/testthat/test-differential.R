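test_that("per-sample null hit probability follows the burden model", {
  config <- null_model_config(n_iter = 1000, genome_mbp = 3000)
  entry <- tibble::tibble(snv_footprint_mbp = 0.002, cna_footprint_bp = 1e5)

  zero <- tibble::tibble(snv_burden_per_mbp = 0, pga = 0)
  expect_equal(per_sample_hit_probability(zero, entry, "SNV", config), 0)
  expect_equal(per_sample_hit_probability(zero, entry, "ncSNV", config), 0)
  expect_equal(per_sample_hit_probability(zero, entry, "CNA_loss", config), 0)
  expect_error(per_sample_hit_probability(zero, entry, "nonsense", config),
               "unknown mutation class")
})

test_that("SNV null probability matches the closed form", {
  config <- null_model_config(n_iter = 1000, genome_mbp = 3000)
  entry <- tibble::tibble(snv_footprint_mbp = 0.002, cna_footprint_bp = NA)
  s <- tibble::tibble(snv_burden_per_mbp = 10, pga = 0)
  p <- per_sample_hit_probability(s, entry, "SNV", config)
  expect_equal(round(p, 4), 0.0198)
  # exact closed form
  expect_equal(p, 1 - (1 - 0.002 / 3000)^30000, tolerance = 1e-9)

  # per-sample exome reference via snv_ref_mbp
  s_ex <- tibble::tibble(snv_burden_per_mbp = 10, pga = 0, snv_ref_mbp = 45)
  p_ex <- per_sample_hit_probability(s_ex, entry, "SNV", config)
  expect_equal(p_ex, 1 - (1 - 0.002 / 45)^450, tolerance = 1e-9)

  big <- tibble::tibble(snv_footprint_mbp = 5000, cna_footprint_bp = NA)
  expect_error(per_sample_hit_probability(s, big, "SNV", config), "exceeds")
})

test_that("CNA null probability is monotone in PGA and uses the segment model", {
  config <- null_model_config(n_iter = 1000)
  entry <- tibble::tibble(snv_footprint_mbp = NA, cna_footprint_bp = 1e6)
  grid <- tibble::tibble(snv_burden_per_mbp = 0,
                         pga = seq(0, 1, length.out = 21))
  p <- per_sample_hit_probability(grid, entry, "CNA_gain", config)
  expect_equal(p[1], 0)
  expect_true(all(diff(p) >= 0))
  expect_true(p[21] < 1) # segment process does not saturate at PGA = 1
  # closed form at pga = 1: M = 300 segments of lambda = 10 Mbp
  expect_equal(p[21], 1 - (1 - (1 + 10) / 3000)^300, tolerance = 1e-12)
})

test_that("null simulation matches closed-form expectations and is reproducible", {
  config <- null_model_config(n_iter = 4000, seed = 99)
  p_mut <- c(runif(60, 0, 0.4))
  states <- rep(c("localized", "mCRPC"), 30)

  sim <- simulate_null(p_mut, states, config)
  truth <- mean(p_mut[states == "mCRPC"]) - mean(p_mut[states == "localized"])
  mc_se <- sd(sim$sim_deltas) / sqrt(config$n_iter)
  expect_lt(abs(sim$expected_delta - truth), 3 * mc_se + 1e-12)

  # balanced equal probabilities -> expected delta ~ 0
  sim0 <- simulate_null(rep(0.2, 60), states, config)
  se0 <- sd(sim0$sim_deltas) / sqrt(config$n_iter)
  expect_lt(abs(sim0$expected_delta), 3 * se0)

  # bit-identical under the same seed
  sim_a <- simulate_null(p_mut, states, config)
  sim_b <- simulate_null(p_mut, states, config)
  expect_identical(sim_a$sim_deltas, sim_b$sim_deltas)

  expect_error(simulate_null(c(0.5, 1.2), c("localized", "mCRPC"), config),
               "lie in")
  expect_error(simulate_null(c(0.5), c("localized"), config), "non-empty")
})

test_that("empirical p-values: two-sided exceedance, CNA halving, floor", {
  sim <- c(-0.02, -0.01, 0, 0.01, 0.02) # mean 0
  expect_equal(empirical_pvalue(0, sim, "SNV"), 1)
  expect_equal(empirical_pvalue(0.015, sim, "SNV"), 2 / 5)
  # CNA halving applied to the same exceedance
  expect_equal(empirical_pvalue(0.015, sim, "CNA_loss"), 1 / 5)

  # beyond every simulated value -> floored at 1/n_iter
  big_sim <- rnorm(100000, 0, 0.001)
  expect_equal(empirical_pvalue(1, big_sim, "SNV"), 1e-5)
  # halving then flooring lands at the same floor
  expect_equal(empirical_pvalue(1, big_sim, "CNA_gain"), 1e-5)
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(adjust_fdr(0.05), 0.05)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # ties at the floor propagate one minimal q
  q <- adjust_fdr(c(1e-5, 1e-5, 1e-5, 0.5))
  expect_equal(q[1:3], rep(4e-5 / 3, 3) * 1) # BH: p * n / k at k = 3
  expect_equal(length(unique(q[1:3])), 1)
  expect_equal(adjust_fdr(numeric(0)), numeric(0))
})

test_that("Yates-corrected delta CI matches direct arithmetic", {
  ci <- delta_ci_yates(0.5, 100, 0.5, 100)
  expect_equal(round(ci$ci_high, 4), 0.1486)
  expect_equal(ci$ci_low, -ci$ci_high)

  # variance terms vanish at p = 0: only the continuity term remains
  ci0 <- delta_ci_yates(0, 50, 0, 200)
  expect_equal(ci0$ci_high, 0.5 * (1 / 50 + 1 / 200))

  widths <- sapply(c(50, 500, 5000), function(n) {
    ci <- delta_ci_yates(0.3, n, 0.2, n)
    ci$ci_high - ci$ci_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("differential table recovers a planted enrichment", {
  catalog <- synthetic_driver_catalog(6)
  planted <- catalog$mutation_type[1]
  cfg <- synthetic_config(
    n_localized = 150, n_mcrpc = 100, seed = 5,
    null = null_model_config(n_iter = 4000, seed = 5)
  )
  truth <- synthetic_truth(catalog, delta = setNames(0.3, planted))
  cohort <- generate_cohort(cfg, catalog, truth)
  dt <- differential_table(cohort$matrix, cohort$samples, catalog, cfg$null)

  expect_s3_class(dt, "drv_differential")
  expect_equal(nrow(dt), 6)
  expect_equal(dt$adjusted_delta, dt$observed_delta - dt$expected_delta)
  expect_equal(dt$mutation_type[which.max(dt$adjusted_delta)], planted)
  expect_lt(dt$q_value[dt$mutation_type == planted], 0.05)
  expect_equal(dt$direction[dt$mutation_type == planted], "enriched_mCRPC")

  # empty catalog -> empty table
  empty <- differential_table(cohort$matrix, cohort$samples,
                              catalog[0, ], cfg$null)
  expect_equal(nrow(empty), 0)
})

test_that("state-label swap negates observed, expected and adjusted exactly", {
  catalog <- synthetic_driver_catalog(4)
  cfg <- synthetic_config(n_localized = 60, n_mcrpc = 40, seed = 8,
                          null = null_model_config(n_iter = 1000, seed = 8))
  cohort <- generate_cohort(cfg, catalog, synthetic_truth(catalog))

  dt <- differential_table(cohort$matrix, cohort$samples, catalog, cfg$null)
  swapped <- cohort$samples
  swapped$state <- ifelse(swapped$state == "mCRPC", "localized", "mCRPC")
  dt_sw <- differential_table(cohort$matrix, swapped, catalog, cfg$null)

  expect_identical(dt_sw$observed_delta, -dt$observed_delta)
  expect_identical(dt_sw$expected_delta, -dt$expected_delta)
  expect_identical(dt_sw$adjusted_delta, -dt$adjusted_delta)
  expect_identical(dt_sw$p_value, dt$p_value)
})

test_that("a state with no assayed samples is flagged, not dropped", {
  catalog <- toy_catalog()
  samples <- toy_samples(3, 2)
  samples$assayed_classes[samples$state == "mCRPC"] <- "CNA,SNV"
  mat <- build_mutation_matrix(list(), catalog, samples)
  dt <- differential_table(mat, samples, catalog,
                           null_model_config(n_iter = 200, seed = 1))
  expect_true(all(dt$flagged[dt$class %in% c("SV", "ncSNV")]))
  expect_true(all(!dt$flagged[!dt$class %in% c("SV", "ncSNV")]))
  expect_true(all(is.na(dt$p_value[dt$flagged])))
  expect_equal(nrow(dt), nrow(catalog))
})

test_that("tidy and glance summarize a differential table", {
  catalog <- synthetic_driver_catalog(4)
  cfg <- synthetic_config(n_localized = 40, n_mcrpc = 30, seed = 2,
                          null = null_model_config(n_iter = 500, seed = 2))
  cohort <- generate_cohort(cfg, catalog, synthetic_truth(catalog))
  dt <- differential_table(cohort$matrix, cohort$samples, catalog, cfg$null)
  td <- generics::tidy(dt)
  expect_false(inherits(td, "drv_differential"))
  gl <- generics::glance(dt)
  expect_equal(gl$n_types, 4)
  expect_s3_class(ggplot2::autoplot(dt), "ggplot")
})
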