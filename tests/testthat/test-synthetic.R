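test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_localized = 50, n_mcrpc = 30, seed = 13,
                          null = null_model_config(n_iter = 200, seed = 13))
  catalog <- synthetic_driver_catalog(5)
  c1 <- generate_cohort(cfg, catalog)
  c2 <- generate_cohort(cfg, catalog)
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$matrix, c2$matrix)
  expect_identical(c1$outcomes, c2$outcomes)

  expect_error(synthetic_config(n_localized = 0), "positive")
})

test_that("state-specific burden and PGA distributions have the right order", {
  cfg <- synthetic_config(n_localized = 10000, n_mcrpc = 10000, seed = 2)
  s <- generate_samples(cfg)
  loc <- s[s$state == "localized", ]
  met <- s[s$state == "mCRPC", ]
  expect_gt(mean(met$snv_burden_per_mbp), mean(loc$snv_burden_per_mbp))
  expect_gt(mean(met$pga), mean(loc$pga))

  # law-of-large-numbers check against the configured moments
  mu_loc <- exp(cfg$burden_meanlog["localized"] + cfg$burden_sdlog^2 / 2)
  se <- sd(loc$snv_burden_per_mbp) / sqrt(nrow(loc))
  expect_lt(abs(mean(loc$snv_burden_per_mbp) - mu_loc), 3 * se)
  beta_mean <- cfg$pga_shape1["mCRPC"] /
    (cfg$pga_shape1["mCRPC"] + cfg$pga_shape2["mCRPC"])
  se_pga <- sd(met$pga) / sqrt(nrow(met))
  expect_lt(abs(mean(met$pga) - beta_mean), 3 * se_pga)
})

test_that("planted deltas shift the prevalence gap by the planted amount", {
  catalog <- synthetic_driver_catalog(4)
  planted <- catalog$mutation_type[2]
  cfg <- synthetic_config(n_localized = 500, n_mcrpc = 500, seed = 6,
                          null = null_model_config(n_iter = 200, seed = 6))
  truth0 <- synthetic_truth(catalog)
  truth1 <- synthetic_truth(catalog, delta = setNames(0.2, planted))

  m0 <- plant_mutations(generate_samples(cfg), catalog, truth0, cfg)
  m1 <- plant_mutations(generate_samples(cfg), catalog, truth1, cfg)
  samples <- generate_samples(cfg)
  gap <- function(m, mt) {
    met <- m[samples$state == "mCRPC", ][[mt]]
    loc <- m[samples$state == "localized", ][[mt]]
    mean(met, na.rm = TRUE) - mean(loc, na.rm = TRUE)
  }
  excess <- gap(m1, planted) - gap(m0, planted)
  se <- sqrt(4 * 0.25 / 500) # conservative binomial bound on the gap diff
  expect_lt(abs(excess - 0.2), 3 * se)

  # pure null: every gap is within binomial noise of the null expectation
  dt0 <- differential_table(m0, samples, catalog, cfg$null)
  expect_true(all(abs(dt0$adjusted_delta) < 0.1))

  expect_equal(ncol(plant_mutations(samples, catalog[0, ], truth0, cfg)), 1)
  expect_error(plant_mutations(samples, catalog, truth0[-1, ], cfg),
               "cover")
})

test_that("outcomes carry planted hazards and honor the censoring rate", {
  catalog <- synthetic_driver_catalog(3)
  target <- catalog$mutation_type[1]
  cfg <- synthetic_config(n_localized = 800, n_mcrpc = 50, seed = 9,
                          censoring_rate = 0.6,
                          null = null_model_config(n_iter = 200, seed = 9))
  truth <- synthetic_truth(catalog, delta = setNames(0.1, target),
                           log_hr = setNames(log(4), target))
  cohort <- generate_cohort(cfg, catalog, truth)
  expect_equal(nrow(cohort$outcomes), 800)
  # realized censoring close to configured
  expect_lt(abs(mean(1 - cohort$outcomes$event) - 0.6), 0.08)

  d <- dplyr::inner_join(cohort$outcomes,
                         cohort$matrix[c("sample_id", target)],
                         by = "sample_id")
  names(d)[names(d) == target] <- "carrier"
  fit <- cox_fit(d, "carrier")
  expect_gt(fit$hr, 1.5)
  expect_lt(fit$ci_low, 4)
  expect_gt(fit$ci_high, 4 * 0.5)

  # all hazards zero: carrier and non-carrier curves coincide (log-rank ns)
  c0 <- generate_cohort(cfg, catalog, synthetic_truth(catalog))
  d0 <- dplyr::inner_join(c0$outcomes, c0$matrix[c("sample_id", target)],
                          by = "sample_id")
  names(d0)[names(d0) == target] <- "carrier"
  if (length(unique(d0$carrier)) == 2) {
    km <- km_logrank(d0, time_months, event, carrier)
    expect_gt(km$p, 0.001)
  }

  # full censoring -> zero events -> Cox refuses to fit
  cfg_cens <- synthetic_config(n_localized = 100, n_mcrpc = 10, seed = 9,
                               censoring_rate = 1)
  o <- generate_outcomes(cohort$samples[1:100, ], cohort$matrix, truth,
                         cfg_cens)
  expect_equal(sum(o$event), 0)
  d1 <- dplyr::inner_join(o, cohort$matrix[c("sample_id", target)],
                          by = "sample_id")
  names(d1)[names(d1) == target] <- "carrier"
  expect_error(cox_fit(d1, "carrier"), "no events")
})

test_that("expression/methylation generator hits the configured correlation", {
  catalog <- synthetic_driver_catalog(3)
  target <- catalog$mutation_type[2] # a CNA_loss entry
  cfg <- synthetic_config(n_localized = 200, n_mcrpc = 100, seed = 14,
                          null = null_model_config(n_iter = 200, seed = 14))
  truth <- synthetic_truth(catalog, delta = setNames(0.3, target))
  cohort <- generate_cohort(cfg, catalog, truth)
  em <- generate_expression_methylation(cohort$samples, cohort$matrix, cfg,
                                        target = target)
  rho <- cor(em$expression$log2_abundance, em$methylation$m_value,
             method = "spearman")
  expect_lt(abs(rho - (-0.4)), 0.1)

  carrier <- dplyr::coalesce(cohort$matrix[[target]], 0L)
  diff_mean <- mean(em$expression$log2_abundance[carrier == 0]) -
    mean(em$expression$log2_abundance[carrier == 1])
  expect_gt(diff_mean, 0) # carriers have lower abundance

  # no planted shift and no methylation coupling: RNA independent of loss
  em0 <- generate_expression_methylation(cohort$samples, cohort$matrix, cfg,
                                         target = target, shift = 0,
                                         beta = 0, meth_shift = 0,
                                         noise_sd = 1)
  p <- wilcox.test(em0$expression$log2_abundance[carrier == 1],
                   em0$expression$log2_abundance[carrier == 0])$p.value
  expect_gt(p, 0.001)
})

test_that("written cohort files reproduce the planted matrix on re-ingestion", {
  catalog <- synthetic_driver_catalog(6)
  cfg <- synthetic_config(n_localized = 40, n_mcrpc = 25, seed = 3,
                          null = null_model_config(n_iter = 200, seed = 3))
  truth <- synthetic_truth(catalog,
                           delta = setNames(0.3, catalog$mutation_type[1]))
  cohort <- generate_cohort(cfg, catalog, truth)
  dir <- withr::local_tempdir()
  write_synthetic_cohort(cohort, dir)
  expect_true(all(file.exists(file.path(
    dir, c("segments.seg", "snv_calls.tsv", "sv_calls.tsv", "clinical.tsv",
           "outcomes.tsv", "catalog.tsv", "truth.json")
  ))))
  catalog2 <- read_driver_catalog(file.path(dir, "catalog.tsv"))
  samples2 <- read_samples(file.path(dir, "clinical.tsv"))
  calls <- list(
    cna = read_seg(file.path(dir, "segments.seg")),
    snv = read_snv_calls(file.path(dir, "snv_calls.tsv")),
    sv = read_sv_calls(file.path(dir, "sv_calls.tsv"))
  )
  rebuilt <- build_mutation_matrix(calls, catalog2, samples2)
  expect_equal(as.data.frame(rebuilt), as.data.frame(cohort$matrix))
})
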