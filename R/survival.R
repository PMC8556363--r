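# Outcome screening: Kaplan-Meier / log-rank, Cox proportional hazards,
# the localized-prevalence candidate filter, and 2x2 odds-ratio
# associations. Model fitting is delegated to the survival package; this
# module owns the screening logic and the Woolf/odds-ratio arithmetic.

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit estimator per group plus the k-group log-rank chi-square
#' (k - 1 degrees of freedom). With a single group only the curve is
#' returned (`chi2` and `p` are `NA`).
#'
#' @param data Data frame with one row per sample.
#' @param time,event,group Columns (tidy-eval) holding follow-up time
#'   (> 0), event indicator (0/1 or logical), and group label.
#' @return List with `curves` (tibble: `group`, `time`, `n_risk`,
#'   `n_event`, `survival`), `chi2`, `df`, `p`.
#' @export
km_logrank <- function(data, time, event, group) {
  grp <- dplyr::pull(data, {{ group }})
  if (is.factor(grp) && any(table(grp) == 0)) {
    abort("every group must have at least one member")
  }
  d <- tibble(
    time = dplyr::pull(data, {{ time }}),
    event = as.integer(as.logical(dplyr::pull(data, {{ event }}))),
    group = as.character(grp)
  )
  if (any(d$time <= 0)) abort("all times must be > 0")
  counts <- table(d$group)

  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  strata_names <- if (is.null(fit$strata)) unique(d$group) else
    sub("^group=", "", names(fit$strata))
  strata_id <- if (is.null(fit$strata)) rep(strata_names, length(fit$time))
    else rep(strata_names, fit$strata)
  curves <- tibble(
    group = strata_id, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, survival = fit$surv
  )

  if (length(counts) < 2) {
    return(list(curves = curves, chi2 = NA_real_, df = NA_integer_,
                p = NA_real_))
  }
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(lr$n) - 1
  list(curves = curves, chi2 = unname(lr$chisq), df = df,
       p = pchisq(lr$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit with Wald inference
#'
#' Fits a (uni- or multivariable) Cox model via [survival::coxph()] with
#' the requested tie handling, and returns one row per model term with the
#' hazard ratio, Wald 95% CI and p-value, plus a Schoenfeld-residual
#' proportional-hazards p-value per term (from [survival::cox.zph()]).
#' Non-convergence and complete separation (monotone likelihood, e.g.
#' every carrier relapsing) raise an error with a diagnostic rather than
#' returning unstable estimates.
#'
#' @param data Data frame with one row per sample.
#' @param covariates Character vector of covariate column names.
#' @param time,event Column names (strings) for follow-up time and the
#'   event indicator.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Tibble of class `drv_cox`: `covariate`, `hr`, `ci_low`,
#'   `ci_high`, `wald_p`, `ph_p`, `n`, `n_events`.
#' @export
cox_fit <- function(data, covariates, time = "time_months",
                    event = "event", ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  data <- as_tibble(data)
  missing <- setdiff(c(covariates, time, event), names(data))
  if (length(missing) > 0) {
    abort(paste0("data missing column(s): ", paste(missing, collapse = ", ")))
  }
  d <- data[complete.cases(data[c(covariates, time, event)]), ]
  if (sum(as.logical(d[[event]])) < 1) abort("no events in the data")
  constant <- covariates[vapply(covariates,
                                function(v) length(unique(d[[v]])) < 2,
                                logical(1))]
  if (length(constant) > 0) {
    abort(paste0("constant covariate(s): ", paste(constant, collapse = ", ")))
  }

  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  warned <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      warned <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    }
  )
  if (!is.null(warned) &&
      grepl("infinite|did not converge|beta may be infinite", warned,
            ignore.case = TRUE)) {
    abort(paste0("Cox fit failed (non-convergence or complete separation): ",
                 warned))
  }
  s <- summary(fit)
  terms <- rownames(s$coefficients)
  if (any(!is.finite(s$coefficients[, "se(coef)"])) ||
      any(abs(s$coefficients[, "coef"]) > 15)) {
    abort("Cox fit unstable: coefficient diverging (likely separation)")
  }
  zph_p <- rep(NA_real_, length(terms))
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  if (!is.null(zph)) {
    tab <- zph$table
    keep <- intersect(covariates, rownames(tab))
    # cox.zph reports per covariate (not per factor level); map by prefix
    for (i in seq_along(terms)) {
      src <- keep[vapply(keep, function(k) startsWith(terms[i], k),
                         logical(1))]
      if (length(src) > 0) zph_p[i] <- tab[src[1], "p"]
    }
  }
  out <- tibble(
    covariate = terms,
    hr = unname(s$coefficients[, "exp(coef)"]),
    ci_low = unname(s$conf.int[, "lower .95"]),
    ci_high = unname(s$conf.int[, "upper .95"]),
    wald_p = unname(s$coefficients[, "Pr(>|z|)"]),
    ph_p = zph_p,
    n = s$n,
    n_events = s$nevent
  )
  structure(out, class = c("drv_cox", class(out)), fit = fit)
}

#' Screen differentially prevalent mutations against outcome
#'
#' Applies the candidate filter — differential `q_value < alpha` and
#' localized prevalence at least `min_prevalence` — then fits a
#' univariable Cox model per candidate against the requested endpoint in
#' the localized stratum, BH-corrects across the candidate set only, and
#' reports every candidate with its hazard ratio and screen q-value.
#' Candidates whose Cox fit violates proportional hazards (Schoenfeld
#' p < 0.05) fall back to the log-rank test p-value (`method` column says
#' which was used).
#'
#' @param differential A `drv_differential` table ([differential_table()]).
#' @param matrix Mutation matrix covering the localized samples.
#' @param samples Sample table (used for the localized stratum).
#' @param outcomes Tibble: `sample_id`, `endpoint`, `time_months`, `event`.
#' @param endpoint Endpoint label to screen against (default
#'   `"metastasis"`).
#' @param alpha Significance level for both filters (default 0.05).
#' @param min_prevalence Minimum localized prevalence (default 0.05).
#' @return Tibble: `mutation_type`, `prevalence_localized`,
#'   `differential_q`, `hr`, `ci_low`, `ci_high`, `p`, `q`, `method`,
#'   `selected` (screen q < alpha).
#' @export
screen_candidates <- function(differential, matrix, samples, outcomes,
                              endpoint = "metastasis", alpha = 0.05,
                              min_prevalence = 0.05) {
  empty <- tibble(
    mutation_type = character(), prevalence_localized = double(),
    differential_q = double(), hr = double(), ci_low = double(),
    ci_high = double(), p = double(), q = double(), method = character(),
    selected = logical()
  )
  if (nrow(differential) == 0) return(empty)
  out_ep <- outcomes %>% filter(.data$endpoint == !!endpoint)
  if (nrow(out_ep) == 0) {
    abort(paste0("no outcome records for endpoint: ", endpoint))
  }
  loc <- samples %>% filter(.data$state == "localized")
  mat_loc <- matrix %>% semi_join(loc, by = "sample_id")

  candidates <- differential %>%
    filter(!.data$flagged, .data$q_value < alpha) %>%
    mutate(prevalence_localized = .data$x_localized / .data$n_localized) %>%
    filter(.data$prevalence_localized >= min_prevalence)
  if (nrow(candidates) == 0) return(empty)

  fits <- purrr::map_dfr(candidates$mutation_type, function(mt) {
    d <- mat_loc %>%
      select("sample_id", carrier = dplyr::all_of(mt)) %>%
      inner_join(out_ep, by = "sample_id") %>%
      filter(!is.na(.data$carrier))
    res <- tryCatch({
      cx <- cox_fit(d, "carrier")
      method <- "cox"
      p <- cx$wald_p[1]
      if (!is.na(cx$ph_p[1]) && cx$ph_p[1] < 0.05) {
        lr <- km_logrank(d, time_months, event, carrier)
        p <- lr$p
        method <- "logrank"
      }
      tibble(mutation_type = mt, hr = cx$hr[1], ci_low = cx$ci_low[1],
             ci_high = cx$ci_high[1], p = p, method = method)
    }, error = function(e) {
      tibble(mutation_type = mt, hr = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, p = NA_real_,
             method = paste0("failed: ", conditionMessage(e)))
    })
    res
  })

  out <- candidates %>%
    select("mutation_type", "prevalence_localized",
           differential_q = "q_value") %>%
    left_join(fits, by = "mutation_type")
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- adjust_fdr(out$p[ok])
  out %>%
    mutate(selected = !is.na(.data$q) & .data$q < alpha) %>%
    select("mutation_type", "prevalence_localized", "differential_q",
           "hr", "ci_low", "ci_high", "p", "q", "method", "selected")
}

#' 2x2 association: odds ratio, Woolf CI, Fisher exact p
#'
#' Cross-product odds ratio `ad/bc` with the Woolf (log-scale normal)
#' confidence interval `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c +
#' 1/d))` and the two-sided Fisher exact p-value. When any cell is zero
#' the Haldane-Anscombe correction (+0.5 to every cell) is applied to the
#' OR and CI only, never to the Fisher test.
#'
#' @param a,b,c,d Non-negative counts, laid out as rows = exposure,
#'   columns = outcome: `a` exposed with outcome, `b` exposed without,
#'   `c` unexposed with, `d` unexposed without.
#' @return One-row tibble: the counts, `odds_ratio`, `ci_low`, `ci_high`,
#'   `fisher_p`.
#' @export
#' @examples
#' two_by_two(9, 27, 18, 323) # OR ~ 5.98 (2.45-14.6)
two_by_two <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) abort("counts must be non-negative")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    abort("both margins must be positive")
  }
  cc <- if (any(counts == 0)) counts + 0.5 else counts
  or <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  se <- sqrt(sum(1 / cc))
  fisher_p <- fisher.test(base::matrix(c(a, b, c, d), nrow = 2,
                                       byrow = TRUE))$p.value
  tibble(
    a = a, b = b, c = c, d = d,
    odds_ratio = unname(or),
    ci_low = unname(exp(log(or) - 1.96 * se)),
    ci_high = unname(exp(log(or) + 1.96 * se)),
    fisher_p = fisher_p
  )
}
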