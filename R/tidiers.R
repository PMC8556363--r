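# broom-style accessors and ggplot2 displays for the result objects.

#' Tidy a differential-prevalence table
#'
#' @param x A `drv_differential` object ([differential_table()]).
#' @param ... Unused.
#' @return A plain tibble with one row per mutation type.
#' @export
tidy.drv_differential <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' Summarize a differential-prevalence run
#'
#' @param x A `drv_differential` object.
#' @param ... Unused.
#' @return One-row tibble: numbers tested, enriched, depleted, and the
#'   significance level used.
#' @export
glance.drv_differential <- function(x, ...) {
  tested <- x[!x$flagged, ]
  tibble(
    n_types = nrow(x),
    n_tested = nrow(tested),
    n_enriched_mcrpc = sum(tested$direction == "enriched_mCRPC",
                           na.rm = TRUE),
    n_depleted_mcrpc = sum(tested$direction == "depleted_mCRPC",
                           na.rm = TRUE),
    alpha = attr(x, "alpha") %||% 0.05
  )
}

#' Tidy a Cox screening fit
#'
#' @param x A `drv_cox` object ([cox_fit()]).
#' @param ... Unused.
#' @return Tibble with one row per model term.
#' @export
tidy.drv_cox <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' Summarize a Cox fit
#'
#' @param x A `drv_cox` object.
#' @param ... Unused.
#' @return One-row tibble with `n`, `n_events`, likelihood-ratio p.
#' @export
glance.drv_cox <- function(x, ...) {
  fit <- attr(x, "fit")
  s <- summary(fit)
  tibble(
    n = s$n, n_events = s$nevent,
    logtest_p = unname(s$logtest["pvalue"]),
    concordance = unname(s$concordance["C"])
  )
}

unclass_result <- function(x) {
  attrs_to_drop <- c("alpha", "fit")
  for (a in attrs_to_drop) attr(x, a) <- NULL
  class(x) <- class(tibble())
  x
}

#' Waterfall plot of adjusted prevalence differences
#'
#' Mutation types ordered by adjusted difference; bars beyond the
#' significance threshold are colored by direction, with the Yates CI of
#' the observed difference overlaid.
#'
#' @param object A `drv_differential` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drv_differential <- function(object, ...) {
  d <- tidy(object) %>%
    filter(!.data$flagged) %>%
    arrange(.data$adjusted_delta) %>%
    mutate(mutation_type = factor(.data$mutation_type,
                                  levels = .data$mutation_type))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mutation_type,
                                  y = .data$adjusted_delta,
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low - .data$expected_delta,
                   ymax = .data$ci_high - .data$expected_delta),
      width = 0.3, linewidth = 0.3
    ) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(
      enriched_mCRPC = "#b2182b", depleted_mCRPC = "#2166ac", null = "grey70"
    )) +
    ggplot2::labs(x = NULL, y = "Adjusted Δ proportion (mCRPC - localized)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Prevalence dot plot per disease state
#'
#' @param prevalence A tibble from [prevalence_table()].
#' @return A ggplot object.
#' @export
plot_prevalence <- function(prevalence) {
  ggplot2::ggplot(prevalence,
                  ggplot2::aes(x = .data$mutation_type, y = .data$p_hat,
                               color = .data$state)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5), size = 0.3
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Prevalence", color = "State") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step curves
#'
#' @param km A result of [km_logrank()].
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  curves <- km$curves %>%
    group_by(.data$group) %>%
    dplyr::group_modify(~ bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0, survival = 1),
      .x
    )) %>%
    ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Relapse-free rate",
                  color = NULL) +
    ggplot2::theme_minimal()
}
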