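# ggplot2 visualisations.

#' Plot cohort GRS distributions with prevalence estimates
#'
#' Density curves of the three cohorts with vertical reference lines are
#' drawn, annotated with each method's estimate.
#'
#' @param object A `prevalence_fit` from [estimate_prevalence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prevalence_fit
#' @export
autoplot.prevalence_fit <- function(object, ...) {
  co <- object$cohorts
  d <- dplyr::bind_rows(
    tibble::tibble(cohort = "case reference", grs = co$cases),
    tibble::tibble(cohort = "non-case reference", grs = co$noncases),
    tibble::tibble(cohort = "mixture", grs = co$mixture)
  )
  lab <- paste(
    sprintf("%s: %.3f", object$estimates$method, object$estimates$p_case),
    collapse = "   "
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$grs, fill = .data$cohort)) +
    ggplot2::geom_density(alpha = 0.35, colour = NA) +
    ggplot2::labs(
      x = "genetic risk score", y = "density",
      title = "Mixture and reference GRS distributions",
      subtitle = paste("estimated case proportion —", lab)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the bootstrap distribution behind a confidence interval
#'
#' Violin of the Monte-Carlo bootstrap estimates with the point estimate and
#' the BCa interval overlaid.
#'
#' @param object A `prevalence_ci` from [prevalence_ci()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prevalence_ci
#' @export
autoplot.prevalence_ci <- function(object, ...) {
  d <- tibble::tibble(method = object$method, p_prime = object$p_prime)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$p_prime)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::annotate("point", x = 1, y = object$p_case, size = 3,
                      shape = 21, fill = "white", stroke = 1.2) +
    ggplot2::annotate("errorbar", x = 1, ymin = object$ci_lo,
                      ymax = object$ci_hi, width = 0.15) +
    ggplot2::labs(
      x = NULL, y = "bootstrap estimate of the case proportion",
      title = sprintf("%s method: %.3f [%.3f, %.3f]",
                      object$method, object$p_case,
                      object$ci_lo, object$ci_hi)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmaps of a proportion-by-size sweep
#'
#' Four tiles panels: the estimate, its bootstrap bias, the deviation from
#' the true proportion, and the CI width (cells whose interval missed the
#' true value are outlined).
#'
#' @param object A `prevalence_sweep` from [sweep_proportion_size()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prevalence_sweep
#' @export
autoplot.prevalence_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[c("p_case", "n", "estimate", "bias",
                               "deviation", "ci_width")],
    cols = c("estimate", "bias", "deviation", "ci_width"),
    names_to = "panel", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$p_case, y = .data$n,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "true case proportion", y = "mixture size",
      title = sprintf("%s method: proportion-by-size sweep",
                      attr(object, "method"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a mixture-composition diagnostic
#'
#' Null distributions of the two diagnostic statistics with the observed
#' values marked.
#'
#' @param object A `mixture_check` from [check_mixture_assumption()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mixture_check
#' @export
autoplot.mixture_check <- function(object, ...) {
  d <- tidyr::unnest(
    dplyr::as_tibble(object)[c("statistic", "null")],
    cols = "null"
  )
  obs <- dplyr::as_tibble(object)[c("statistic", "observed", "percentile")]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey80", colour = "grey50") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "red") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(
      x = "statistic under the two-component null", y = "count",
      title = "Mixture-composition diagnostic",
      subtitle = paste(
        sprintf("%s: observed %.3g (percentile %.2f)",
                obs$statistic, obs$observed, obs$percentile),
        collapse = "   "
      )
    ) +
    ggplot2::theme_minimal()
}
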