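# broom-style tidiers for fitted objects.

#' Tidy a prevalence fit
#'
#' @param x A `prevalence_fit` from [estimate_prevalence()].
#' @param ... Unused.
#' @return A tibble with one row per method: `method`, `estimate`
#'   (`p_case`), `p_noncase`, and method-specific diagnostic columns
#'   (reference median used, reference means, independent EMD estimates and
#'   their deviation from summing to one, KDE weights and residual norm).
#' @method tidy prevalence_fit
#' @export
tidy.prevalence_fit <- function(x, ...) {
  diag_tbl <- purrr::map(x$estimates$diagnostics, function(d) {
    tibble::as_tibble(d[vapply(d, is.numeric, logical(1))])
  })
  dplyr::bind_cols(
    tibble::tibble(
      method = x$estimates$method,
      estimate = x$estimates$p_case,
      p_noncase = x$estimates$p_noncase
    ),
    dplyr::bind_rows(diag_tbl)
  )
}

#' Glance at a prevalence fit
#'
#' @param x A `prevalence_fit`.
#' @param ... Unused.
#' @return A one-row tibble with cohort sizes, the reference AUC and the grid
#'   geometry.
#' @method glance prevalence_fit
#' @export
glance.prevalence_fit <- function(x, ...) {
  tibble::tibble(
    n_mixture = x$n_mixture,
    n_case_ref = x$n_case_ref,
    n_noncase_ref = x$n_noncase_ref,
    auc = x$auc,
    grid_bins = if (is.null(x$grid)) NA_integer_ else length(x$grid$centres),
    grid_h = if (is.null(x$grid)) NA_real_ else x$grid$h
  )
}

#' Tidy a bootstrap confidence interval
#'
#' @param x A `prevalence_ci` from [prevalence_ci()].
#' @param ... Unused.
#' @return A one-row tibble: `method`, `estimate`, `bias`, `conf_low`,
#'   `conf_high`, `ci_defined`, `z0`, `acceleration`.
#' @method tidy prevalence_ci
#' @export
tidy.prevalence_ci <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    estimate = x$p_case,
    bias = x$bias,
    conf_low = x$ci_lo,
    conf_high = x$ci_hi,
    ci_defined = x$ci_defined,
    z0 = x$z0,
    acceleration = x$acceleration
  )
}

#' Glance at a bootstrap confidence interval
#'
#' @param x A `prevalence_ci`.
#' @param ... Unused.
#' @return A one-row tibble with the replication settings and the adjusted
#'   quantile levels actually used.
#' @method glance prevalence_ci
#' @export
glance.prevalence_ci <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_mixtures = x$n_mixtures,
    n_boot = x$n_boot,
    alpha = x$alpha,
    level_low = x$levels[1],
    level_high = x$levels[2],
    seed = x$seed
  )
}

#' Tidy a minimum-mixture-size search
#'
#' @param x A `min_size_result` from [min_mixture_size()].
#' @param ... Unused.
#' @return The per-run tibble (selected size, CI, miss flag per run).
#' @method tidy min_size_result
#' @export
tidy.min_size_result <- function(x, ...) {
  x$runs
}

#' Glance at a minimum-mixture-size search
#'
#' @param x A `min_size_result`.
#' @param ... Unused.
#' @return The one-row summary tibble (median / quartiles of the minimum
#'   size, misses, convergence flag).
#' @method glance min_size_result
#' @export
glance.min_size_result <- function(x, ...) {
  x$summary
}
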