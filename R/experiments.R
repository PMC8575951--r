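# Simulation studies: proportion-by-size sweeps, the minimum-mixture-size
# search, the mixture-composition diagnostic, and trait-mean reconstruction.

#' Sweep mixture proportion and size
#'
#' Evaluates an estimator over a grid of true proportions and mixture sizes.
#' For each cell one mixture is resampled (with replacement) from the
#' hold-out cohorts, the proportion is estimated, and a BCa confidence
#' interval is computed; the cell records the estimate, its bias, the
#' deviation from the true proportion, the CI width, and a miss flag (true
#' when the CI excludes the true value, is degenerate, or is undefined).
#' Cell-level estimator errors are recorded, not fatal.
#'
#' @param references Data frame with the case / non-case reference cohorts.
#' @param holdout Data frame with hold-out case / non-case cohorts (disjoint
#'   from the references) from which mixtures are resampled.
#' @param method One of `"excess"`, `"means"`, `"emd"`, `"kde"`.
#' @param p_grid True proportions to evaluate.
#' @param n_grid Mixture sizes to evaluate.
#' @param alpha,n_mixtures,n_boot Interval settings, see [prevalence_ci()].
#' @param score,cohort,case_label,noncase_label As in [estimate_prevalence()].
#' @param seed Master seed; per-cell seeds are derived from it and the cell
#'   index.
#' @return A tibble of class `prevalence_sweep` with one row per cell.
#' @export
sweep_proportion_size <- function(references, holdout,
                                  method = c("excess", "means", "emd", "kde"),
                                  p_grid = seq(0, 1, by = 0.01),
                                  n_grid = seq(100, 2500, by = 100),
                                  alpha = 0.05, n_mixtures = 100, n_boot = 1000,
                                  score = grs, cohort = cohort,
                                  case_label = "case", noncase_label = "noncase",
                                  seed = 1) {
  method <- match.arg(method)
  refs <- split_cohorts(references, {{ score }}, {{ cohort }},
                        case_label, noncase_label, require_mixture = FALSE)
  hold <- split_cohorts(holdout, {{ score }}, {{ cohort }},
                        case_label, noncase_label, require_mixture = FALSE)
  cells <- tidyr::expand_grid(p_case = p_grid, n = n_grid)
  rows <- purrr::pmap(
    list(cells$p_case, cells$n, seq_len(nrow(cells))),
    function(p, n, cell) {
      mix <- withr::with_seed(derive_seed(seed, 11L, cell), {
        n_case <- round(p * n)
        c(
          sample(hold$cases, n_case, replace = TRUE),
          sample(hold$noncases, n - n_case, replace = TRUE)
        )
      })
      res <- tryCatch(
        ci_core(mix, refs$cases, refs$noncases, method,
                alpha = alpha, n_mixtures = n_mixtures, n_boot = n_boot,
                seed = derive_seed(seed, 12L, cell)),
        error = function(e) NULL
      )
      if (is.null(res)) {
        return(tibble::tibble(
          p_case = p, n = n, estimate = NA_real_, bias = NA_real_,
          deviation = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          ci_width = NA_real_, miss = TRUE, error = TRUE
        ))
      }
      degenerate <- !res$ci_defined || res$ci_lo == res$ci_hi
      tibble::tibble(
        p_case = p, n = n, estimate = res$p_case, bias = res$bias,
        deviation = p - res$p_case, ci_lo = res$ci_lo, ci_hi = res$ci_hi,
        ci_width = res$ci_hi - res$ci_lo,
        miss = degenerate || p < res$ci_lo || p > res$ci_hi,
        error = FALSE
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  class(out) <- c("prevalence_sweep", class(out))
  attr(out, "method") <- method
  attr(out, "settings") <- list(alpha = alpha, n_mixtures = n_mixtures,
                                n_boot = n_boot, seed = seed)
  out
}

#' Minimum mixture size achieving a target CI width
#'
#' Searches, over repeated estimation runs, for the smallest mixture size at
#' which the BCa confidence interval around a target prevalence first becomes
#' narrower than `ci_width_target`. References are synthetic Gaussian cohorts
#' generated once at the requested AUC (or supplied); each run walks a ladder
#' of mixture sizes, drawing a fresh synthetic mixture per size, until the CI
#' is defined and its width drops below the target. A run whose selected CI
#' excludes the true proportion is disregarded as a miss; the reported
#' median and quartiles of the minimum size are taken over the remaining
#' runs. When no run yields a covering interval the search is flagged as
#' non-convergent (the estimator converges to a value away from the truth).
#'
#' @param method One of `"excess"`, `"means"`, `"emd"`, `"kde"`.
#' @param auc Discriminability of the synthetic score.
#' @param p_case True prevalence in the simulated mixtures.
#' @param ci_width_target Required CI width.
#' @param runs Number of independent estimation runs.
#' @param n_step,n_max Ladder of candidate sizes `seq(n_step, n_max, n_step)`.
#' @param coarse_from,coarse_step Optional second ladder phase: above
#'   `coarse_from` sizes advance by `coarse_step` (used for the costlier KDE
#'   method).
#' @param n_ref Reference cohort size (per cohort) when simulating.
#' @param references Optional data frame of reference cohorts overriding the
#'   synthetic generation.
#' @param alpha,n_mixtures,n_boot Interval settings.
#' @param seed Master seed.
#' @return An object of class `min_size_result`: a list with a one-row
#'   `summary` tibble (median / Q25 / Q75 minimum size, misses, runs,
#'   convergence flag) and a per-run `runs` tibble.
#' @export
min_mixture_size <- function(method = c("excess", "means", "emd", "kde"),
                             auc = 0.9, p_case = 0.1, ci_width_target = 0.1,
                             runs = 100, n_step = 100, n_max = 10000,
                             coarse_from = NULL, coarse_step = 500,
                             n_ref = 2000, references = NULL,
                             alpha = 0.05, n_mixtures = 100, n_boot = 1000,
                             seed = 1) {
  method <- match.arg(method)
  if (ci_width_target <= 0) abort("`ci_width_target` must be positive.")
  if (runs < 1) abort("`runs` must be at least 1.")
  offset <- if (auc == 1) 7 else offset_for_auc(auc)
  if (is.null(references)) {
    # One frozen, moment-matched reference draw is reused across all runs and
    # sizes, so results reflect the generator rather than one draw's luck.
    references <- simulate_references(n_ref = n_ref, offset = offset,
                                      seed = derive_seed(seed, 1L),
                                      moment_match = TRUE)
  }
  refs <- split_cohorts(references, grs, cohort, require_mixture = FALSE)
  ladder <- if (is.null(coarse_from) || coarse_from >= n_max) {
    seq(n_step, n_max, by = n_step)
  } else {
    c(seq(n_step, coarse_from, by = n_step),
      seq(coarse_from + coarse_step, n_max, by = coarse_step))
  }

  run_rows <- purrr::map(seq_len(runs), function(r) {
    for (n in ladder) {
      n_case <- round(p_case * n)
      mix <- withr::with_seed(derive_seed(seed, 21L, r, n), {
        c(rnorm(n_case), rnorm(n - n_case) + offset)
      })
      res <- ci_core(mix, refs$cases, refs$noncases, method,
                     alpha = alpha, n_mixtures = n_mixtures, n_boot = n_boot,
                     seed = derive_seed(seed, 22L, r, n))
      width <- res$ci_hi - res$ci_lo
      if (res$ci_defined && width < ci_width_target) {
        return(tibble::tibble(
          run = r, min_n = n, estimate = res$p_case,
          ci_lo = res$ci_lo, ci_hi = res$ci_hi, ci_width = width,
          miss = p_case < res$ci_lo || p_case > res$ci_hi,
          selected = TRUE
        ))
      }
    }
    tibble::tibble(run = r, min_n = NA_real_, estimate = NA_real_,
                   ci_lo = NA_real_, ci_hi = NA_real_, ci_width = NA_real_,
                   miss = TRUE, selected = FALSE)
  })
  run_tbl <- dplyr::bind_rows(run_rows)
  ok <- run_tbl$selected & !run_tbl$miss
  q <- if (any(ok)) {
    quantile(run_tbl$min_n[ok], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  } else {
    rep(NA_real_, 3)
  }
  summary <- tibble::tibble(
    method = method, auc = auc, p_case = p_case,
    ci_width_target = ci_width_target,
    median_min_n = q[2], q25 = q[1], q75 = q[3],
    misses = sum(run_tbl$miss), runs = runs,
    non_selected = sum(!run_tbl$selected),
    converged = any(ok)
  )
  structure(
    list(summary = summary, runs = run_tbl,
         settings = list(alpha = alpha, n_mixtures = n_mixtures,
                         n_boot = n_boot, seed = seed, ladder = ladder,
                         n_ref = n_ref)),
    class = "min_size_result"
  )
}

#' @export
print.min_size_result <- function(x, ...) {
  s <- x$summary
  if (s$converged) {
    cat(sprintf(
      "%s method, AUC %.2f: minimum mixture size for CI width < %.2g around p_case = %.2g\n  median %g [Q25 %g, Q75 %g]; misses %d/%d\n",
      s$method, s$auc, s$ci_width_target, s$p_case,
      s$median_min_n, s$q25, s$q75, s$misses, s$runs
    ))
  } else {
    cat(sprintf(
      "%s method, AUC %.2f: does not converge to p_case = %.2g (misses %d/%d)\n",
      s$method, s$auc, s$p_case, s$misses, s$runs
    ))
  }
  invisible(x)
}

#' Diagnostic for the two-component mixture assumption
#'
#' The estimators assume the mixture contains only individuals drawn from the
#' two reference distributions (so that the case and non-case proportions sum
#' to one). This diagnostic computes two statistics sensitive to violations:
#' the deviation of the two independent EMD estimates from summing to one,
#' `|p_C^EMD + p_N^EMD - 1|`, and the residual sum of squares of the KDE
#' template fit. Each observed value is compared against a Monte-Carlo null
#' distribution obtained by re-generating mixtures from the references under
#' the two-component assumption at the estimated composition, and reported
#' with its empirical percentile (large percentiles flag a violation).
#'
#' @inheritParams estimate_prevalence
#' @param n_rep Number of null-model replicates.
#' @param seed Integer seed.
#' @return A tibble of class `mixture_check` with columns `statistic`,
#'   `observed`, `percentile` and a list-column `null` holding the null
#'   replicates.
#' @export
check_mixture_assumption <- function(data, n_rep = 200,
                                     score = grs, cohort = cohort,
                                     case_label = "case",
                                     noncase_label = "noncase",
                                     mixture_label = "mixture",
                                     seed = 1) {
  co <- split_cohorts(data, {{ score }}, {{ cohort }},
                      case_label, noncase_label, mixture_label)
  grid <- fd_grid(co$cases, co$noncases, co$mixture)
  ctx_e <- emd_context(co$cases, co$noncases, grid)
  ctx_k <- kde_context(co$cases, co$noncases, grid)
  est_e <- est_emd_core(co$mixture, ctx_e)
  est_k <- est_kde_core(co$mixture, ctx_k)
  n <- length(co$mixture)

  null_of <- function(p_hat, f) {
    mixes <- model_mixtures_core(co$cases, co$noncases, p_hat, n, n_rep,
                                 derive_seed(seed, 31L))
    vapply(mixes, f, numeric(1))
  }
  null_e <- null_of(est_e$p_case, function(m) {
    est_emd_core(m, ctx_e)$diagnostics$deviation
  })
  null_k <- null_of(est_k$p_case, function(m) {
    est_kde_core(m, ctx_k)$diagnostics$rss
  })

  out <- tibble::tibble(
    statistic = c("emd_deviation", "kde_rss"),
    observed = c(est_e$diagnostics$deviation, est_k$diagnostics$rss),
    percentile = c(mean(null_e <= est_e$diagnostics$deviation),
                   mean(null_k <= est_k$diagnostics$rss)),
    estimate = c(est_e$p_case, est_k$p_case),
    null = list(null_e, null_k)
  )
  class(out) <- c("mixture_check", class(out))
  out
}

#' Mean of a clinical trait in the genetically defined case group
#'
#' Once the mixture proportion is estimated, the mean of any clinical trait
#' in the (unobserved) case subgroup follows from decomposing the mixture
#' mean: `x_C = (x_M - (1 - p_case) * x_N) / p_case`, where `x_M` and `x_N`
#' are the trait means in the mixture and in the non-case reference.
#'
#' @param mixture_mean Observed trait mean in the mixture cohort.
#' @param noncase_mean Trait mean in the non-case reference.
#' @param p_case Estimated case proportion; must be positive.
#' @return The reconstructed trait mean among cases.
#' @examples
#' case_trait_mean(26, 25, 0.5)
#' @export
case_trait_mean <- function(mixture_mean, noncase_mean, p_case) {
  if (any(p_case <= 0)) {
    abort("Trait reconstruction undefined for zero prevalence (`p_case` must be > 0).")
  }
  (mixture_mean - (1 - p_case) * noncase_mean) / p_case
}
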