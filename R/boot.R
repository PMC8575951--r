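# Monte-Carlo modelled mixtures + bootstrap resampling and BCa intervals.

#' Model new mixtures from the reference cohorts
#'
#' Stochastically re-creates the mixture-generation process: each modelled
#' mixture has the same size as the observed cohort and the composition given
#' by the point estimate, i.e. `round(p_case * n)` scores sampled with
#' replacement from the case reference and the remainder from the non-case
#' reference (so an estimate of 0.3 on a cohort of 1000 yields 300 case-drawn
#' and 700 non-case-drawn values per modelled mixture).
#'
#' @param data A data frame holding the two reference cohorts.
#' @param p_case Composition of the modelled mixtures (typically the point
#'   estimate from [estimate_prevalence()]).
#' @param n Size of each modelled mixture.
#' @param n_mixtures Number of modelled mixtures.
#' @param score,cohort,case_label,noncase_label As in [estimate_prevalence()].
#' @param seed Integer seed.
#' @return A tibble with columns `mixture_id`, `cohort` (`"mixture"`), `grs`.
#' @export
model_mixtures <- function(data, p_case, n, n_mixtures = 100,
                           score = grs, cohort = cohort,
                           case_label = "case", noncase_label = "noncase",
                           seed = 1) {
  co <- split_cohorts(data, {{ score }}, {{ cohort }},
                      case_label, noncase_label, require_mixture = FALSE)
  mixes <- model_mixtures_core(co$cases, co$noncases, p_case, n, n_mixtures, seed)
  tibble::tibble(
    mixture_id = rep(seq_len(n_mixtures), each = n),
    cohort = "mixture",
    grs = unlist(mixes)
  )
}

model_mixtures_core <- function(cases, noncases, p_case, n, n_mixtures, seed) {
  if (p_case < 0 || p_case > 1) abort("`p_case` must be in [0, 1].")
  if (n < 1) abort("`n` must be positive.")
  n_case <- round(p_case * n)
  lapply(seq_len(n_mixtures), function(j) {
    withr::with_seed(derive_seed(seed, 101L, j), {
      c(
        sample(cases, n_case, replace = TRUE),
        sample(noncases, n - n_case, replace = TRUE)
      )
    })
  })
}

# Bootstrap p' estimates: for each modelled mixture, n_boot resamples with
# replacement (same size) scored by the chosen estimator. Method-specific
# precomputation keeps the inner loop cheap; each fast path is tested against
# direct re-estimation.
bootstrap_pprime <- function(modelled, method, ctx, n_boot, seed) {
  n <- length(modelled[[1L]])
  out <- numeric(length(modelled) * n_boot)
  pos <- 0L
  for (j in seq_along(modelled)) {
    mj <- modelled[[j]]
    pre <- switch(method,
      excess = NULL,
      means = NULL,
      emd = centre_bin_index(mj, ctx$grid$centres),
      kde = outer(mj, ctx$grid$centres,
                  function(x, z) dnorm((z - x) / ctx$grid$h)) / ctx$grid$h
    )
    k <- if (method %in% c("emd", "kde")) length(ctx$grid$centres) else 0L
    bin_w <- if (method == "kde") ctx$grid$centres[2L] - ctx$grid$centres[1L] else 0
    withr::with_seed(derive_seed(seed, 202L, j), {
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        out[pos + b] <- switch(method,
          excess = est_excess_core(mj[idx], ctx)$p_case,
          means = means_from_mean(sum(mj[idx]) / n, ctx$mu_cases, ctx$mu_noncases),
          emd = emd_from_cdf(cdf_from_bins(pre[idx], k, n), ctx)$p_case,
          kde = {
            w <- tabulate(idx, nbins = n)
            dens <- as.vector(crossprod(pre, w)) / n
            kde_fit_weights(dens / (sum(dens) * bin_w), ctx)$p_case
          }
        )
      }
    })
    pos <- pos + n_boot
  }
  out
}

# ---- jackknife (leave-one-out over mixture points; references fixed) ------

jackknife_estimates <- function(method, mix, ctx) {
  switch(method,
    excess = jack_excess(mix, ctx),
    means = jack_means(mix, ctx),
    emd = jack_emd(mix, ctx),
    kde = jack_kde(mix, ctx)
  )
}

jack_means <- function(mix, ctx) {
  n <- length(mix)
  mu_loo <- (sum(mix) - mix) / (n - 1)
  means_from_mean(mu_loo, ctx$mu_cases, ctx$mu_noncases)
}

jack_excess <- function(mix, ctx) {
  n <- length(mix)
  ord <- order(mix)
  s <- mix[ord]
  r <- integer(n)
  r[ord] <- seq_len(n) # rank with ties broken by position (loo multiset is
                       # identical whichever duplicate is removed)
  n1 <- n - 1L
  if (n1 %% 2L == 1L) {
    j <- (n1 + 1L) %/% 2L
    med_loo <- ifelse(r > j, s[j], s[j + 1L])
  } else {
    j <- n1 %/% 2L
    v1 <- ifelse(r > j, s[j], s[j + 1L])
    v2 <- ifelse(r > j + 1L, s[j + 1L], s[j + 2L])
    med_loo <- (v1 + v2) / 2
  }
  use_case <- abs(ctx$med_cases - med_loo) < abs(ctx$med_noncases - med_loo)
  m <- ifelse(use_case, ctx$med_cases, ctx$med_noncases)
  cnt_le <- findInterval(m, s) # ties at m count below, as in the estimator
  above <- (n - cnt_le) - (mix > m)
  below <- n1 - above
  clip01(abs(above - below) / n1)
}

jack_emd <- function(mix, ctx, chunk = 2048L) {
  n <- length(mix)
  k <- length(ctx$grid$centres)
  h <- ctx$grid$h
  cnt <- findInterval(ctx$grid$centres, sort(mix)) # #\{x <= z_j\}
  p <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    ind <- outer(mix[rows], ctx$grid$centres, "<=") * 1
    loo <- (matrix(cnt, length(rows), k, byrow = TRUE) - ind) / (n - 1)
    emd_c <- rowSums(abs(sweep(loo, 2L, ctx$cdf_cases))) * h
    emd_n <- rowSums(abs(sweep(loo, 2L, ctx$cdf_noncases))) * h
    p[rows] <- clip01((ctx$emd_refs + emd_n - emd_c) / (2 * ctx$emd_refs))
  }
  p
}

jack_kde <- function(mix, ctx) {
  n <- length(mix)
  centres <- ctx$grid$centres
  bin_w <- centres[2L] - centres[1L]
  K <- outer(mix, centres, function(x, z) dnorm((z - x) / ctx$grid$h)) /
    ctx$grid$h
  S <- colSums(K)
  vapply(seq_len(n), function(i) {
    dens <- (S - K[i, ]) / (n - 1)
    kde_fit_weights(dens / (sum(dens) * bin_w), ctx)$p_case
  }, numeric(1))
}

# ---- BCa machinery ---------------------------------------------------------

#' Median bias of the bootstrap estimates
#'
#' The difference between the median of the Monte-Carlo bootstrap estimates
#' and the point estimate, `B = median(p_prime) - p_case`.
#'
#' @param p_prime Numeric vector of bootstrap estimates.
#' @param p_case The point estimate.
#' @return A scalar.
#' @export
median_bias <- function(p_prime, p_case) {
  check_scores(p_prime, "`p_prime`")
  median(p_prime) - p_case
}

#' Narrowness-bias expanded confidence level
#'
#' Expands a nominal one-sided level via the Student-t quantile,
#' `alpha' = Phi(T^{-1}_{n-1}(alpha) * sqrt(n / (n - 1)))`, to counteract the
#' narrowness bias of bootstrap intervals at finite mixture size `n`.
#'
#' @param alpha One-sided nominal level(s) in (0, 1).
#' @param n Mixture size (the t distribution has `n - 1` degrees of freedom).
#' @return Expanded level(s).
#' @export
expand_level <- function(alpha, n) {
  pnorm(qt(alpha, df = n - 1) * sqrt(n / (n - 1)))
}

#' BCa-adjusted quantile level
#'
#' Applies the bias-corrected and accelerated adjustment to a (narrowness-
#' expanded) one-sided level:
#' `alpha_BCa = Phi(z0 + (z0 + z_a') / (1 - a * (z0 + z_a')))` with
#' `z_a' = qnorm(expand_level(alpha, n))`. With `z0 = 0` and
#' `acceleration = 0` this reduces exactly to the expanded level.
#'
#' @inheritParams expand_level
#' @param z0 Median-bias correction factor.
#' @param acceleration Acceleration factor (skewness correction).
#' @return Adjusted quantile level(s) of the bootstrap distribution.
#' @export
bca_level <- function(alpha, z0, acceleration, n) {
  z_a <- z0 + qnorm(expand_level(alpha, n))
  pnorm(z0 + z_a / (1 - acceleration * z_a))
}

acceleration_factor <- function(p_hat, p_jack) {
  n <- length(p_jack)
  u <- (n - 1) * (p_hat - p_jack)
  denom <- sum(u^2)^(3 / 2)
  if (denom == 0) {
    warn("All jackknife estimates are equal; acceleration set to 0.")
    return(0)
  }
  sum(u^3) / (6 * denom)
}

ci_core <- function(mix, cases, noncases, method, alpha = 0.05,
                    n_mixtures = 100, n_boot = 1000, seed = 1, grid = NULL) {
  method <- match.arg(method, grsmix_methods)
  if (is.null(grid) && method %in% c("emd", "kde")) {
    grid <- fd_grid(cases, noncases, mix)
  }
  ctx <- estimator_context(method, cases, noncases, mix, grid)
  p_hat <- estimate_core(method, mix, ctx)$p_case
  n <- length(mix)

  modelled <- model_mixtures_core(cases, noncases, p_hat, n, n_mixtures, seed)
  p_prime <- bootstrap_pprime(modelled, method, ctx, n_boot, seed)
  n_tot <- length(p_prime)

  bias <- median(p_prime) - p_hat
  n_le <- sum(p_prime <= p_hat)

  p_jack <- jackknife_estimates(method, mix, ctx)
  accel <- acceleration_factor(p_hat, p_jack)

  if (n_le == 0L || n_le == n_tot) {
    # Extreme median bias: the point estimate lies outside (or at the edge
    # of) the bootstrap distribution, z0 is infinite and both limits collapse
    # onto the corresponding extreme of p_prime.
    z0 <- if (n_le == 0L) -Inf else Inf
    lim <- if (n_le == 0L) min(p_prime) else max(p_prime)
    ci <- c(lim, lim)
    levels <- c(NA_real_, NA_real_)
    defined <- FALSE
  } else {
    z0 <- qnorm(n_le / n_tot)
    levels <- bca_level(c(alpha / 2, 1 - alpha / 2), z0, accel, n)
    ci <- unname(quantile(p_prime, levels, type = 7))
    ci <- sort(ci)
    defined <- TRUE
  }

  list(
    method = method, p_case = p_hat, p_prime = p_prime, bias = bias,
    z0 = z0, acceleration = accel, alpha = alpha,
    levels = levels, ci_lo = ci[1], ci_hi = ci[2], ci_defined = defined,
    n = n, n_mixtures = n_mixtures, n_boot = n_boot, seed = seed
  )
}

#' Bootstrap BCa confidence interval for the mixture proportion
#'
#' Quantifies the uncertainty of a prevalence estimate by combining
#' Monte-Carlo modelling of the mixture with bootstrap resampling. First,
#' `n_mixtures` new mixtures of the observed size are composed from the
#' reference cohorts at the point estimate ([model_mixtures()]); each is then
#' resampled `n_boot` times with replacement and re-estimated, giving
#' `n_mixtures * n_boot` bootstrap estimates. The interval is the
#' bias-corrected and accelerated (BCa) bootstrap interval: the median-bias
#' factor `z0` comes from the fraction of bootstrap estimates at or below the
#' point estimate, the acceleration from the jackknife influence values over
#' the observed mixture (references held fixed), and the nominal level is
#' first expanded against narrowness bias ([expand_level()]). If the point
#' estimate falls outside the bootstrap distribution the interval is reported
#' as undefined, with both limits collapsed onto the corresponding extreme.
#'
#' @inheritParams estimate_prevalence
#' @param method One of `"excess"`, `"means"`, `"emd"`, `"kde"`.
#' @param alpha Two-sided nominal level (0.05 for a 95% interval).
#' @param n_mixtures,n_boot Monte-Carlo and bootstrap replication counts.
#' @param seed Integer master seed; all sub-streams derive from it.
#' @return An object of class `prevalence_ci`; see [tidy.prevalence_ci()].
#' @examples
#' d <- simulate_grs_cohorts(auc = 0.9, n_ref = 500, n_mix = 400,
#'                           p_case = 0.3, seed = 7)
#' ci <- prevalence_ci(d, method = "means", n_mixtures = 5, n_boot = 50)
#' tidy(ci)
#' @export
prevalence_ci <- function(data, method = c("excess", "means", "emd", "kde"),
                          alpha = 0.05, n_mixtures = 100, n_boot = 1000,
                          score = grs, cohort = cohort,
                          case_label = "case", noncase_label = "noncase",
                          mixture_label = "mixture",
                          grid = NULL, seed = 1) {
  method <- match.arg(method)
  co <- split_cohorts(data, {{ score }}, {{ cohort }},
                      case_label, noncase_label, mixture_label)
  res <- ci_core(co$mixture, co$cases, co$noncases, method,
                 alpha = alpha, n_mixtures = n_mixtures, n_boot = n_boot,
                 seed = seed, grid = grid)
  class(res) <- "prevalence_ci"
  res
}

#' @export
print.prevalence_ci <- function(x, ...) {
  cat(sprintf(
    "%s method: p_case = %.4f, %g%% BCa CI [%.4f, %.4f]%s\n",
    x$method, x$p_case, 100 * (1 - x$alpha), x$ci_lo, x$ci_hi,
    if (x$ci_defined) "" else " (undefined: extreme median bias)"
  ))
  cat(sprintf(
    "  bias = %.4f, z0 = %.3f, acceleration = %.4f (n = %d, %d x %d bootstrap estimates)\n",
    x$bias, x$z0, x$acceleration, x$n, x$n_mixtures, x$n_boot
  ))
  invisible(x)
}
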