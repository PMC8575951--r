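#' Mean offset of the non-case generator for a target AUC
#'
#' Under the binormal model with unit standard deviations, two Gaussian score
#' distributions whose means differ by `d` have discriminability
#' `AUC = Phi(d / sqrt(2))`; inverting gives `d = sqrt(2) * qnorm(auc)`.
#' Rounded to two decimals this reproduces the canonical synthetic offsets
#' (0.74 at AUC 0.7, 1.81 at AUC 0.9).
#'
#' @param auc Target AUC in `[0.5, 1)`.
#' @return The mean offset (a non-negative scalar).
#' @examples
#' round(offset_for_auc(0.7), 2)
#' @export
offset_for_auc <- function(auc) {
  if (!is.numeric(auc) || length(auc) != 1L || is.na(auc)) {
    abort("`auc` must be a single number.")
  }
  if (auc >= 1) {
    abort(paste0(
      "AUC = 1 implies an infinite offset; complete separation is emulated ",
      "with a sentinel offset of 7 (see `simulate_references(offset = 7)`)."
    ))
  }
  if (auc < 0.5) abort("`auc` must be at least 0.5.")
  sqrt(2) * qnorm(auc)
}

#' Simulate Gaussian reference cohorts at a target AUC
#'
#' Draws the case reference from N(0, 1) and the non-case reference from
#' N(offset, 1), where the offset is either given directly or derived from a
#' target AUC via [offset_for_auc()]. (In this synthetic design the non-case
#' generator is the shifted one; the case generator mean is always 0.)
#'
#' @param n_ref Number of individuals per reference cohort.
#' @param auc Target AUC (ignored when `offset` is given). `auc = 1` is
#'   emulated with a sentinel offset of 7.
#' @param offset Mean of the non-case generator.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param moment_match If `TRUE`, each reference sample is recentred and
#'   rescaled to the exact generator moments (mean 0 or `offset`, SD 1).
#'   Intended for experiments that freeze one reference draw and reuse it
#'   throughout: it guarantees the frozen draw is representative of its
#'   generator rather than an outlier. Default `FALSE`.
#' @return A tibble with columns `cohort` (`"case"` / `"noncase"`) and `grs`.
#' @examples
#' refs <- simulate_references(n_ref = 1000, auc = 0.7, seed = 1)
#' @export
simulate_references <- function(n_ref = 2000, auc = NULL, offset = NULL,
                                seed = 1, moment_match = FALSE) {
  if (is.null(offset)) {
    if (is.null(auc)) abort("Provide either `auc` or `offset`.")
    offset <- if (auc == 1) 7 else offset_for_auc(auc)
  }
  if (n_ref < 2) abort("`n_ref` must be at least 2.")
  withr::with_seed(seed, {
    cases <- rnorm(n_ref)
    noncases <- rnorm(n_ref) + offset
  })
  if (moment_match) {
    cases <- (cases - mean(cases)) / stats::sd(cases)
    noncases <- (noncases - mean(noncases)) / stats::sd(noncases) + offset
  }
  tibble::tibble(
    cohort = rep(c("case", "noncase"), each = n_ref),
    grs = c(cases, noncases)
  )
}

#' Simulate a Gaussian mixture cohort
#'
#' Draws `round(p_case * n)` scores from the case generator N(0, 1) and the
#' remainder from the shifted non-case generator N(offset, 1), using draws
#' independent of any reference sample. (Counts use R's round-half-to-even.)
#'
#' @param n Mixture size.
#' @param p_case True proportion of cases in `[0, 1]`.
#' @inheritParams simulate_references
#' @return A tibble with columns `cohort` (`"mixture"`) and `grs`.
#' @export
simulate_mixture <- function(n, p_case, auc = NULL, offset = NULL, seed = 1) {
  if (is.null(offset)) {
    if (is.null(auc)) abort("Provide either `auc` or `offset`.")
    offset <- if (auc == 1) 7 else offset_for_auc(auc)
  }
  if (p_case < 0 || p_case > 1) abort("`p_case` must be in [0, 1].")
  if (n < 1) abort("`n` must be positive.")
  n_case <- round(p_case * n)
  withr::with_seed(seed, {
    x <- c(rnorm(n_case), rnorm(n - n_case) + offset)
  })
  tibble::tibble(cohort = "mixture", grs = x)
}

#' Simulate reference and mixture cohorts together
#'
#' Convenience wrapper combining [simulate_references()] and
#' [simulate_mixture()] (with independent sub-seeds derived from `seed`) into
#' one long tibble ready for [estimate_prevalence()].
#'
#' @inheritParams simulate_references
#' @param n_mix Mixture size.
#' @param p_case True mixture proportion of cases.
#' @return A tibble with columns `cohort` and `grs` for all three cohorts.
#' @export
simulate_grs_cohorts <- function(auc = NULL, offset = NULL, n_ref = 2000,
                                 n_mix = 5000, p_case = 0.1, seed = 1) {
  dplyr::bind_rows(
    simulate_references(n_ref = n_ref, auc = auc, offset = offset,
                        seed = derive_seed(seed, 1)),
    simulate_mixture(n = n_mix, p_case = p_case, auc = auc, offset = offset,
                     seed = derive_seed(seed, 2))
  )
}

#' Construct a mixture by resampling hold-out cohorts
#'
#' Builds a mixture of size `n` by sampling with replacement
#' `round(p_case * n)` scores from hold-out cases and the remainder from
#' hold-out non-cases. The hold-out cohorts should be disjoint from the
#' reference cohorts used for estimation. Sampling with replacement permits
#' mixtures larger than the hold-out sets.
#'
#' @param holdout A data frame of hold-out scores with case / non-case labels.
#' @param p_case True proportion of cases.
#' @param n Mixture size.
#' @param score,cohort,case_label,noncase_label As in [estimate_prevalence()].
#' @param seed Integer seed.
#' @return A tibble with columns `cohort` (`"mixture"`) and `grs`.
#' @export
resample_mixture <- function(holdout, p_case, n,
                             score = grs, cohort = cohort,
                             case_label = "case", noncase_label = "noncase",
                             seed = 1) {
  co <- split_cohorts(holdout, {{ score }}, {{ cohort }},
                      case_label, noncase_label, require_mixture = FALSE)
  if (p_case < 0 || p_case > 1) abort("`p_case` must be in [0, 1].")
  n_case <- round(p_case * n)
  withr::with_seed(seed, {
    x <- c(
      sample(co$cases, n_case, replace = TRUE),
      sample(co$noncases, n - n_case, replace = TRUE)
    )
  })
  tibble::tibble(cohort = "mixture", grs = x)
}

auc_mann_whitney <- function(cases, noncases) {
  n_c <- as.double(length(cases))
  n_n <- as.double(length(noncases))
  r <- rank(c(cases, noncases))
  u <- sum(r[seq_len(n_c)]) - n_c * (n_c + 1) / 2
  u / (n_c * n_n)
}

#' Mann-Whitney AUC of the reference pair
#'
#' The probability that a randomly drawn case score exceeds a randomly drawn
#' non-case score, with ties counted half (the normalised Mann-Whitney U
#' statistic; equivalently the area under the ROC curve for classifying case
#' vs non-case by score, in the case-high direction). Values below 0.5 simply
#' indicate that non-cases score higher; discriminability is
#' `max(auc, 1 - auc)`.
#'
#' @inheritParams estimate_prevalence
#' @return A scalar in `[0, 1]`.
#' @examples
#' d <- simulate_references(n_ref = 500, auc = 0.8, seed = 2)
#' compute_auc(d)
#' @export
compute_auc <- function(data, score = grs, cohort = cohort,
                        case_label = "case", noncase_label = "noncase") {
  co <- split_cohorts(data, {{ score }}, {{ cohort }},
                      case_label, noncase_label, require_mixture = FALSE)
  auc_mann_whitney(co$cases, co$noncases)
}
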