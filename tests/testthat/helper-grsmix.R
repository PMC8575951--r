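# Shared fixtures and independent oracles.

# Exact 1-D Wasserstein distance between empirical samples: the integral of
# |F_a - F_b| over the union of breakpoints (both ECDFs are right-continuous
# step functions, constant between consecutive breakpoints).
exact_w1 <- function(a, b) {
  z <- sort(unique(c(a, b)))
  if (length(z) < 2) return(0)
  fa <- stats::ecdf(a)(z[-length(z)])
  fb <- stats::ecdf(b)(z[-length(z)])
  sum(abs(fa - fb) * diff(z))
}

# Naive leave-one-out jackknife: re-run the full estimator on each reduced
# mixture (grid and reference context held fixed).
naive_jackknife <- function(method, mix, ctx) {
  vapply(seq_along(mix), function(i) {
    grsmix:::estimate_core(method, mix[-i], ctx)$p_case
  }, numeric(1))
}

# Long cohort tibble from three score vectors.
cohort_tbl <- function(cases, noncases, mixture = NULL) {
  d <- dplyr::bind_rows(
    tibble::tibble(cohort = "case", grs = cases),
    tibble::tibble(cohort = "noncase", grs = noncases)
  )
  if (!is.null(mixture)) {
    d <- dplyr::bind_rows(d, tibble::tibble(cohort = "mixture", grs = mixture))
  }
  d
}

# Pull one cohort's scores back out of a long tibble.
scores_of <- function(data, label) data$grs[data$cohort == label]
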