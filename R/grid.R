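#' Shared evaluation grid from the Freedman-Diaconis rule
#'
#' Builds the common grid on which empirical CDFs (for the EMD estimator) and
#' kernel-density templates (for the KDE estimator) are evaluated. The bin
#' width is the Freedman-Diaconis width `h = 2 * IQR / n^(1/3)` computed on
#' the two reference cohorts pooled together (quantile type 7); the support is
#' the interval from the minimum to the maximum score over all three cohorts.
#' Bin centres start at `support_lo + h/2` and advance in steps of `h` until
#' the support is covered (the final, possibly partial, bin is retained).
#'
#' @param cases,noncases Numeric vectors of reference-cohort scores.
#' @param mixture Numeric vector of mixture-cohort scores.
#' @return An object of class `grs_grid`: a list with elements `support`
#'   (length-2 numeric), `h` (bin width, also the KDE bandwidth) and
#'   `centres` (increasing numeric vector of bin centres).
#' @examples
#' g <- fd_grid(rnorm(500), rnorm(500) + 1, rnorm(200) + 0.5)
#' g$h
#' @export
fd_grid <- function(cases, noncases, mixture) {
  check_scores(cases, "case reference scores")
  check_scores(noncases, "non-case reference scores")
  check_scores(mixture, "mixture scores")
  refs <- c(cases, noncases)
  iqr <- IQR(refs, type = 7)
  if (iqr <= 0) {
    abort("Combined reference cohorts have zero IQR; grid is degenerate.")
  }
  h <- 2 * iqr / length(refs)^(1 / 3)
  lo <- min(cases, noncases, mixture)
  hi <- max(cases, noncases, mixture)
  k <- max(1L, ceiling((hi - lo) / h))
  centres <- lo + h / 2 + (seq_len(k) - 1) * h
  structure(
    list(support = c(lo, hi), h = h, centres = centres),
    class = "grs_grid"
  )
}

#' @export
print.grs_grid <- function(x, ...) {
  cat(sprintf(
    "<grs_grid> %d bins of width %.4g on [%.4g, %.4g]\n",
    length(x$centres), x$h, x$support[1], x$support[2]
  ))
  invisible(x)
}

grid_covers <- function(grid, x, tol = 1e-8) {
  min(x) >= grid$support[1] - tol && max(x) <= grid$support[2] + tol
}

# Right-continuous empirical CDF evaluated at the grid centres.
cdf_at <- function(x, centres) {
  findInterval(centres, sort(x)) / length(x)
}

# Bin index c_i = number of centres strictly below x_i (so that the CDF at
# centre j over a subsample idx is cumsum(tabulate(c[idx] + 1))[j] / n).
centre_bin_index <- function(x, centres) {
  findInterval(x, centres, left.open = TRUE)
}

cdf_from_bins <- function(bins, k, n) {
  cumsum(tabulate(bins + 1L, nbins = k + 1L))[seq_len(k)] / n
}
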