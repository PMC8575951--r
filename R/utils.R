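# Internal helpers: validation, deterministic seed derivation, column capture.

check_scores <- function(x, what = "scores") {
  if (length(x) == 0L) {
    abort(sprintf("%s must be non-empty.", what))
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("%s must be finite numeric values.", what))
  }
  invisible(x)
}

# Deterministic sub-stream seeds: fold indices into a 31-bit state with an
# LCG-style mix. Products stay below 2^53 so doubles are exact.
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (i in c(...)) {
    s <- (s * 69069 + as.double(i) + 12345) %% 2147483647
  }
  as.integer(s)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# Pull the three cohorts out of a long data frame of per-individual scores.
split_cohorts <- function(data, score, cohort,
                          case_label = "case",
                          noncase_label = "noncase",
                          mixture_label = "mixture",
                          require_mixture = TRUE) {
  score <- enquo(score)
  cohort <- enquo(cohort)
  sc <- dplyr::pull(data, !!score)
  lab <- dplyr::pull(data, !!cohort)
  take <- function(label, what, required = TRUE) {
    x <- sc[lab == label]
    if (length(x) == 0L && !required) return(NULL)
    check_scores(x, sprintf("%s scores (cohort label '%s')", what, label))
    x
  }
  if (identical(case_label, noncase_label)) {
    abort("case and non-case cohort labels must be distinct.")
  }
  list(
    cases = take(case_label, "case reference"),
    noncases = take(noncase_label, "non-case reference"),
    mixture = take(mixture_label, "mixture", required = require_mixture)
  )
}
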