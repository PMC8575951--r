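# References used across estimator tests: medians/means known exactly.

test_that("excess method counts the surplus around the nearer reference median", {
  rc <- c(2, 3)            # median 2.5
  rn <- c(20, 21)          # median 20.5, far from every mixture median used
  d <- cohort_tbl(rc, rn, c(1, 2, 3, 4))          # mixture median 2.5 -> m = 2.5
  est <- tidy(estimate_prevalence(d, "excess"))
  expect_equal(est$estimate, 0)

  d2 <- cohort_tbl(rc, rn, c(1, 2, 3, 10, 11, 12)) # 4 above, 2 at/below m = 2.5
  expect_equal(tidy(estimate_prevalence(d2, "excess"))$estimate, 1 / 3)

  d3 <- cohort_tbl(rc, rn, c(5, 6, 7, 8))          # entirely above m
  expect_equal(tidy(estimate_prevalence(d3, "excess"))$estimate, 1)
})

test_that("excess median ties break toward the non-case reference and ties at m count below", {
  rc <- c(3, 3); rn <- c(2, 2)                     # |3 - 2.5| == |2 - 2.5|
  d <- cohort_tbl(rc, rn, c(2, 3))                 # mixture median 2.5
  fit <- estimate_prevalence(d, "excess")
  expect_equal(fit$estimates$diagnostics[[1]]$reference_used, "noncase")
  expect_equal(fit$estimates$diagnostics[[1]]$reference_median, 2)
  # m = 2: scores equal to m count on the 'below' side
  expect_equal(fit$estimates$p_case, 0)            # one at m, one above
})

test_that("means method interpolates between reference means with 0/1 edge rules", {
  rc <- c(0.5, 1.5)        # mean 1
  rn <- c(-0.5, 0.5)       # mean 0
  expect_equal(tidy(estimate_prevalence(
    cohort_tbl(rc, rn, c(0.2, 0.4)), "means"))$estimate, 0.3)
  expect_equal(tidy(estimate_prevalence(
    cohort_tbl(rc, rn, c(1.1, 1.3)), "means"))$estimate, 1)
  expect_equal(tidy(estimate_prevalence(
    cohort_tbl(rc, rn, c(-0.2, 0.0)), "means"))$estimate, 0)
  expect_error(estimate_prevalence(cohort_tbl(c(0, 2), c(0.5, 1.5), c(1, 1)),
                                   "means"),
               "equal reference means")
})

test_that("means estimate is monotone in the mixture mean between the reference means", {
  rc <- rnorm(100, 2, 0.4); rn <- rnorm(100, 0, 0.4)
  mus <- seq(mean(rn), mean(rc), length.out = 11)
  ests <- vapply(mus, function(mu) {
    grsmix:::est_means_core(c(mu - 0.1, mu + 0.1),
                            grsmix:::means_context(rc, rn))$p_case
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("emd_1d matches the exact sorted-sample Wasserstein oracle", {
  expect_equal(emd_1d(c(1, 2, 3), c(1, 2, 3),
                      fd_grid(c(1, 2, 3), c(1.1, 2.1, 3.1), c(1, 3))), 0)

  # point masses at 0 and 1: unit transport cost, resolved to one bin
  a <- rep(0, 50); b <- rep(1, 50)
  g <- fd_grid(c(a, -0.5, 0.5), c(b, 0.5, 1.5), c(a, b))
  expect_equal(emd_1d(a, b, g), 1, tolerance = g$h)

  # random samples: agreement with the exact oracle within 2 bin widths
  for (s in 1:8) {
    set.seed(s)
    a <- rnorm(120 + 10 * s)
    b <- rnorm(150, 0.8, 1.2)
    g <- fd_grid(a, b, c(a, b))
    expect_equal(emd_1d(a, b, g), exact_w1(a, b), tolerance = 2 * g$h)
    expect_equal(emd_1d(a, b, g), emd_1d(b, a, g)) # symmetry
  }

  # equal-SD Gaussians offset by d: distance approaches d
  set.seed(42)
  a <- rnorm(20000); b <- rnorm(20000) + 1.3
  g <- fd_grid(a, b, c(a, b))
  expect_equal(emd_1d(a, b, g), 1.3, tolerance = 0.05)
})

test_that("EMD estimator hits the pure-mixture extremes and reports the sum deviation", {
  set.seed(7)
  rc <- rnorm(300); rn <- rnorm(300) + 1.5
  fit <- estimate_prevalence(cohort_tbl(rc, rn, rc), "emd")
  expect_equal(fit$estimates$p_case, 1)
  expect_equal(fit$estimates$diagnostics[[1]]$deviation, 0, tolerance = 1e-12)
  fit0 <- estimate_prevalence(cohort_tbl(rc, rn, rn), "emd")
  expect_equal(fit0$estimates$p_case, 0)
  expect_error(estimate_prevalence(cohort_tbl(rc, rc, rn), "emd"), "identical")
})

test_that("KDE estimator recovers pure and balanced mixtures", {
  set.seed(8)
  rc <- rnorm(400); rn <- rnorm(400) + 1.6
  expect_gt(tidy(estimate_prevalence(cohort_tbl(rc, rn, rc), "kde"))$estimate,
            0.97)
  pooled <- c(rc, rn)
  expect_equal(tidy(estimate_prevalence(cohort_tbl(rc, rn, pooled),
                                        "kde"))$estimate,
               0.5, tolerance = 0.03)
})

test_that("all estimators stay in [0,1] and complement to one", {
  for (s in 1:6) {
    d <- simulate_grs_cohorts(auc = 0.7 + 0.04 * s, n_ref = 300, n_mix = 250,
                              p_case = s / 7, seed = s)
    est <- tidy(estimate_prevalence(d))
    expect_true(all(est$estimate >= 0 & est$estimate <= 1))
    expect_equal(est$estimate + est$p_noncase, rep(1, 4))
  }
})

test_that("swapping reference labels maps the estimate to its complement", {
  for (s in 1:4) {
    d <- simulate_grs_cohorts(auc = 0.8, n_ref = 300, n_mix = 300,
                              p_case = 0.3, seed = 10 + s)
    swapped <- dplyr::mutate(d, cohort = dplyr::recode(
      cohort, case = "noncase", noncase = "case"))
    for (m in c("means", "emd", "kde")) {
      p <- tidy(estimate_prevalence(d, m))$estimate
      p_sw <- tidy(estimate_prevalence(swapped, m))$estimate
      expect_equal(p_sw, 1 - p, tolerance = 1e-6)
    }
  }
})

test_that("adding a constant to every score leaves all four estimates unchanged", {
  d <- simulate_grs_cohorts(auc = 0.8, n_ref = 400, n_mix = 300,
                            p_case = 0.4, seed = 21)
  shifted <- dplyr::mutate(d, grs = grs + 3.7)
  e1 <- tidy(estimate_prevalence(d))
  e2 <- tidy(estimate_prevalence(shifted))
  expect_equal(e2$estimate, e1$estimate, tolerance = 1e-10)
})

test_that("excess underestimates on symmetric Gaussian mixtures", {
  # equal-SD Gaussian synthetic design, pC = 0.5, AUC 0.75, n = 5000
  off <- offset_for_auc(0.75)
  refs <- simulate_references(2000, offset = off, seed = 1,
                              moment_match = TRUE)
  rc <- scores_of(refs, "case"); rn <- scores_of(refs, "noncase")
  ctx <- grsmix:::excess_context(rc, rn)
  ests <- vapply(1:50, function(s) {
    mix <- withr::with_seed(s, c(rnorm(2500), rnorm(2500) + off))
    grsmix:::est_excess_core(mix, ctx)$p_case
  }, numeric(1))
  expect_lt(median(ests), 0.5)
})
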