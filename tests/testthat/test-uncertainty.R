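test_that("modelled mixtures have the prescribed composition and draw only reference values", {
  set.seed(3)
  refs <- cohort_tbl(rnorm(200), rnorm(200) + 10)
  mm <- model_mixtures(refs, p_case = 0.3, n = 1000, n_mixtures = 3, seed = 5)
  expect_equal(nrow(mm), 3000)
  cases <- scores_of(refs, "case")
  for (j in 1:3) {
    mj <- mm$grs[mm$mixture_id == j]
    expect_equal(sum(mj %in% cases), 300)     # 300 case-drawn, 700 non-case
    expect_true(all(mj %in% refs$grs))
  }
  m0 <- model_mixtures(refs, p_case = 0, n = 100, n_mixtures = 1, seed = 1)
  expect_equal(sum(m0$grs %in% cases), 0)
  m1 <- model_mixtures(refs, p_case = 1, n = 7, n_mixtures = 1, seed = 1)
  expect_equal(sum(m1$grs %in% cases), 7)
})

test_that("bootstrap estimates count n_mixtures x n_boot and are seed-deterministic", {
  set.seed(11)
  rc <- rnorm(150); rn <- rnorm(150) + 1.5
  mix <- c(rnorm(60), rnorm(140) + 1.5)
  ci1 <- grsmix:::ci_core(mix, rc, rn, "means", n_mixtures = 2, n_boot = 3, seed = 9)
  expect_length(ci1$p_prime, 6)
  ci2 <- grsmix:::ci_core(mix, rc, rn, "means", n_mixtures = 2, n_boot = 3, seed = 9)
  expect_identical(ci1$p_prime, ci2$p_prime)
  ci3 <- grsmix:::ci_core(mix, rc, rn, "means", n_mixtures = 2, n_boot = 3, seed = 10)
  expect_false(identical(ci1$p_prime, ci3$p_prime))
})

test_that("fast bootstrap paths agree exactly with direct re-estimation", {
  set.seed(12)
  rc <- rnorm(200); rn <- rnorm(200) + 1.6
  mix <- c(rnorm(50), rnorm(100) + 1.6)
  grid <- fd_grid(rc, rn, mix)
  n <- length(mix)
  for (m in c("excess", "means", "emd", "kde")) {
    ctx <- grsmix:::estimator_context(m, rc, rn, mix, grid)
    modelled <- grsmix:::model_mixtures_core(rc, rn, 0.3, n, 2, seed = 4)
    fast <- grsmix:::bootstrap_pprime(modelled, m, ctx, n_boot = 5, seed = 4)
    # replay the identical resampling stream, estimating directly
    naive <- numeric(0)
    for (j in 1:2) {
      withr::with_seed(grsmix:::derive_seed(4, 202L, j), {
        for (b in 1:5) {
          idx <- sample.int(n, n, replace = TRUE)
          naive <- c(naive,
                     grsmix:::estimate_core(m, modelled[[j]][idx], ctx)$p_case)
        }
      })
    }
    expect_equal(fast, naive, tolerance = 1e-10, label = m)
  }
})

test_that("fast jackknife paths agree with naive leave-one-out re-estimation", {
  set.seed(13)
  rc <- rnorm(150); rn <- rnorm(150) + 1.4
  for (n_mix in c(60, 61)) {      # even and odd leave-one-out sizes
    mix <- c(rnorm(n_mix %/% 3), rnorm(n_mix - n_mix %/% 3) + 1.4)
    grid <- fd_grid(rc, rn, mix)
    for (m in c("excess", "means", "emd", "kde")) {
      ctx <- grsmix:::estimator_context(m, rc, rn, mix, grid)
      fast <- grsmix:::jackknife_estimates(m, mix, ctx)
      expect_equal(fast, naive_jackknife(m, mix, ctx),
                   tolerance = if (m == "kde") 1e-6 else 1e-12,
                   label = paste(m, n_mix))
    }
  }
})

test_that("median bias is the median of bootstrap estimates minus the point estimate", {
  expect_equal(median_bias(c(0.1, 0.2, 0.3), 0.1), 0.1)
  expect_equal(median_bias(seq(0, 0.2, by = 0.01), 0.1), 0)
})

test_that("level expansion and BCa adjustment obey their closed forms", {
  a <- c(0.025, 0.975)
  n <- 500
  expect_equal(expand_level(a, n), pnorm(qt(a, n - 1) * sqrt(n / (n - 1))))
  expect_lt(expand_level(0.025, 50), 0.025)    # expansion widens the interval
  expect_gt(expand_level(0.975, 50), 0.975)
  # with no median bias and no acceleration the BCa level is the expanded level
  expect_equal(bca_level(a, z0 = 0, acceleration = 0, n = n),
               expand_level(a, n))
  # positive z0 shifts both levels upward
  expect_true(all(bca_level(a, 0.3, 0, n) > expand_level(a, n)))
})

test_that("degenerate jackknife spread yields zero acceleration with a warning", {
  rc <- c(0, 1); rn <- c(9, 10)
  mix <- rep(5, 40)      # constant mixture: all leave-one-out means equal
  expect_warning(
    ci <- grsmix:::ci_core(mix, rc, rn, "means", n_mixtures = 2, n_boot = 20,
                           seed = 2),
    "acceleration"
  )
  expect_equal(ci$acceleration, 0)
})

test_that("a point estimate outside the bootstrap range collapses the interval", {
  set.seed(14)
  rc <- rnorm(100, 1); rn <- rnorm(100)
  mix <- rnorm(80, 1.5)      # mean above both references -> estimate exactly 1
  ci <- grsmix:::ci_core(mix, rc, rn, "means", n_mixtures = 5, n_boot = 40,
                         seed = 3)
  expect_equal(ci$p_case, 1)
  expect_false(ci$ci_defined)
  expect_identical(ci$z0, Inf)
  expect_equal(ci$ci_lo, max(ci$p_prime))
  expect_equal(ci$ci_hi, max(ci$p_prime))
})

test_that("confidence intervals narrow as the mixture grows", {
  off <- offset_for_auc(0.85)
  refs <- simulate_references(1000, offset = off, seed = 30,
                              moment_match = TRUE)
  rc <- scores_of(refs, "case"); rn <- scores_of(refs, "noncase")
  med_width <- vapply(c(500, 1000, 5000), function(n) {
    widths <- vapply(1:3, function(s) {
      mix <- withr::with_seed(100 * n + s,
                              c(rnorm(round(0.1 * n)),
                                rnorm(n - round(0.1 * n)) + off))
      ci <- grsmix:::ci_core(mix, rc, rn, "means", n_mixtures = 10,
                             n_boot = 100, seed = s)
      ci$ci_hi - ci$ci_lo
    }, numeric(1))
    median(widths)
  }, numeric(1))
  expect_true(all(diff(med_width) < 0))
})

test_that("prevalence_ci returns a tidy one-row summary", {
  d <- simulate_grs_cohorts(auc = 0.9, n_ref = 300, n_mix = 300,
                            p_case = 0.4, seed = 17)
  ci <- prevalence_ci(d, "emd", n_mixtures = 4, n_boot = 50, seed = 2)
  td <- tidy(ci)
  expect_equal(nrow(td), 1)
  expect_true(td$conf_low <= td$estimate && td$estimate <= td$conf_high)
  gl <- glance(ci)
  expect_equal(gl$n_mixtures, 4)
  expect_equal(gl$n_boot, 50)
})

test_that("full-replication CI widths cross the 0.1 target near the characterised sizes", {
  # At n_mixtures = 30, n_boot = 300 the extreme BCa quantiles are no longer
  # truncated by the bootstrap sample; the width-vs-size curve should then
  # bracket the known crossing sizes at AUC 0.9, p_case = 0.1 (EMD ~1000,
  # Means ~1100-1200).
  off <- offset_for_auc(0.9)
  refs <- simulate_references(2000, offset = off, seed = grsmix:::derive_seed(1, 1),
                              moment_match = TRUE)
  rc <- scores_of(refs, "case"); rn <- scores_of(refs, "noncase")
  width_at <- function(method, n) {
    ws <- vapply(1:3, function(s) {
      mix <- withr::with_seed(grsmix:::derive_seed(s, n),
                              c(rnorm(round(0.1 * n)),
                                rnorm(n - round(0.1 * n)) + off))
      ci <- grsmix:::ci_core(mix, rc, rn, method, n_mixtures = 30,
                             n_boot = 300, seed = s)
      ci$ci_hi - ci$ci_lo
    }, numeric(1))
    median(ws)
  }
  expect_gt(width_at("emd", 700), 0.1)
  expect_lt(width_at("emd", 1200), 0.1)
  expect_gt(width_at("means", 800), 0.1)
  expect_lt(width_at("means", 1400), 0.1)
})
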