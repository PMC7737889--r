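test_that("Welch t-test matches a permutation oracle and basic identities", {
  # fixture MMSE separation
  tab <- suppressWarnings(load_mmse_fixture())
  wt <- welch_t(tab$mmse[tab$diagnosis == "Normal"],
                tab$mmse[tab$diagnosis == "Mild AD"])
  expect_lt(wt$p, 1e-4)
  expect_gt(wt$t, 0)

  # identical samples: t = 0, p = 1
  a <- c(1, 2, 3, 4)
  wt0 <- welch_t(a, a)
  expect_equal(wt0$t, 0)
  expect_equal(wt0$p, 1)

  # exact permutation agreement at n = 5 with a large effect
  withr::with_seed(5, {
    x <- rnorm(5, 0, 1)
    y <- rnorm(5, 3, 1)
  })
  expect_lt(abs(welch_t(x, y)$p - h_perm_p(x, y)), 0.05)

  # label-swap antisymmetry
  expect_equal(welch_t(x, y)$t, -welch_t(y, x)$t)
  expect_equal(welch_t(x, y)$p, welch_t(y, x)$p)

  expect_error(welch_t(1, a), "n >= 2")
  expect_error(welch_t(c(2, 2), c(2, 2)), "zero variance")
})

test_that("BH step-up equals the brute-force definition on random p-vectors", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.03, 0.9), 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 10), 0.05)))
  expect_true(bh_fdr(0.04, 0.05))

  withr::with_seed(101, {
    for (i in 1:1000) {
      m <- sample(1:30, 1)
      p <- switch(sample(3, 1),
                  runif(m),
                  runif(m)^3,          # enrich small p
                  round(runif(m), 2))  # ties
      q <- sample(c(0.01, 0.05, 0.1), 1)
      got <- bh_fdr(p, q)
      expect_identical(got, h_bh_oracle(p, q))
      # cross-check against the standard adjusted-p route
      expect_identical(got, unname(p.adjust(p, "BH") <= q))
    }
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(0.5, q = 1.2), "invalid FDR")
})

test_that("m_eff shrinks the BH denominator and is admissible", {
  p <- c(0.03, 0.2, 0.5)
  expect_false(any(bh_fdr(p, 0.05)))              # 0.03 > 0.05/3
  expect_true(any(bh_fdr(p, 0.05, m_eff = 1.5)))  # 0.03 <= 0.05/1.5
  expect_error(bh_fdr(p, 0.05, m_eff = 5), "m_eff")
})

test_that("effective test count collapses duplicates, keeps independents, is monotone", {
  withr::with_seed(7, {
    base <- rnorm(200)
    dup <- matrix(rep(base, 6), ncol = 6)
    expect_lt(effective_test_count(dup + 1e-8 * rnorm(length(dup))), 1.2)

    indep <- matrix(rnorm(200 * 6), ncol = 6)
    expect_gt(effective_test_count(indep), 0.9 * 6)

    m_at_rho <- vapply(c(0, 0.5, 0.9), function(rho) {
      z <- rnorm(500)
      X <- vapply(1:6, function(j) sqrt(rho) * z + sqrt(1 - rho) * rnorm(500),
                  numeric(500))
      effective_test_count(X)
    }, numeric(1))
    expect_true(all(diff(m_at_rho) < 0))
  })
  expect_error(effective_test_count(cbind(1:5, rep(2, 5))), "constant")
  expect_error(effective_test_count(matrix(1:4, 2, 2)), "three subjects")
})

test_that("odor selection returns 24 results and honors group structure", {
  sim <- h_small_cohort(seed = 31, effects = "recovery")
  sel <- select_significant_odors(sim$cohort)
  expect_equal(nrow(sel$results), 24)
  expect_identical(sel$results$item, paste0("Q", 1:24))
  expect_true(all(sel$results$p >= 0 & sel$results$p <= 1))
  expect_identical(sel$selected, which(sel$results$significant))
  one_group <- sim$cohort[sim$cohort$group == "AD", ]
  expect_error(select_significant_odors(one_group), "both groups")
})

test_that("under zero group effects odor selection is usually empty", {
  hits <- vapply(1:30, function(s) {
    sim <- generate_cohort(cohort_config(seed = s, effects = "null",
                                         subject_sigma = 0, age_slope = 0),
                           recordings = FALSE)
    length(select_significant_odors(sim$cohort)$selected) > 0
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("age lines fit the healthy group exactly and residuals behave", {
  ages <- c(60, 65, 70, 75, 80, 62, 68, 74)
  healthy <- rep(c(TRUE, FALSE), each = 4)
  vals <- 30 - 0.2 * ages
  line <- fit_age_line(vals, ages, healthy)
  expect_equal(line$slope, -0.2, tolerance = 1e-12)
  expect_equal(line$intercept, 30, tolerance = 1e-10)

  withr::with_seed(17, {
    noisy <- 30 - 0.2 * ages + rnorm(8)
  })
  line2 <- fit_age_line(noisy, ages, healthy)
  res <- age_adjust(noisy, ages, line2)
  expect_lt(abs(mean(res[healthy])), 1e-10)      # LS residuals sum to zero

  # a pure AD level shift -delta is recovered in the mean residual
  shifted <- vals - ifelse(healthy, 0, 5)
  line3 <- fit_age_line(shifted, ages, healthy)
  expect_equal(mean(age_adjust(shifted, ages, line3)[!healthy]), -5,
               tolerance = 1e-10)

  # affine invariance: adding c*age + d and refitting leaves residuals unchanged
  tilted <- noisy + 0.7 * ages + 3
  line4 <- fit_age_line(tilted, ages, healthy)
  expect_equal(age_adjust(tilted, ages, line4), res, tolerance = 1e-10)

  expect_error(fit_age_line(vals[1:4], ages[1:4], c(TRUE, TRUE, FALSE, FALSE)),
               "3 healthy")
  expect_error(fit_age_line(vals, rep(70, 8), healthy), "variance")
})

test_that("generator age slope is recovered by the fitted line sign", {
  signs <- vapply(1:20, function(s) {
    co <- h_small_cohort(seed = s)$cohort
    line <- fit_age_line(co$upsit_total, co$age, co$group == "healthy")
    line$slope < 0
  }, logical(1))
  expect_gte(mean(signs), 0.8)
})

test_that("Pearson correlation handles exact, null and symmetric cases", {
  x <- 1:20
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  withr::with_seed(23, {
    nulls <- vapply(1:40, function(i) abs(pearson_cor(rnorm(1000), rnorm(1000))$r),
                    numeric(1))
  })
  expect_gte(mean(nulls < 0.1), 0.9)
  withr::with_seed(24, {
    u <- rnorm(30); v <- rnorm(30)
  })
  expect_equal(pearson_cor(u, v)$r, pearson_cor(v, u)$r)
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
})
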