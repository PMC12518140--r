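test_that("washout_activity evaluates the product model", {
  m11 <- pure_c11()
  p <- bio_washout_params(1000, Ws = 0.6, ks = 1e-3, kf = 1e-2)
  expect_equal(washout_activity(p, m11, 0), 1000)
  # frozen from independent 30-digit evaluation
  expect_equal(washout_activity(p, m11, 600), 234.899053028474,
               tolerance = 1e-13)
  # single-component reduction
  p1 <- bio_washout_params(1000, ks = 2e-3, n_components = 1)
  t <- c(0, 50, 500)
  expect_equal(washout_activity(p1, m11, t),
               1000 * fraction_remaining(m11, t) * exp(-2e-3 * t))
})

test_that("parameter container enforces its invariants", {
  expect_error(bio_washout_params(-1, 0.5, 1e-4, 1e-3), "A0")
  expect_error(bio_washout_params(1, 1.5, 1e-4, 1e-3), "Ws")
  expect_error(bio_washout_params(1, 0.5, 1e-2, 1e-3), "ks <= kf")
  p1 <- bio_washout_params(1, ks = 1e-3, n_components = 1)
  expect_equal(p1$Ws, 1)
})

test_that("noiseless round trips recover the generating parameters", {
  m <- c11_beam_mixture()
  truth <- bio_washout_params(5e4, Ws = 0.5, ks = 3e-4, kf = 5e-3)
  fit <- fit_washout(model_series(truth, m), m, 2)
  expect_true(fit$converged)
  expect_equal(fit$params$ks, truth$ks, tolerance = 1e-4)
  expect_equal(fit$params$kf, truth$kf, tolerance = 1e-4)
  expect_equal(fit$params$Ws, truth$Ws, tolerance = 1e-4)
  expect_equal(fit$params$A0, truth$A0, tolerance = 1e-4)
  expect_equal(fit$dof, 30 - 4)

  truth1 <- bio_washout_params(2e4, ks = 7e-4, n_components = 1)
  fit1 <- fit_washout(model_series(truth1, m), m, 1)
  expect_equal(fit1$params$ks, truth1$ks, tolerance = 1e-6)

  # pure physical decay: no biological washout left to estimate
  t <- seq(30, 1770, 60)
  phys <- time_activity_series(t, 3e4 * fraction_remaining(m, t))
  fit0 <- fit_washout(phys, m, 1)
  expect_lte(fit0$params$ks, 1e-6)
})

test_that("fit rejects inadequate input and never worsens with the richer model", {
  m <- c11_beam_mixture()
  t7 <- seq(30, 430, length.out = 7)
  expect_error(fit_washout(time_activity_series(t7, rep(10, 7)), m, 1),
               "at least 8")
  t11 <- seq(30, 1000, length.out = 11)
  expect_error(fit_washout(time_activity_series(t11, rep(10, 11)), m, 2),
               "at least 12")
  zero <- time_activity_series(seq(30, 1770, 60), rep(0, 30))
  expect_error(fit_washout(zero, m, 1), "all-zero")

  set.seed(71)
  for (i in 1:5) {
    p <- bio_washout_params(3e4, Ws = runif(1, 0.3, 0.9),
                            ks = 10^runif(1, -4, -3.2),
                            kf = 10^runif(1, -2.8, -2))
    s <- poisson_series(p, m)
    f1 <- fit_washout(s, m, 1); f2 <- fit_washout(s, m, 2)
    expect_lte(f2$chi2, f1$chi2 + 1e-9)
    expect_lte(f2$params$ks, f2$params$kf)  # labels always sorted
  }
})

test_that("nested F matches brute-force arithmetic and the chi-square ratio is reported", {
  mk <- function(chi2, n_free, n_points) {
    structure(list(params = bio_washout_params(1, if (n_free == 2) 1 else 0.5,
                                               1e-4, 1e-3,
                                               n_components = if (n_free == 2) 1L else 2L),
                   chi2 = chi2, dof = n_points - n_free, n_free = n_free,
                   param_se = NULL, converged = TRUE, n_points = n_points),
              class = "washout_fit")
  }
  sel <- f_test(mk(200, 2, 104), mk(100, 4, 104))
  expect_equal(sel$F, 50)                   # ((200-100)/2)/(100/100)
  expect_equal(sel$p_value, stats::pf(50, 2, 100, lower.tail = FALSE))
  expect_lt(sel$p_value, 1e-14)
  expect_equal(sel$chi2_ratio, 2)
  expect_equal(sel$chosen, "double")

  same <- f_test(mk(100, 2, 104), mk(100, 4, 104))
  expect_equal(same$F, 0)
  expect_equal(same$chosen, "single")

  # brute-force equivalence on random instances
  set.seed(5)
  for (i in 1:20) {
    c2 <- runif(1, 10, 100); c1 <- c2 + runif(1, 0, 50)
    n <- sample(20:200, 1)
    sel <- f_test(mk(c1, 2, n), mk(c2, 4, n))
    expect_equal(sel$F, ((c1 - c2) / 2) / (c2 / (n - 4)))
  }
})

test_that("F-test decision is valid (type-I error at or below nominal) and detects a real fast component", {
  m <- c11_beam_mixture()
  set.seed(202)
  p1 <- bio_washout_params(5e4, ks = 3e-4, n_components = 1)
  hits <- replicate(120, {
    s <- poisson_series(p1, m)
    f_test(fit_washout(s, m, 1), fit_washout(s, m, 2))$chosen == "double"
  })
  expect_lte(mean(hits), 0.07)  # boundary null makes the test conservative

  p2 <- bio_washout_params(5e4, Ws = 0.5, ks = 3e-4, kf = 5e-3)
  power_hits <- replicate(20, {
    s <- poisson_series(p2, m)
    f_test(fit_washout(s, m, 1), fit_washout(s, m, 2))$chosen == "double"
  })
  expect_gte(mean(power_hits), 0.9)
})

test_that("near-degenerate truth leaves the extra component unsupported in both conventions", {
  m <- c11_beam_mixture()
  set.seed(11)
  p <- bio_washout_params(5e4, Ws = 0.995, ks = 3e-4, kf = 4e-4)
  s <- poisson_series(p, m)
  sel <- f_test(fit_washout(s, m, 1), fit_washout(s, m, 2))
  expect_lt(sel$F, 10)
  expect_lt(sel$chi2_ratio, 1.5)
})

test_that("outlier mask implements the median +/- 1.5 IQR rule", {
  expect_equal(detect_outliers(c(1, 2, 3, 4, 5)), rep(TRUE, 5))
  # median 3, Q1 2, Q3 4, bounds [0, 6] -> 100 excluded
  expect_equal(detect_outliers(c(1, 2, 3, 4, 100)),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_warning(mask <- detect_outliers(rep(7, 6)), "IQR")
  expect_equal(mask, rep(TRUE, 6))
  expect_error(detect_outliers(1:3), "at least 4")
})

test_that("group comparison reproduces the pooled-variance t-test", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # hand-computed pooled t for {1,2,3} vs {4,5,6}
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.67423461417477, tolerance = 1e-12)
  expect_equal(res$p_value, 0.0213116411287567, tolerance = 1e-10)
  # degenerate: zero variance, unequal means
  deg <- compare_groups(c(2, 2), c(5, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)
})

test_that("group separation power at realistic effect size", {
  # two cohorts whose true kf differ by >= 2 SD of the fitted estimates
  m <- c11_beam_mixture()
  set.seed(909)
  detect <- replicate(20, {
    kf_a <- replicate(8, fit_washout(poisson_series(
      bio_washout_params(5e4, 0.5, 3e-4, 4e-3), m), m, 2)$params$kf)
    kf_b <- replicate(8, fit_washout(poisson_series(
      bio_washout_params(5e4, 0.5, 3e-4, 8e-3), m), m, 2)$params$kf)
    compare_groups(kf_a, kf_b)$p_value < 0.05
  })
  expect_gte(mean(detect), 0.9)
})
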