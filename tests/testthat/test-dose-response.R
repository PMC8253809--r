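test_that("replicate pooling concatenates without averaging, order-free", {
  r1 <- data.frame(concentration_M = c(1e-6, 1e-7),
                   activity_pct = c(80, 20))
  expect_equal(nrow(pool_replicates(r1)), 2)
  expect_equal(pool_replicates(r1)$activity_pct, c(20, 80))

  conc <- build_dilution_series(35e-6, 10, 3)$concentrations
  reps <- lapply(1:3, function(i) {
    data.frame(concentration_M = conc, activity_pct = stats::rnorm(10, 50, 10))
  })
  pooled <- pool_replicates(reps)
  expect_equal(nrow(pooled), 30)
  shuffled <- pool_replicates(reps[c(3, 1, 2)])
  expect_identical(pooled, shuffled)
  expect_error(pool_replicates(list()), "no replicate")
})

test_that("concentration medians use the midpoint convention", {
  m <- concentration_medians(rep(1e-6, 3), c(0, 50, 100))
  expect_equal(m$median, 50)
  m2 <- concentration_medians(rep(1e-6, 2), c(10, 20))
  expect_equal(m2$median, 15)
  m3 <- concentration_medians(c(1e-6, 1e-7), c(30, 70))
  expect_equal(m3$median, c(70, 30)) # ascending concentration order
  expect_equal(m3$min_median, 30)
  expect_equal(m3$max_median, 70)
})

test_that("AICc follows the Gaussian least-squares form", {
  expect_equal(aicc(30, 3, 30), 30 * log(1) + 6 + 24 / 26, tolerance = 1e-12)
  expect_lt(aicc(30, 3, 30), aicc(30, 4, 30)) # penalty monotone in k
  expect_error(aicc(5, 4, 10), "n > k")
  expect_error(aicc(10, 3, 0), "positive")
})

test_that("noiseless exact-model data are recovered to 0.1%", {
  conc <- build_dilution_series(3.5e-4, 10, 3)$concentrations
  act <- sigmoid_curve(conc, 0, 100, -1, 1e-7)
  fit <- fit_sigmoid(conc, act, "three_param")
  expect_true(fit$converged)
  expect_lt(abs(fit$yFin - 100) / 100, 1e-3)
  expect_lt(abs(fit$hill - (-1)), 1e-3 * 10)
  expect_lt(abs(fit$ec50 - 1e-7) / 1e-7, 1e-3)
  expect_equal(ec50_from_fit(fit), fit$ec50)
})

test_that("constrained optimizer attains the grid-search optimum", {
  set.seed(41)
  conc <- build_dilution_series(35e-6, 8, 3)$concentrations
  for (i in 1:10) {
    truth <- list(yFin = stats::runif(1, 40, 100),
                  hill = stats::runif(1, -4, -0.8),
                  ec50 = 10^stats::runif(1, -7.5, -5.5))
    act <- sigmoid_curve(conc, 0, truth$yFin, truth$hill, truth$ec50)
    med <- concentration_medians(conc, act)
    fit <- fit_sigmoid(conc, act, "three_param", med)
    grid_rss <- oracle_grid_rss3(conc, act, med$max_median)
    expect_lte(fit$rss, grid_rss + 1e-9)
  }
})

test_that("a null-response dataset yields a near-zero AUC", {
  conc <- build_dilution_series(35e-6, 10, 3)$concentrations
  cs <- fit_dose_response(rep(conc, 3), rep(0, 30))
  expect_lte(cs$auc, 0.01 * 700)
})

test_that("model selection prefers the lowest AICc with honest fallbacks", {
  mk <- function(aicc, k, conv = TRUE) {
    structure(list(model = if (k == 3) "three_param" else "four_param",
                   aicc = aicc, k = k, converged = conv, rss = 1),
              class = "sigmoid_fit")
  }
  expect_equal(select_model(mk(10, 3), mk(12, 4))$model, "three_param")
  expect_equal(select_model(mk(12, 3), mk(10, 4))$model, "four_param")
  # exact tie goes to the simpler model
  expect_equal(select_model(mk(10, 3), mk(10, 4))$model, "three_param")
  expect_equal(select_model(mk(10, 3), mk(5, 4, conv = FALSE))$model,
               "three_param")
  expect_null(select_model(mk(10, 3, conv = FALSE), mk(10, 4, conv = FALSE)))
})

test_that("a true nonzero baseline steers AICc toward the 4-parameter model", {
  # 20 simulated triplicate curves with y0 = 20% at 5% CV noise
  truth <- sample_screen_truth(20, 1, seed = 77, ec50_log10_range = c(-8, -6),
                               hill_range = c(-4, -1),
                               yfin_range = c(60, 110),
                               baseline_fraction = 1)
  scr <- simulate_screen(20, 1, seed = 77, cv = 0.05, truth = truth)
  np <- normalize_plates(scr$reads, scr$layout)
  fits <- fit_screen(np$activities)
  expect_gte(sum(fits$model == "four_param", na.rm = TRUE), 19)
})

test_that("spline fallback engages on non-sigmoidal data and keeps lines", {
  conc <- build_dilution_series(35e-6, 10, 3)$concentrations
  u <- log10(conc)
  bell <- 100 * exp(-(u + 7)^2 / 0.5)
  cs <- fit_dose_response(conc, bell)
  expect_equal(cs$fit_kind, "spline")
  expect_true(is.finite(cs$auc))
  expect_true(is.na(cs$ec50))

  # exactly linear data in log10 space: the smoothing spline reproduces the
  # line, and the AUC is the trapezoid of line plus flat extensions
  u6 <- seq(-9, -6, length.out = 6)
  act <- 5 + 10 * (u6 + 9)
  sp <- fit_spline_fallback(10^u6, act)
  expect_equal(predict_curve(sp, 10^u6), act, tolerance = 1e-6)
  analytic <- 5 * 2 + (5 + 35) / 2 * 3 + 35 * 2
  expect_equal(compute_auc(sp), analytic, tolerance = 1e-4)

  expect_error(fit_spline_fallback(c(1e-6, 1e-7, 1e-8), c(1, 2, 3)),
               ">= 4 distinct")
})

test_that("trapezoid AUC matches the closed-form logistic integral", {
  f0 <- structure(list(y0 = 0, yFin = 0, hill = -1, ec50 = 1e-7,
                       converged = TRUE), class = "sigmoid_fit")
  expect_equal(compute_auc(f0), 0)
  f100 <- structure(list(y0 = 100, yFin = 100, hill = -1, ec50 = 1e-7,
                         converged = TRUE), class = "sigmoid_fit")
  expect_equal(compute_auc(f100), 700, tolerance = 1e-9)

  fex <- structure(list(y0 = 0, yFin = 100, hill = -2, ec50 = 10^-7.5,
                        converged = TRUE), class = "sigmoid_fit")
  expect_equal(compute_auc(fex),
               oracle_logistic_auc(0, 100, -2, 10^-7.5),
               tolerance = 1e-3)
  expect_error(compute_auc(fex, lo = 1e-4, hi = 1e-11), "lo < hi")

  # grid refinement does not move the AUC by more than 0.01%
  expect_equal(compute_auc(fex, n_grid = 7001) / compute_auc(fex), 1,
               tolerance = 1e-4)
})

test_that("accepted sigmoid curves are monotone non-decreasing in dose", {
  set.seed(13)
  grid <- 10^seq(-11, -4, length.out = 300)
  for (i in 1:10) {
    truth <- sample_screen_truth(1, 1, ec50_log10_range = c(-8, -6))
    conc <- rep(build_dilution_series(35e-6, 10, 3)$concentrations, 3)
    act <- sigmoid_curve(conc, truth$y0, truth$yFin, truth$hill, truth$ec50) +
      stats::rnorm(30, 0, 3)
    cs <- fit_dose_response(conc, act)
    if (cs$fit_kind == "sigmoid") {
      y <- predict_curve(cs$fit, grid)
      expect_true(all(diff(y) >= -1e-9))
    }
  }
})

test_that("fit results do not depend on replicate order", {
  truth <- sample_screen_truth(1, 1, seed = 3, ec50_log10_range = c(-8, -6))
  conc <- build_dilution_series(35e-6, 10, 3)$concentrations
  set.seed(4)
  reps <- lapply(1:3, function(i) {
    data.frame(concentration_M = conc,
               activity_pct = sigmoid_curve(conc, truth$y0, truth$yFin,
                                            truth$hill, truth$ec50) +
                 stats::rnorm(10, 0, 3))
  })
  p1 <- pool_replicates(reps)
  p2 <- pool_replicates(reps[c(2, 3, 1)])
  f1 <- fit_dose_response(p1$concentration_M, p1$activity_pct)
  f2 <- fit_dose_response(p2$concentration_M, p2$activity_pct)
  expect_identical(f1$ec50, f2$ec50)
  expect_identical(f1$auc, f2$auc)
})
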