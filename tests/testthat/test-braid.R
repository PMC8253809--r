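test_that("the surface evaluates the stated combined-dose form", {
  p <- braid_params(0, 100, 1e-7, 1e-7, 1, 1, 0)
  # D_A = D_B = 1 at the midpoints, D = 2, effect = 100 * 2/3
  expect_equal(braid_effect(p, 1e-7, 1e-7), 200 / 3, tolerance = 1e-12)
  expect_equal(braid_effect(p, 0, 0), 0)
  expect_error(braid_params(0, 100, 1e-7, 1e-7, 1, 1, -2), "kappa")
  expect_error(braid_params(50, 10, 1e-7, 1e-7, 1, 1, 0), "exceed")
})

test_that("zero-dose edges reduce to the single-agent Hill curves", {
  set.seed(71)
  d <- 10^seq(-10, -5, length.out = 40)
  for (i in 1:20) {
    p <- rand_params()
    hill_a <- p$E0 + (p$Ef - p$E0) * d^p$n_a / (d^p$n_a + p$ec50_a^p$n_a)
    hill_b <- p$E0 + (p$Ef - p$E0) * d^p$n_b / (d^p$n_b + p$ec50_b^p$n_b)
    expect_equal(braid_effect(p, d, 0), hill_a, tolerance = 1e-12)
    expect_equal(braid_effect(p, 0, d), hill_b, tolerance = 1e-12)
  }
})

test_that("kappa = 0 with equal slopes gives the straight Loewe isobole", {
  p <- braid_params(0, 100, 2e-8, 8e-8, 2, 2, 0)
  iso <- isobole(p, 50, n_points = 201)
  # endpoints are the single-agent iso-effective doses (here the EC50s)
  expect_equal(iso$dose_a_M[nrow(iso)], 2e-8, tolerance = 1e-9)
  expect_equal(iso$dose_b_M[1], 8e-8, tolerance = 1e-9)
  # dose_a/dA* + dose_b/dB* = 1 along the whole contour
  dev <- iso$dose_a_M / 2e-8 + iso$dose_b_M / 8e-8 - 1
  expect_lt(max(abs(dev)), 1e-6)
})

test_that("isoboles are symmetric, on-level, and empty when unattainable", {
  p <- braid_params(0, 100, 5e-8, 5e-8, 1.5, 1.5, 2)
  iso <- isobole(p, 70, n_points = 101)
  # symmetric parameters: swapping the doses of any contour point stays on
  # the contour, and the endpoints mirror each other
  swapped <- braid_effect(p, iso$dose_b_M, iso$dose_a_M)
  expect_equal(swapped, rep(70, nrow(iso)), tolerance = 1e-6)
  expect_equal(iso$dose_a_M[nrow(iso)], iso$dose_b_M[1], tolerance = 1e-9)

  eff <- braid_effect(p, iso$dose_a_M, iso$dose_b_M)
  expect_equal(eff, rep(70, nrow(iso)), tolerance = 70 * 1e-3)
  # the trade-off is monotone: more A needs no more B
  expect_true(all(diff(iso$dose_b_M) <= 1e-15))

  expect_equal(nrow(isobole(p, 120)), 0)
})

test_that("noiseless surfaces are recovered, including kappa", {
  doses <- 1e-9 * 3^(0:7)
  for (k in c(-1, 0, 1, 3)) {
    truth <- braid_params(0, 100, 2e-8, 5e-8, 1.5, 0.8, k)
    g <- simulate_combination_grid(truth, doses, doses, noise_sd = 0,
                                   seed = 100 + k)
    fit <- fit_braid(g)
    expect_true(fit$converged)
    expect_lt(abs(fit$params$kappa - k), 0.05)
    expect_lt(abs(fit$params$ec50_a - 2e-8) / 2e-8, 0.01)
    expect_lt(abs(fit$params$ec50_b - 5e-8) / 5e-8, 0.01)
    expect_lt(abs(fit$params$n_a - 1.5) / 1.5, 0.01)
    expect_lt(abs(fit$params$Ef - 100) / 100, 0.01)
  }
})

test_that("surface edge parameters agree with an independent edge fit", {
  truth <- braid_params(0, 100, 3e-8, 6e-8, 2, 1.2, 1)
  doses <- 1e-9 * 3^(0:7)
  g <- simulate_combination_grid(truth, doses, doses, noise_sd = 0, seed = 1)
  fit <- fit_braid(g)
  edge <- g[g$dose_b_M == 0 & g$dose_a_M > 0, ]
  single <- fit_sigmoid(edge$dose_a_M, edge$activity_pct, "four_param")
  expect_lt(abs(fit$params$ec50_a - single$ec50) / single$ec50, 0.01)
  expect_lt(abs(fit$params$n_a - (-single$hill)) / (-single$hill), 0.01)
})

test_that("interaction classification follows the sign of kappa", {
  mk <- function(k) {
    structure(list(params = braid_params(0, 100, 1e-7, 1e-7, 1, 1, k),
                   converged = TRUE), class = "braid_fit")
  }
  expect_equal(classify_interaction(mk(2)), "synergistic")
  expect_equal(classify_interaction(mk(0)), "additive")
  expect_equal(classify_interaction(mk(-0.5)), "antagonistic")
  expect_equal(classify_interaction(mk(0.05)), "additive") # inside tol
  bad <- structure(list(converged = FALSE), class = "braid_fit")
  expect_error(classify_interaction(bad), "non-converged")
})

test_that("kappa sign is classified correctly under 3% noise", {
  doses <- 1e-9 * 3^(0:7)
  ok <- 0
  for (i in 1:20) {
    k <- if (i %% 2 == 0) 2 else -1.5
    truth <- braid_params(0, 100, 2e-8, 5e-8, 1.5, 0.8, k)
    g <- simulate_combination_grid(truth, doses, doses, noise_sd = 3,
                                   seed = 500 + i)
    fit <- fit_braid(g)
    cls <- classify_interaction(fit)
    if ((k > 0 && cls == "synergistic") ||
        (k < 0 && cls == "antagonistic")) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("IAE honors its boundary, monotonicity and counting contracts", {
  # a surface that never reaches the threshold inside the window scores 1
  weak <- braid_params(0, 40, 1e-7, 1e-7, 1, 1, 0)
  r <- compute_iae(weak, threshold = 50, cmax = 1e-6)
  expect_identical(r$iae, 1)
  expect_identical(r$achieving_fraction, 0)

  # monotone in Ef, all else fixed
  iaes <- sapply(c(60, 80, 100, 140), function(ef) {
    compute_iae(braid_params(0, ef, 1e-7, 1e-7, 1, 1, 0))$iae
  })
  expect_true(all(diff(iaes) >= 0))

  # independent count oracle: drug B inert, achieving region = columns with
  # dose_a above the midpoint; near half the window, IAE near sqrt(2)
  p <- braid_params(0, 100, 10^-8.01, 1, 1, 1, 0)
  r2 <- compute_iae(p, threshold = 50, cmax = 1e-6)
  u <- 10^seq(log10(1e-10), log10(1e-6), length.out = 201)
  count <- sum(outer(u, u, function(a, b) braid_effect(p, a, b)) >= 50)
  expect_equal(r2$achieving_fraction, count / 201^2, tolerance = 1e-12)
  expect_equal(r2$iae, sqrt(1 / (1 - count / 201^2)), tolerance = 1e-12)
  expect_equal(r2$iae, sqrt(2), tolerance = 0.01)

  # relabeling A <-> B with swapped parameters leaves the IAE unchanged
  set.seed(91)
  for (i in 1:5) {
    pp <- rand_params()
    qq <- braid_params(pp$E0, pp$Ef, pp$ec50_b, pp$ec50_a,
                       pp$n_b, pp$n_a, pp$kappa)
    expect_equal(compute_iae(pp)$iae, compute_iae(qq)$iae, tolerance = 1e-12)
  }
})

test_that("analyze_synergy assembles fit, class, IAE and isoboles", {
  truth <- braid_params(0, 100, 5e-8, 5e-8, 1.5, 1.5, 3)
  doses <- 1e-9 * 3^(0:7)
  g <- simulate_combination_grid(truth, doses, doses, noise_sd = 1, seed = 8)
  res <- analyze_synergy(g)
  expect_equal(res$interaction, "synergistic")
  expect_gt(res$iae$iae, 1)
  expect_named(res$isoboles, c("level_50", "level_90"))
  expect_gt(nrow(res$isoboles$level_50), 0)
})
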