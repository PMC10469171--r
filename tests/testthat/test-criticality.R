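test_that("beta regression is exact on noiseless power-law data", {
  bf <- fit_beta(c(1, 4, 9, 16), c(1, 2, 3, 4))
  expect_equal(bf$beta_fit, 2, tolerance = 1e-12)
  expect_equal(bf$n_points, 4L)
  # multiplying sizes by a constant shifts the intercept, not the slope
  bf2 <- fit_beta(10 * c(1, 4, 9, 16), c(1, 2, 3, 4))
  expect_equal(bf2$beta_fit, bf$beta_fit, tolerance = 1e-12)
  expect_equal(bf2$intercept, bf$intercept + log(10), tolerance = 1e-12)

  expect_error(fit_beta(c(1, 2, 3), c(2, 2, 2)), "insufficient")
  expect_error(fit_beta(1:3, 1:2), "paired")
})

test_that("DCC follows the exponent relation arithmetic", {
  d <- dcc(alpha = 3, tau = 2, beta_fit = 1.7)
  expect_equal(as.numeric(d), 0.3)
  expect_equal(attr(d, "beta_pred"), 2)
  expect_equal(as.numeric(dcc(3, 2, 2)), 0)
  # symmetric in the two betas by construction
  expect_equal(as.numeric(dcc(3, 2, 2.4)), as.numeric(abs(2 - 2.4)))
  expect_error(dcc(3, 1, 2), "tau = 1")
})

test_that("branching slopes are exact for noiseless exponential decay", {
  pop <- 1000 * 0.5^(0:20)
  br <- branching_ratio(pop, k_max = 5)
  expect_equal(br$r_k, 0.5^(1:5), tolerance = 1e-10)
  expect_equal(br$m, 0.5, tolerance = 1e-4)
  expect_equal(br$b, 1, tolerance = 1e-4)
})

test_that("r_1 equals the conventional single-lag regression slope", {
  set.seed(8)
  pop <- rpois(500, 6)
  br <- branching_ratio(pop, k_max = 4)
  conv <- unname(coef(lm(pop[-1] ~ pop[-length(pop)]))[2])
  expect_equal(br$r_k[1], conv, tolerance = 1e-10)
})

test_that("multistep estimator is unbiased under subsampling", {
  # same underlying process observed fully and at 10%: estimates agree
  est <- sapply(1:4, function(sd) {
    s <- simulate_branching(m = 0.9, h = 5, mu = 0.1, T = 3e4, seed = sd)
    c(branching_ratio(s$full)$m, branching_ratio(s$observed)$m)
  })
  expect_equal(mean(est[1, ]), mean(est[2, ]), tolerance = 0.02)
  expect_equal(mean(est[2, ]), 0.9, tolerance = 0.02)

  expect_error(branching_ratio(rep(3, 100)), "zero variance")
  expect_error(branching_ratio(1:15, k_max = 10), "bins")
})

test_that("shape collapse recovers the scaling exponent of exact profiles", {
  profs <- make_collapse_profiles(gamma = 1)
  sc <- shape_collapse(profs, beta_pred = 1.6)
  expect_equal(sc$beta_collapse, 2, tolerance = 0.011)
  expect_lt(sc$collapse_quality, 1e-6)
  expect_equal(sc$sc_error, abs(2 - 1.6), tolerance = 0.011)
  expect_equal(sc$gamma, sc$beta_collapse - 1)

  # scale invariance: common positive factor leaves the error curve alone
  sc2 <- shape_collapse(lapply(profs, `*`, 13), beta_pred = 1.6)
  expect_equal(sc2$error, sc$error, tolerance = 1e-9)

  # random profiles collapse at least 10x worse
  set.seed(12)
  noise <- lapply(rep(4:20, each = 4), function(D) runif(D))
  scn <- shape_collapse(noise, beta_pred = 2)
  expect_gt(scn$collapse_quality, 10 * max(sc$collapse_quality, 1e-8))

  expect_error(shape_collapse(profs[1:4], beta_pred = 2), "insufficient")
})

test_that("metric pipeline assembles a coherent session record", {
  s <- quick_critical_session(seed = 2, T = 1e4)
  m <- suppressWarnings(criticality_metrics(s$full))
  expect_s3_class(m, "criticality_metrics")
  expect_equal(m$dcc, abs(m$beta_pred - m$beta_fit), tolerance = 1e-12)
  expect_equal(m$beta_pred, (m$alpha - 1) / (m$tau - 1), tolerance = 1e-12)
  expect_equal(m$sc_error, abs(m$beta_collapse - m$beta_pred),
               tolerance = 1e-12)
  expect_gt(m$br, 0.9)
  df <- as.data.frame(m)
  expect_equal(nrow(df), 1L)
  expect_true(all(c("tau", "alpha", "dcc", "br", "sc_error") %in% names(df)))
})

test_that("branching ratio is untouched by the detection threshold", {
  s <- simulate_branching(m = 0.9, h = 0.5, T = 1e4, seed = 3)
  sweep <- suppressWarnings(threshold_sweep(s$full))
  expect_equal(nrow(sweep), 5L)
  expect_lt(diff(range(sweep$br)), 1e-12)
})
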