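test_that("inverse-method sampler matches the truncated discrete law", {
  x <- sample_powerlaw(1.5, 1, 100, 1e5, seed = 7)
  expect_true(all(x >= 1 & x <= 100))
  # empirical CDF within KS 0.01 of the directly normalised mass function
  pmf <- dpowerlaw(1:100, 1.5, 1, 100)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  emp <- cumsum(tabulate(x, 100)) / length(x)
  expect_lt(max(abs(emp - cumsum(pmf))), 0.01)
  # reproducible given a seed
  expect_identical(x, sample_powerlaw(1.5, 1, 100, 1e5, seed = 7))
  expect_error(sample_powerlaw(1, 1, 100, 10), "tau")
  expect_error(sample_powerlaw(2, 5, 5, 10), "x_min")
})

test_that("iterative MLE/KS fit recovers a known exponent", {
  x <- sample_powerlaw(1.5, 1, 100, 2e4, seed = 11)
  f <- fit_truncated_powerlaw(x)
  expect_true(f$converged)
  expect_equal(f$exponent, 1.5, tolerance = 0.05)
  expect_lt(f$ks, 1 / sqrt(f$n_events))
  expect_true(f$x_min %in% sort(unique(x))[1:3])

  expect_error(fit_truncated_powerlaw(rep(7L, 100)), "degenerate")
  expect_error(fit_truncated_powerlaw(c(1L, 2L, 3L)), "insufficient")
})

test_that("accepted fits always satisfy the KS acceptance rule", {
  for (tau in c(1.3, 2, 3)) {
    x <- sample_powerlaw(tau, 1, 200, 5000, seed = round(100 * tau))
    f <- fit_truncated_powerlaw(x)
    if (f$converged) expect_lt(f$ks, 1 / sqrt(f$n_events))
  }
})

test_that("MLE approaches the closed-form continuous estimator", {
  # wide untruncated-range data; continuous Hill estimator with the
  # standard half-integer offset
  x <- sample_powerlaw(2.5, 5, 5000, 2e4, seed = 21)
  tau_d <- critaval:::pl_mle(x, 5L, max(x))
  tau_c <- 1 + length(x) / sum(log(x / 4.5))
  expect_equal(tau_d, tau_c, tolerance = 0.1)
})

test_that("surrogate test keeps good fits and rejects a lognormal", {
  x <- sample_powerlaw(1.8, 1, 80, 5000, seed = 31)
  f <- fit_truncated_powerlaw(x)
  f <- surrogate_test(f, n_surrogates = 200, seed = 1)
  expect_gte(f$p_value, 0.05)

  # p-value is invariant to reordering the input values (fit depends on
  # the multiset only)
  f2 <- fit_truncated_powerlaw(sample(x))
  f2 <- surrogate_test(f2, n_surrogates = 200, seed = 1)
  expect_identical(f$p_value, f2$p_value)

  set.seed(5)
  ln <- pmax(1, round(rlnorm(1e4, 1, 2)))
  fl <- tryCatch(fit_truncated_powerlaw(ln), error = function(e) NULL)
  if (!is.null(fl) && fl$converged) {
    fl <- surrogate_test(fl, n_surrogates = 200, seed = 2)
    expect_lt(fl$p_value, 0.05)
  } else {
    succeed("no acceptable truncated power law: hypothesis rejected")
  }

  bad <- f
  bad$converged <- FALSE
  expect_error(surrogate_test(bad), "converged")
  expect_error(surrogate_test(f, n_surrogates = 50), ">= 100")
})
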