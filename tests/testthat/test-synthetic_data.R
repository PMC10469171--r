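test_that("branching simulator honours its conditional-mean contract", {
  expect_warning(z <- simulate_branching(0, 0, T = 100, seed = 1),
                 "identically zero")
  expect_true(all(z$full$population == 0))

  s <- simulate_branching(m = 0.9, h = 1, T = 2e4, seed = 2)
  expect_equal(mean(s$full$population), 10, tolerance = 0.15)
  # one-step conditional mean: regress N(t+1) on N(t)
  pop <- s$full$population
  co <- coef(lm(pop[-1] ~ pop[-length(pop)]))
  expect_equal(unname(co[2]), 0.9, tolerance = 0.03)
  expect_equal(unname(co[1]), 1, tolerance = 0.3)

  expect_error(simulate_branching(-1, 1), "non-negative")
  expect_error(simulate_branching(1, 1, mu = 0), "mu")
})

test_that("generators are bit-reproducible given a seed", {
  a <- simulate_branching(0.95, 2, mu = 0.3, T = 5000, seed = 42)
  b <- simulate_branching(0.95, 2, mu = 0.3, T = 5000, seed = 42)
  expect_identical(a$full$population, b$full$population)
  expect_identical(a$observed$population, b$observed$population)

  r1 <- simulate_session_set(n_per_condition = 2, T = 2000, seed = 9)
  r2 <- simulate_session_set(n_per_condition = 2, T = 2000, seed = 9)
  expect_identical(r1, r2)
})

test_that("observed activity is a mu-thinning of the full population", {
  s <- simulate_branching(m = 0.8, h = 4, mu = 0.25, T = 2e4, seed = 5)
  expect_true(all(s$observed$population <= s$full$population))
  expect_equal(mean(s$observed$population) / mean(s$full$population),
               0.25, tolerance = 0.02)
  expect_equal(s$config$mu_eff, 256 / 1024)
})

test_that("channel-resolved mode round-trips through the CSV raster", {
  s <- simulate_branching(m = 0.7, h = 2, n_units = 8, T = 200, seed = 6,
                          keep_counts = TRUE)
  expect_equal(unname(colSums(s$full$counts)), s$full$population)
  r <- as_spike_raster(s$full, seed = 7)
  p <- tempfile(fileext = ".csv")
  write_spike_table(r, p)
  b <- bin_spikes(load_spike_table(p, duration_s = r$duration_s), 50)
  expect_equal(sum(b$population), sum(s$full$population))
  expect_equal(unname(b$population), unname(s$full$population))
})

test_that("session sets plant the requested condition contrast", {
  recs <- simulate_session_set(n_per_condition = 4, T = 4000, seed = 31)
  expect_equal(nrow(recs), 8L)
  expect_setequal(unique(recs$condition), c("Gameplay", "Rest"))
  expect_true(all(c("dcc", "br", "sc_error", "hm_ratio", "m_true") %in%
                    names(recs)))
  # planted m contrast shows up in the true parameters and recovered BR
  expect_gt(mean(recs$m_true[recs$condition == "Gameplay"]),
            mean(recs$m_true[recs$condition == "Rest"]))
  expect_gt(mean(recs$br[recs$condition == "Gameplay"]),
            mean(recs$br[recs$condition == "Rest"]))

  r0 <- simulate_session_set(n_per_condition = 3, T = 4000,
                             effect_size = 0, seed = 32)
  expect_lt(abs(mean(r0$m_true[r0$condition == "Gameplay"]) -
                  mean(r0$m_true[r0$condition == "Rest"])), 0.1)
})
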