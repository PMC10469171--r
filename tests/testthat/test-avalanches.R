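test_that("threshold-crossing detection matches a manual scan", {
  b <- binned_activity(c(0, 3, 5, 4, 0, 2, 0), 50)
  # median 2, threshold 0.8; runs above: bins 2-4 and bin 6
  a <- detect_avalanches(b, 0.4)
  expect_equal(a$threshold_value, 0.8)
  expect_equal(a$n_avalanches, 2L)
  expect_equal(a$events$size, c(12, 2))
  expect_equal(a$events$d_bins, c(3L, 1L))
  expect_equal(a$events$start_bin, c(2L, 6L))
  expect_equal(a$events$end_bin, c(5L, 7L)) # half-open
  expect_equal(a$profiles[[1]], c(3, 5, 4))
  expect_false(any(a$events$censored))

  # robustness of this toy input across the paper's threshold range
  a3 <- detect_avalanches(b, 0.3)
  a7 <- detect_avalanches(b, 0.7)
  expect_equal(a3$events[, c("start_bin", "end_bin")],
               a$events[, c("start_bin", "end_bin")])
  expect_equal(a7$events[, c("start_bin", "end_bin")],
               a$events[, c("start_bin", "end_bin")])
})

test_that("degenerate populations are handled", {
  z <- binned_activity(rep(0, 10), 50)
  expect_warning(az <- detect_avalanches(z), "")
  expect_equal(az$n_avalanches, 0L)

  sparse <- binned_activity(c(0, 0, 0, 2, 3, 0, 1, 0), 50)
  # median 0: default continuation -> runs of non-zero activity
  expect_warning(as_ <- detect_avalanches(sparse), "runs of non-zero")
  expect_equal(as_$events$size, c(5, 1))
  # spec-contract alternative
  expect_warning(ae <- detect_avalanches(sparse, zero_median = "empty"),
                 "degenerate")
  expect_equal(ae$n_avalanches, 0L)

  expect_error(detect_avalanches(binned_activity(1:5, 50), 0), "0, 1")
  expect_error(detect_avalanches(binned_activity(1:5, 50), 1.2), "0, 1")
})

test_that("boundary avalanches are kept but flagged censored", {
  b <- binned_activity(c(5, 5, 0, 1, 0, 5), 50)
  a <- suppressWarnings(detect_avalanches(b, 0.4))
  expect_true(a$events$censored[1])
  expect_true(a$events$censored[nrow(a$events)])
})

test_that("detection is invariant to rescaling the population", {
  set.seed(3)
  pop <- rpois(500, 4)
  a1 <- detect_avalanches(binned_activity(pop, 50))
  a2 <- detect_avalanches(binned_activity(pop * 7, 50))
  expect_equal(a2$events[, c("start_bin", "end_bin")],
               a1$events[, c("start_bin", "end_bin")])
})

test_that("fixed-threshold detection commutes with concatenation", {
  set.seed(4)
  p1 <- c(rpois(200, 3), 0) # force sub-threshold seam
  p2 <- rpois(200, 3)
  thr <- 1.5
  a12 <- detect_avalanches(binned_activity(c(p1, p2), 50),
                           threshold_value = thr)
  a1 <- detect_avalanches(binned_activity(p1, 50), threshold_value = thr)
  a2 <- detect_avalanches(binned_activity(p2, 50), threshold_value = thr)
  expect_equal(a12$n_avalanches, a1$n_avalanches + a2$n_avalanches)
  expect_equal(a12$events$size, c(a1$events$size, a2$events$size))
})

test_that("summaries mirror the event table and total spikes bound", {
  e <- suppressWarnings(
    detect_avalanches(binned_activity(rep(0, 5), 50)))
  s0 <- avalanche_summaries(e)
  expect_length(s0$sizes, 0)
  expect_length(s0$durations, 0)

  b <- binned_activity(c(0, 3, 5, 4, 0, 2, 0), 50)
  a <- detect_avalanches(b, 0.4)
  s <- avalanche_summaries(a)
  expect_equal(s$sizes, c(12L, 2L))
  expect_equal(s$durations, c(3L, 1L))
  expect_lte(sum(s$sizes), sum(b$population))
})
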