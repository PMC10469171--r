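test_that("Alexander-Govern matches an independent reference", {
  g1 <- c(12.1, 14.3, 11.8, 13.5, 12.9, 15.0)
  g2 <- c(18.2, 16.9, 17.5, 19.1, 18.8)
  g3 <- c(12.0, 12.4, 13.1, 11.7, 12.8, 12.2, 13.0)
  # frozen oracle values (scipy.stats.alexandergovern)
  r2 <- alexander_govern(g1, g2)
  expect_equal(r2$statistic, 16.0896203603, tolerance = 1e-9)
  expect_equal(r2$p_value, 6.041425839e-05, tolerance = 1e-6)
  r3 <- alexander_govern(g1, g2, g3)
  expect_equal(r3$statistic, 22.7769500770, tolerance = 1e-9)
  expect_equal(r3$p_value, 1.132525876e-05, tolerance = 1e-6)
  expect_equal(r3$df, 2L)
  # list form gives the same answer
  expect_equal(alexander_govern(list(g1, g2))$statistic, r2$statistic)
})

test_that("identical group means give statistic 0 and p = 1", {
  g1 <- c(1, 2, 3) # mean 2
  g2 <- c(0, 2, 4) # mean 2
  r <- alexander_govern(g1, g2)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(alexander_govern(c(1, 1, 1), g2), "zero-variance")
  expect_error(alexander_govern(g1), "2 groups")
})

test_that("separated normal groups are detected decisively", {
  set.seed(99)
  r <- alexander_govern(rnorm(50), rnorm(50, 2))
  expect_lt(r$p_value, 0.001)
})

test_that("test level is near nominal and tracks Welch for 2 groups", {
  set.seed(123)
  reps <- 500
  p3 <- replicate(reps,
    alexander_govern(rnorm(20), rnorm(20), rnorm(20))$p_value)
  expect_gte(mean(p3 < 0.05), 0.02)
  expect_lte(mean(p3 < 0.05), 0.09)

  agree <- replicate(200, {
    a <- rnorm(30)
    b <- rnorm(35, mean = sample(c(0, 0.8), 1), sd = 1.5)
    (alexander_govern(a, b)$p_value < 0.05) ==
      (t.test(a, b)$p.value < 0.05)
  })
  expect_gte(mean(agree), 0.95)
})

test_that("correlation wrapper reproduces exact cases and errors", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_metric(x, x)$r, 1)
  expect_equal(correlate_metric(x, -x)$r, -1)
  expect_error(correlate_metric(x, rep(2, 5)), "constant")
  expect_error(correlate_metric(x[1:2], x[1:2]), "3 paired")
})

make_records <- function(n, signal = 0, seed = 1) {
  set.seed(seed)
  lab <- rep(c("Gameplay", "Rest"), each = n / 2)
  data.frame(condition = lab,
             dcc = rnorm(n) + signal * (lab == "Gameplay"),
             br = rnorm(n),
             sc_error = rnorm(n),
             hm_ratio = rnorm(n))
}

test_that("pure-noise features classify at chance", {
  recs <- make_records(200, signal = 0, seed = 2)
  acc <- classify_sessions(recs, "3-criticality", "logistic",
                           repeats = 3, seed = 3)$mean_accuracy
  expect_gte(acc, 0.40)
  expect_lte(acc, 0.60)
})

test_that("classifier uses exactly the schema's signal columns", {
  # signal lives in dcc only: with it accuracy is high, without it accuracy
  # collapses to chance — held-out folds carry no leaked information
  recs <- make_records(200, signal = 6, seed = 4)
  with_sig <- classify_sessions(recs, "dcc", "logistic",
                                repeats = 2, seed = 5)$mean_accuracy
  no_sig <- classify_sessions(recs, "br", "logistic",
                              repeats = 2, seed = 5)$mean_accuracy
  expect_gte(with_sig, 0.95)
  expect_lte(no_sig, 0.62)
})

test_that("classification guards its preconditions", {
  recs <- make_records(20, seed = 6)
  expect_error(classify_sessions(recs[recs$condition == "Rest", ]),
               "2 classes")
  expect_error(classify_sessions(recs[c(1:4, 11:14), ]), "at least 10")
  expect_error(classify_sessions(recs, schema = "nope"), "unknown schema")
})

test_that("accuracy matrix covers classifiers x schemas", {
  recs <- make_records(40, signal = 5, seed = 7)
  m <- classification_matrix(recs, schemas = c("3-criticality", "dcc"),
                             repeats = 1, seed = 8)
  expect_equal(rownames(m), c("logistic", "svm", "random_forest"))
  expect_equal(colnames(m), c("3-criticality", "dcc"))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("t-SNE embedding separates planted clusters and reports KL", {
  recs <- make_records(60, signal = 8, seed = 9)
  em <- embed_sessions(recs, "4-metrics", seed = 10)
  expect_equal(dim(em$coordinates), c(60L, 2L))
  expect_true(is.finite(em$kl_divergence) && em$kl_divergence >= 0)
  if (requireNamespace("cluster", quietly = TRUE)) {
    sil <- cluster::silhouette(as.integer(factor(recs$condition)),
                               dist(em$coordinates))
    expect_gt(mean(sil[, "sil_width"]), 0)
  }

  dup <- recs[rep(1:5, each = 3), ]
  expect_warning(em2 <- embed_sessions(dup, "4-metrics", seed = 11),
                 "jitter")
  expect_equal(nrow(em2$coordinates), 15L)
  expect_error(embed_sessions(recs[1:4, ], seed = 1), "at least 5")
})
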