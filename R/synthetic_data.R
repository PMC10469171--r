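#' Simulate a driven branching process with subsampling
#'
#' Population activity follows a driven Galton-Watson process: each spike at
#' time `t` spawns a Poisson(`m`) number of spikes at `t + 1`, plus a
#' Poisson(`h`) external drive, so the conditional mean is
#' `<N(t+1) | N(t)> = m N(t) + h`. Spikes are assigned uniformly to
#' `n_units` channels and a fixed subset of `round(mu * n_units)` channels
#' is observed, making the observed activity a binomial thinning of the full
#' population with `<n(t) | N(t)> = mu_eff N(t)` (the offset `xi` is 0 by
#' construction).
#'
#' For `m < 1` the chain starts at its stationary mean `h / (1 - m)`; at or
#' above 1 it starts at `h` (activity then grows linearly or exponentially
#' in expectation). The channels x bins count matrix is only materialised on
#' request: every estimator in the package operates on the population and
#' observed-population vectors.
#'
#' @param m Offspring mean (branching ratio) of the process, `>= 0`.
#' @param h External drive, mean immigrant spikes per bin, `>= 0`.
#' @param n_units Number of units (channels) spikes are spread over.
#' @param mu Observed fraction of units, in (0, 1].
#' @param T Number of time bins.
#' @param bin_width_ms Bin width in milliseconds (metadata; the process is
#'   defined per bin).
#' @param seed Optional integer seed.
#' @param keep_counts If `TRUE`, also materialise channel-resolved count
#'   matrices (only sensible for small `n_units * T`).
#' @param session_id Session identifier.
#' @return List with `full` and `observed`, both [binned_activity()]
#'   objects, plus `config` echoing the parameters.
#' @examples
#' s <- simulate_branching(m = 0.9, h = 1, T = 5000, seed = 1)
#' mean(s$full$population) # near h / (1 - m) = 10
#' @export
simulate_branching <- function(m, h, n_units = 1024, mu = 1, T = 10000,
                               bin_width_ms = 50, seed = NULL,
                               keep_counts = FALSE, session_id = "sim") {
  if (m < 0 || h < 0) stop("m and h must be non-negative")
  if (mu <= 0 || mu > 1) stop("mu must be in (0, 1]")
  if (T < 1) stop("T must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  N <- integer(T)
  N[1] <- stats::rpois(1, if (m < 1) h / (1 - m) else max(h, 1))
  if (m == 0 && h == 0 && N[1] == 0) {
    warning("m = 0, h = 0 and no seed activity: output is identically zero")
  }
  for (t in seq_len(T - 1L)) {
    N[t + 1L] <- stats::rpois(1, m * N[t] + h)
  }
  n_obs_units <- max(1L, round(mu * n_units))
  mu_eff <- n_obs_units / n_units
  n_obs <- if (mu_eff >= 1) N else stats::rbinom(T, N, mu_eff)
  counts_full <- counts_obs <- NULL
  if (keep_counts) {
    counts_full <- matrix(0L, nrow = n_units, ncol = T)
    for (t in seq_len(T)) {
      if (N[t] > 0) {
        tab <- tabulate(sample.int(n_units, N[t], replace = TRUE),
                        nbins = n_units)
        counts_full[, t] <- tab
      }
    }
    counts_obs <- counts_full[seq_len(n_obs_units), , drop = FALSE]
    n_obs <- colSums(counts_obs)
  }
  cfg <- list(m = m, h = h, n_units = n_units, mu = mu, mu_eff = mu_eff,
              T = T, bin_width_ms = bin_width_ms, seed = seed)
  list(
    full = binned_activity(N, bin_width_ms, counts = counts_full,
                           session_id = paste0(session_id, "_full")),
    observed = binned_activity(n_obs, bin_width_ms, counts = counts_obs,
                               session_id = paste0(session_id, "_obs")),
    config = cfg)
}

#' Convert channel-resolved binned activity to a spike raster
#'
#' Spike times are placed uniformly at random inside their bin; used to
#' produce CSV rasters for round-trip and pipeline tests.
#'
#' @param binned A [binned_activity()] with a counts matrix.
#' @param seed Optional seed for the within-bin placement.
#' @return A [spike_raster()].
#' @export
as_spike_raster <- function(binned, seed = NULL) {
  stopifnot(inherits(binned, "binned_activity"))
  if (is.null(binned$counts)) {
    stop("binned activity has no channel-resolved counts")
  }
  if (!is.null(seed)) set.seed(seed)
  delta <- binned$bin_width_ms / 1000
  spikes <- lapply(seq_len(nrow(binned$counts)), function(i) {
    cnt <- binned$counts[i, ]
    bins <- rep(seq_along(cnt) - 1L, cnt)
    sort(delta * (bins + stats::runif(length(bins))))
  })
  names(spikes) <- if (is.null(binned$channel_ids))
    seq_len(nrow(binned$counts)) - 1L else binned$channel_ids
  spike_raster(spikes, duration_s = binned$duration_s,
               session_id = binned$session_id)
}

#' Simulate a collection of sessions under two conditions
#'
#' Emulates a task-present ("Gameplay") vs task-absent ("Rest") study:
#' per-session branching parameters and hit/miss ratios are drawn from
#' condition-specific distributions and the full metric pipeline is run on
#' each simulated session. With `effect_size = 1` Gameplay-like sessions run
#' near-critical (`m ~ 0.99`) with high H/M ratios, Rest-like sessions
#' subcritical (`m ~ 0.85`) with lower H/M ratios; `effect_size = 0`
#' removes all condition differences (both conditions drawn from the Rest
#' distributions), giving chance-level classification by construction.
#'
#' @param n_per_condition Sessions per condition.
#' @param effect_size Scales the Gameplay-Rest separation of the planted
#'   parameter distributions (0 = none, 1 = study-like contrast).
#' @param T Bins per session.
#' @param rate Target stationary mean population (spikes per bin); the
#'   drive is set per session as `h = rate * (1 - m)` so conditions differ
#'   in dynamics, not firing rate (with a floor of 0.01 on `1 - m`).
#' @param bin_width_ms Bin width in milliseconds.
#' @param conditions Two condition labels.
#' @param seed Integer seed for the whole collection.
#' @param surrogates Passed to [criticality_metrics()].
#' @return data.frame of session records: `session_id`, `condition`,
#'   `hm_ratio`, `m_true`, and the metric columns of
#'   [as.data.frame.criticality_metrics()].
#' @export
simulate_session_set <- function(n_per_condition = 20, effect_size = 1,
                                 T = 10000, rate = 5, bin_width_ms = 50,
                                 conditions = c("Gameplay", "Rest"),
                                 seed = NULL, surrogates = 0) {
  if (length(conditions) < 2L) stop("need at least 2 conditions")
  if (!is.finite(effect_size)) stop("effect_size must be finite")
  if (!is.null(seed)) set.seed(seed)
  if (n_per_condition < 2L && effect_size == 0) {
    warning("degenerate configuration: single session per condition")
  }
  # Rest-like baselines; effect_size interpolates the Gameplay-like shifts.
  m_rest <- c(mean = 0.85, sd = 0.03)
  m_game <- c(mean = 0.99, sd = 0.004)
  hm_rest <- c(mean = 0.75, sd = 0.06)
  hm_game <- c(mean = 0.9, sd = 0.06)
  rows <- list()
  idx <- 0L
  for (ci in seq_along(conditions)) {
    gamey <- if (ci == 1L) effect_size else 0
    m_mu <- m_rest["mean"] + gamey * (m_game["mean"] - m_rest["mean"])
    m_sd <- m_rest["sd"] + gamey * (m_game["sd"] - m_rest["sd"])
    hm_mu <- hm_rest["mean"] + gamey * (hm_game["mean"] - hm_rest["mean"])
    for (s in seq_len(n_per_condition)) {
      idx <- idx + 1L
      m_i <- min(stats::rnorm(1, m_mu, m_sd), 0.999)
      hm_i <- max(stats::rnorm(1, hm_mu, hm_rest["sd"]), 0)
      h <- rate * max(1 - m_i, 0.01)
      sim <- simulate_branching(m = m_i, h = h, T = T,
                                bin_width_ms = bin_width_ms,
                                session_id = sprintf("s%03d", idx))
      met <- suppressWarnings(
        criticality_metrics(sim$full, surrogates = surrogates))
      row <- as.data.frame(met)
      row$condition <- conditions[ci]
      row$hm_ratio <- hm_i
      row$m_true <- m_i
      rows[[idx]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hand-labelled burst fixtures covering every classifier branch
#'
#' Deterministic burst-size and start-time lists with expected labels for
#' all outcomes of [classify_size_distribution()], [classify_burst_rate()]
#' and [classify_superbursts()]. Expected labels were derived by applying
#' the classification rules by hand (see each fixture's `derivation`).
#'
#' @return Named list of fixtures, each a list with `sizes` and/or `starts`,
#'   the `expected` label, the classifier it targets, and a one-line
#'   `derivation`.
#' @export
make_burst_fixtures <- function() {
  cluster_starts <- function(sizes_per_cluster, intra = 1, inter = 100) {
    t0 <- 0
    out <- numeric(0)
    for (k in sizes_per_cluster) {
      out <- c(out, t0 + intra * (seq_len(k) - 1))
      t0 <- out[length(out)] + inter
    }
    out
  }
  list(
    irregular_A = list(
      classifier = "size",
      sizes = c(120, 110, 100, 60, 55, 50, 45, 40, 20, 10),
      expected = "irregular",
      derivation = "N*=100; large {120,110,100}=3, medium {60..40}=5, small {20,10}=2; medium > large"),
    bimodal_A = list(
      classifier = "size",
      sizes = c(100, 100, 100, 50, rep(10, 10)),
      expected = "bimodal",
      derivation = "N*=100; large=3, medium={50}=1, small=10; small > large"),
    fixed_A = list(
      classifier = "size",
      sizes = c(100, 100, 100, 100, 100, 50, 10),
      expected = "fixed",
      derivation = "N*=100; large=5 > medium=1 and > small=1"),
    undetermined_tie = list(
      classifier = "size",
      sizes = c(100, 90, 80, 50, 45, 40, 10, 5, 3),
      expected = "undetermined",
      derivation = "N*=80; large=3, medium=3, small=3; all comparisons tie"),
    too_few = list(
      classifier = "size",
      sizes = c(10, 20),
      expected = "undetermined",
      derivation = "fewer than 3 bursts"),
    periodic = list(
      classifier = "rate",
      starts = 5 * (0:14),
      expected = "not_variable",
      derivation = "uniform 5 s intervals; max_rate = min_rate"),
    variable_A = list(
      classifier = "rate",
      starts = cumsum(c(0, rep(0.1, 10), rep(20, 3))),
      expected = "highly_variable",
      derivation = "10 IBIs in 1 s vs 3 IBIs in 60 s; rate ratio 200 >= 10"),
    rate_too_few = list(
      classifier = "rate",
      starts = 5 * (0:4),
      expected = "undetermined",
      derivation = "fewer than 11 bursts"),
    superburst_regular = list(
      classifier = "superburst",
      starts = cluster_starts(rep(8, 5)),
      sizes = rep(100, 40),
      expected = "regular",
      derivation = "5 clusters of 8, intra 1 s, inter 100 s; var 0 < mean/2 = 4"),
    superburst_short = list(
      classifier = "superburst",
      starts = cluster_starts(c(2, 3, 12, 4, 5)),
      sizes = rep(100, 26),
      expected = "short",
      derivation = "cluster sizes {2,3,12,4,5}: var 15.7 >= 2.6, mean 5.2 < 10"),
    superburst_long = list(
      classifier = "superburst",
      starts = cluster_starts(c(12, 13, 14, 11, 30)),
      sizes = rep(100, 80),
      expected = "long",
      derivation = "cluster sizes {12,13,14,11,30}: var 62.5 >= 8, mean 16 >= 10"),
    no_superbursts = list(
      classifier = "superburst",
      starts = 5 * (0:19),
      sizes = rep(100, 20),
      expected = "none",
      derivation = "uniform spacing: no gap reaches 10x the median interval"))
}
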