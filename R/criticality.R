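#' Fit the size-duration scaling exponent beta
#'
#' At criticality mean avalanche size scales with duration as
#' `<S> ~ D^beta`. Sizes are grouped by duration, the mean size per distinct
#' duration computed, and `log<S>` regressed on `log D` by ordinary least
#' squares.
#'
#' @param sizes,durations Paired integer vectors (one entry per avalanche).
#' @param d_range Optional `c(min, max)` duration window: only avalanches
#'   whose duration falls inside it enter the regression. The metric
#'   pipeline passes the accepted range of the duration power-law fit here,
#'   so that the exponent relation is evaluated over one common scaling
#'   window.
#' @return An object of class `beta_fit`: `beta_fit` (slope), `intercept`,
#'   `n_points` (distinct durations used).
#' @examples
#' fit_beta(c(1, 4, 9, 16), c(1, 2, 3, 4))$beta_fit # exactly 2
#' @export
fit_beta <- function(sizes, durations, d_range = NULL) {
  if (length(sizes) != length(durations)) {
    stop("sizes and durations must be paired")
  }
  if (!is.null(d_range)) {
    keep <- durations >= d_range[1] & durations <= d_range[2]
    sizes <- sizes[keep]
    durations <- durations[keep]
  }
  mean_s <- tapply(sizes, durations, mean)
  d <- as.numeric(names(mean_s))
  if (length(d) < 3L) {
    stop("insufficient data: need >= 3 distinct durations")
  }
  fit <- stats::lm.fit(cbind(1, log(d)), log(as.numeric(mean_s)))
  structure(list(beta_fit = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n_points = length(d)),
            class = "beta_fit")
}

#' Deviation from criticality coefficient (DCC)
#'
#' The crackling-noise exponent relation predicts
#' `beta_pred = (alpha - 1) / (tau - 1)` from the duration exponent `alpha`
#' and size exponent `tau`. The DCC is the absolute gap between this
#' prediction and the directly fitted `beta_fit`; it approaches 0 as the
#' system approaches criticality.
#'
#' @param alpha Duration-distribution exponent.
#' @param tau Size-distribution exponent (must not equal 1).
#' @param beta_fit Regression slope from [fit_beta()].
#' @return Non-negative `|beta_pred - beta_fit|`, with `beta_pred` attached
#'   as attribute `"beta_pred"`.
#' @examples
#' dcc(alpha = 3, tau = 2, beta_fit = 1.7) # beta_pred = 2, DCC = 0.3
#' @export
dcc <- function(alpha, tau, beta_fit) {
  if (tau == 1) stop("tau = 1: beta_pred is undefined")
  beta_pred <- (alpha - 1) / (tau - 1)
  structure(abs(beta_pred - beta_fit), beta_pred = beta_pred)
}

#' Subsampling-corrected branching ratio (multistep regression estimator)
#'
#' The branching ratio `m` is the expected number of spikes at `t + 1` per
#' spike at `t`; `m = 1` marks criticality. When only a fraction of units is
#' observed, the conventional lag-1 regression slope underestimates `m` by a
#' bias factor `b`, but all lag-`k` slopes are biased by the *same* factor,
#' `r_k = b * m^k`. The estimator therefore regresses activity at `t + k` on
#' activity at `t` for `k = 1..k_max` and fits the exponential `b * m^k`
#' through the slopes, which recovers `m` free of the subsampling bias
#' (`r_1` alone is the conventional, biased estimator).
#'
#' The exponential is fitted by least squares in the original scale
#' (initialised log-linearly from the positive slopes); fitting in log
#' scale would over-weight the near-zero, noise-dominated slopes at large
#' lags and biases the estimate upward for strongly subcritical activity.
#'
#' @param binned A [binned_activity()] (population activity is used), or a
#'   plain numeric activity vector.
#' @param k_max Largest regression lag (default 10).
#' @return An object of class `branching_fit`: `m`, `b`, `r_k` (length
#'   `k_max`), `k_max`.
#' @export
branching_ratio <- function(binned, k_max = 10) {
  pop <- if (inherits(binned, "binned_activity")) binned$population
         else as.numeric(binned)
  T_len <- length(pop)
  if (T_len < k_max + 10) stop("need at least k_max + 10 bins")
  if (stats::var(pop) == 0) {
    stop("population has zero variance: branching ratio is not estimable")
  }
  r_k <- vapply(seq_len(k_max), function(k) {
    x <- pop[1:(T_len - k)]
    y <- pop[(k + 1):T_len]
    stats::cov(x, y) / stats::var(x)
  }, numeric(1))
  pos <- which(r_k > 0)
  m0 <- if (length(pos) >= 2) {
    min(max(exp(stats::lm.fit(cbind(1, pos),
                              log(r_k[pos]))$coefficients[2]), 1e-3), 2)
  } else 0.5
  b0 <- if (length(pos)) max(r_k[pos[1]] / m0^pos[1], 1e-3) else 1
  obj <- function(p) sum((r_k - p[2] * p[1]^seq_len(k_max))^2)
  op <- stats::optim(c(m0, b0), obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 2000))
  m <- op$par[1]
  b <- op$par[2]
  if (m <= 0) warning("fitted branching ratio is non-positive")
  structure(list(m = m, b = b, r_k = r_k, k_max = k_max),
            class = "branching_fit")
}

#' @export
print.branching_fit <- function(x, ...) {
  cat(sprintf("branching_fit: m = %.4f (bias factor b = %.3f, k_max = %d)\n",
              x$m, x$b, x$k_max))
  invisible(x)
}

#' Avalanche shape collapse
#'
#' At criticality mean avalanche profiles of different durations are copies
#' of one universal scaling function: `s(t, D) ~ D^gamma F(t/D)` with
#' `gamma = beta - 1`. For each candidate `beta` on a grid, mean profiles
#' `<s(t, D)>` for each admissible duration are rescaled by `D^gamma`,
#' interpolated onto a common normalised-time grid, and the collapse error
#' `var(F) / (max(F) - min(F))^2` evaluated (variance across profiles at
#' each grid point, averaged over the grid; range over the whole stack). The
#' `beta` minimising the error is the collapse exponent; the shape-collapse
#' (SC) error is its absolute gap to `beta_pred`.
#'
#' @param avalanche_set An `avalanche_set`, or a plain list of numeric
#'   profiles with durations taken as their lengths.
#' @param beta_pred Predicted exponent `(alpha - 1)/(tau - 1)` used for the
#'   SC error; may be `NA` (then `sc_error` is `NA`).
#' @param d_min_bins,d_max_bins Duration window in bins (default 4-20; at a
#'   50 ms bin width this is 200-1000 ms, below which profiles are too short
#'   to rescale and above which counts are too sparse).
#' @param beta_grid `c(lo, hi, step)` candidate grid (default 1-3 by 0.01).
#' @param min_count Minimum number of avalanches a duration needs to
#'   contribute a mean profile (default 4).
#' @param n_grid Points of the common normalised-time grid (default 100).
#' @param method `"variance"` (default) uses the cross-profile variance at
#'   each normalised time; `"poly"` uses the variance of residuals around a
#'   degree-2 polynomial fit to the stacked collapse.
#' @return List with `beta_collapse`, `gamma` (`= beta_collapse - 1`),
#'   `collapse_quality` (minimum error), `sc_error`
#'   (`|beta_collapse - beta_pred|`), `n_durations`, and the error curve
#'   (`beta`, `error`).
#' @export
shape_collapse <- function(avalanche_set, beta_pred = NA,
                           d_min_bins = 4, d_max_bins = 20,
                           beta_grid = c(1, 3, 0.01), min_count = 4,
                           n_grid = 100, method = c("variance", "poly")) {
  method <- match.arg(method)
  if (inherits(avalanche_set, "avalanche_set")) {
    profiles <- avalanche_set$profiles
    durations <- avalanche_set$events$d_bins
  } else {
    profiles <- avalanche_set
    durations <- lengths(profiles)
  }
  keep <- durations >= d_min_bins & durations <= d_max_bins
  profiles <- profiles[keep]
  durations <- durations[keep]
  cnt <- table(durations)
  good_d <- as.integer(names(cnt))[cnt >= min_count]
  if (length(good_d) < 3L) {
    stop("insufficient data: need >= 3 durations in [", d_min_bins, ", ",
         d_max_bins, "] with >= ", min_count, " avalanches each")
  }
  grid_t <- seq(0, 1, length.out = n_grid)
  # mean profile per duration, cubic-spline interpolated onto the common
  # grid (linear interpolation biases the collapse of coarsely sampled
  # short profiles)
  prof_mat <- vapply(good_d, function(d) {
    pm <- Reduce(`+`, profiles[durations == d]) / sum(durations == d)
    if (d == 1L) rep(pm, n_grid)
    else if (d == 2L) stats::approx(c(0, 1), pm, xout = grid_t)$y
    else stats::spline(seq(0, 1, length.out = d), pm, xout = grid_t,
                       method = "fmm")$y
  }, numeric(n_grid)) # n_grid x n_durations
  betas <- seq(beta_grid[1], beta_grid[2], by = beta_grid[3])
  errs <- vapply(betas, function(beta) {
    F <- sweep(prof_mat, 2, good_d^(beta - 1), "/")
    rng2 <- (max(F) - min(F))^2
    if (rng2 == 0) return(0)
    if (method == "variance") {
      mean(apply(F, 1, stats::var)) / rng2
    } else {
      X <- cbind(1, grid_t, grid_t^2)
      co <- stats::lm.fit(X[rep(seq_len(n_grid), ncol(F)), , drop = FALSE],
                          as.vector(F))$coefficients
      pred <- as.vector(X %*% co)
      mean((as.vector(F) - rep(pred, ncol(F)))^2) / rng2
    }
  }, numeric(1))
  i <- which.min(errs)
  beta_collapse <- betas[i]
  list(beta_collapse = beta_collapse, gamma = beta_collapse - 1,
       collapse_quality = errs[i],
       sc_error = abs(beta_collapse - beta_pred),
       n_durations = length(good_d),
       beta = betas, error = errs)
}

#' Compute the full criticality-metric panel for one session
#'
#' Runs avalanche detection, truncated power-law fits for sizes (`tau`) and
#' durations (`alpha`), the size-duration regression (`beta_fit`), the
#' exponent-relation prediction and DCC, the subsampling-corrected branching
#' ratio, and the shape collapse, returning one `criticality_metrics`
#' record.
#'
#' @param binned A [binned_activity()].
#' @param threshold_fraction Avalanche detection threshold fraction.
#' @param k_max Branching-ratio lag span.
#' @param d_min_bins,d_max_bins,beta_grid,min_count Shape-collapse settings,
#'   see [shape_collapse()].
#' @param min_events Minimum events for the power-law fits.
#' @param surrogates If > 0, run [surrogate_test()] with this many
#'   surrogates on the size and duration fits (default 0: skip).
#' @param seed Optional seed covering the surrogate draws.
#' @return An object of class `criticality_metrics`: `tau`, `alpha`,
#'   `beta_fit`, `beta_pred`, `beta_collapse`, `gamma`, `dcc`, `br`,
#'   `sc_error`, `collapse_quality`, `n_avalanches`, plus the underlying fit
#'   objects in `$fits`. Stages without enough data yield `NA` fields with a
#'   warning rather than failing the session.
#' @export
criticality_metrics <- function(binned, threshold_fraction = 0.4,
                                k_max = 10, d_min_bins = 4, d_max_bins = 20,
                                beta_grid = c(1, 3, 0.01), min_count = 4,
                                min_events = 20, surrogates = 0,
                                seed = NULL) {
  stopifnot(inherits(binned, "binned_activity"))
  if (!is.null(seed)) set.seed(seed)
  av <- detect_avalanches(binned, threshold_fraction)
  s <- avalanche_summaries(av)
  size_fit <- try_fit(s$sizes, min_events)
  dur_fit <- try_fit(s$durations, min_events)
  if (surrogates > 0) {
    if (!is.null(size_fit) && size_fit$converged) {
      size_fit <- surrogate_test(size_fit, surrogates)
    }
    if (!is.null(dur_fit) && dur_fit$converged) {
      dur_fit <- surrogate_test(dur_fit, surrogates)
    }
  }
  tau <- if (is.null(size_fit)) NA_real_ else size_fit$exponent
  alpha <- if (is.null(dur_fit)) NA_real_ else dur_fit$exponent
  d_range <- if (!is.null(dur_fit)) c(dur_fit$x_min, dur_fit$x_max)
  bf <- tryCatch(fit_beta(s$sizes, s$durations, d_range), error = function(e) {
    warning("beta_fit unavailable: ", conditionMessage(e))
    NULL
  })
  beta_fit <- if (is.null(bf)) NA_real_ else bf$beta_fit
  d <- if (!is.na(tau) && !is.na(alpha) && !is.na(beta_fit) && tau != 1) {
    dcc(alpha, tau, beta_fit)
  } else NA_real_
  beta_pred <- if (is.na(d[1])) NA_real_ else attr(d, "beta_pred")
  br <- tryCatch(branching_ratio(binned, k_max), error = function(e) {
    warning("branching ratio unavailable: ", conditionMessage(e))
    NULL
  })
  sc <- tryCatch(
    shape_collapse(av, beta_pred, d_min_bins, d_max_bins, beta_grid,
                   min_count),
    error = function(e) {
      warning("shape collapse unavailable: ", conditionMessage(e))
      NULL
    })
  structure(
    list(tau = tau, alpha = alpha, beta_fit = beta_fit,
         beta_pred = beta_pred,
         beta_collapse = if (is.null(sc)) NA_real_ else sc$beta_collapse,
         gamma = if (is.null(sc)) NA_real_ else sc$gamma,
         dcc = as.numeric(d),
         br = if (is.null(br)) NA_real_ else br$m,
         sc_error = if (is.null(sc)) NA_real_ else sc$sc_error,
         collapse_quality = if (is.null(sc)) NA_real_ else
           sc$collapse_quality,
         n_avalanches = av$n_avalanches,
         threshold_fraction = threshold_fraction,
         session_id = binned$session_id,
         fits = list(size = size_fit, duration = dur_fit, beta = bf,
                     branching = br, collapse = sc)),
    class = "criticality_metrics")
}

try_fit <- function(values, min_events) {
  tryCatch(fit_truncated_powerlaw(values, min_events = min_events),
           error = function(e) {
             warning("power-law fit unavailable: ", conditionMessage(e))
             NULL
           })
}

#' @export
print.criticality_metrics <- function(x, ...) {
  cat(sprintf("criticality_metrics '%s' (%d avalanches)\n", x$session_id,
              x$n_avalanches))
  cat(sprintf("  tau = %.3f  alpha = %.3f  beta_fit = %.3f  beta_pred = %.3f\n",
              x$tau, x$alpha, x$beta_fit, x$beta_pred))
  cat(sprintf("  DCC = %.3f  BR = %.4f  SC error = %.3f\n",
              x$dcc, x$br, x$sc_error))
  invisible(x)
}

#' Flatten criticality metrics to a one-row data frame
#' @param x A `criticality_metrics` object.
#' @return One-row data.frame of the numeric metric fields.
#' @export
as.data.frame.criticality_metrics <- function(x, ...) {
  data.frame(session_id = x$session_id, tau = x$tau, alpha = x$alpha,
             beta_fit = x$beta_fit, beta_pred = x$beta_pred,
             beta_collapse = x$beta_collapse, dcc = x$dcc, br = x$br,
             sc_error = x$sc_error, collapse_quality = x$collapse_quality,
             n_avalanches = x$n_avalanches,
             threshold_fraction = x$threshold_fraction,
             stringsAsFactors = FALSE)
}

#' Sweep the avalanche detection threshold
#'
#' Recomputes avalanche counts and criticality metrics across a range of
#' threshold fractions (default 0.30-0.70), the standard robustness check
#' for the 40% default.
#'
#' @param binned A [binned_activity()].
#' @param fractions Threshold fractions to evaluate.
#' @param ... Passed to [criticality_metrics()].
#' @return data.frame with one row per fraction.
#' @export
threshold_sweep <- function(binned, fractions = seq(0.3, 0.7, by = 0.1),
                            ...) {
  do.call(rbind, lapply(fractions, function(f) {
    m <- suppressWarnings(
      criticality_metrics(binned, threshold_fraction = f, ...))
    as.data.frame(m)
  }))
}
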