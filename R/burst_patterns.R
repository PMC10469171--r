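#' Classify the burst size distribution of a session
#'
#' Bursts (detected avalanches) are sized against `N*`, the spike count of
#' the third-largest burst: `large` if at least 75% of `N*`, `medium` if in
#' `[25%, 75%)`, `small` below 25%. The distribution is `irregular` when
#' medium bursts outnumber large ones, otherwise `bimodal` when small bursts
#' outnumber large ones, otherwise `fixed` when large bursts strictly
#' outnumber both medium and small; remaining ties are `undetermined`.
#'
#' @param burst_sizes Integer burst sizes (spike counts).
#' @return One of `"bimodal"`, `"irregular"`, `"fixed"`, `"undetermined"`,
#'   with the per-class counts attached as attribute `"counts"`.
#' @export
classify_size_distribution <- function(burst_sizes) {
  if (length(burst_sizes) < 3L) {
    warning("fewer than 3 bursts: size class undetermined")
    return("undetermined")
  }
  cl <- burst_size_classes(burst_sizes)
  n_large <- sum(cl == "large")
  n_medium <- sum(cl == "medium")
  n_small <- sum(cl == "small")
  out <- if (n_medium > n_large) "irregular"
         else if (n_small > n_large) "bimodal"
         else if (n_large > n_medium && n_large > n_small) "fixed"
         else "undetermined"
  structure(out, counts = c(large = n_large, medium = n_medium,
                            small = n_small))
}

#' Per-burst size classes relative to the third-largest burst
#'
#' @param burst_sizes Integer burst sizes; needs at least 3.
#' @return Character vector (`"large"`, `"medium"`, `"small"`) parallel to
#'   the input.
#' @export
burst_size_classes <- function(burst_sizes) {
  if (length(burst_sizes) < 3L) stop("N* requires at least 3 bursts")
  n_star <- sort(burst_sizes, decreasing = TRUE)[3]
  ifelse(burst_sizes >= 0.75 * n_star, "large",
         ifelse(burst_sizes >= 0.25 * n_star, "medium", "small"))
}

#' Classify the burst rate of a session
#'
#' The maximum rate is 10 divided by the shortest window spanning 10
#' consecutive inter-burst intervals; the minimum rate is 3 divided by the
#' longest window spanning exactly 3 consecutive intervals. The rate is
#' `highly_variable` when the two differ by a factor of 10 or more,
#' otherwise `not_variable`.
#'
#' @param burst_start_times Burst onset times in seconds (at least 11 bursts
#'   are needed for a 10-interval window).
#' @return One of `"highly_variable"`, `"not_variable"`, `"undetermined"`.
#' @export
classify_burst_rate <- function(burst_start_times) {
  n <- length(burst_start_times)
  if (n < 11L) {
    warning("fewer than 11 bursts: rate class undetermined")
    return("undetermined")
  }
  ibi <- diff(sort(burst_start_times))
  win10 <- rolling_sum(ibi, 10L)
  win3 <- rolling_sum(ibi, 3L)
  max_rate <- 10 / min(win10)
  min_rate <- 3 / max(win3)
  if (max_rate / min_rate >= 10) "highly_variable" else "not_variable"
}

rolling_sum <- function(x, k) {
  cs <- cumsum(c(0, x))
  cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]
}

#' Classify superbursting of a session
#'
#' Large and medium bursts (see [burst_size_classes()]) are clustered by a
#' greedy gap split: gaps at least 10 times the median intra-cluster
#' interval separate clusters, iterated to a fixed point. A recording is
#' superburst-dominated only when at least half of the large/medium bursts
#' fall into multi-burst clusters separated by such gaps; otherwise the
#' class is `none`. Superbursts are `regular` when the variance of bursts
#' per cluster is below half the mean, else `short` when the mean bursts per
#' cluster is below 10, else `long`.
#'
#' @param burst_start_times Burst onset times in seconds.
#' @param burst_sizes Parallel burst sizes (spike counts).
#' @param max_iter Fixed-point iterations for the gap threshold.
#' @return One of `"none"`, `"regular"`, `"short"`, `"long"`.
#' @export
classify_superbursts <- function(burst_start_times, burst_sizes,
                                 max_iter = 5) {
  if (length(burst_start_times) != length(burst_sizes)) {
    stop("start times and sizes must be paired")
  }
  if (length(burst_sizes) < 3L) return("none")
  cl <- burst_size_classes(burst_sizes)
  t_lm <- sort(burst_start_times[cl != "small"])
  if (length(t_lm) < 2L) return("none")
  gaps <- diff(t_lm)
  intra <- stats::median(gaps)
  groups <- NULL
  for (i in seq_len(max_iter)) {
    thr <- 10 * intra
    brk <- gaps >= thr
    new_groups <- cumsum(c(0, brk))
    within <- gaps[!brk]
    if (identical(new_groups, groups) || !length(within)) {
      groups <- new_groups
      break
    }
    groups <- new_groups
    intra <- stats::median(within)
  }
  sizes_per_cluster <- as.integer(table(groups))
  multi <- sizes_per_cluster[sizes_per_cluster >= 2L]
  if (length(sizes_per_cluster) < 2L || sum(multi) < length(t_lm) / 2) {
    return("none")
  }
  mu <- mean(sizes_per_cluster)
  v <- stats::var(sizes_per_cluster)
  if (v < mu / 2) "regular" else if (mu < 10) "short" else "long"
}

#' Full burst-pattern label for one avalanche set
#'
#' @param set An `avalanche_set` from [detect_avalanches()].
#' @return List with `size_class`, `rate_class`, `superburst_class`.
#' @export
burst_pattern <- function(set) {
  stopifnot(inherits(set, "avalanche_set"))
  sizes <- set$events$size
  starts <- (set$events$start_bin - 1L) * set$bin_width_ms / 1000
  list(
    size_class = as.character(suppressWarnings(
      classify_size_distribution(sizes))),
    rate_class = suppressWarnings(classify_burst_rate(starts)),
    superburst_class = if (length(sizes) < 3L) "none" else
      classify_superbursts(starts, sizes))
}
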