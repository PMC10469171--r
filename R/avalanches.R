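#' Detect neuronal avalanches from population activity
#'
#' An avalanche is a maximal run of consecutive time bins whose population
#' count lies strictly above a threshold, taken as a fraction (default 40%)
#' of the median population over all bins, zeros included. Size `S` is the
#' total spike count inside the supra-threshold window; duration `D` is its
#' length in bins (the time between the upward and downward threshold
#' crossings).
#'
#' Avalanches touching the first or last bin cannot be confirmed to start or
#' end with a threshold crossing and are flagged as censored (kept by
#' default).
#'
#' @param binned A [binned_activity()].
#' @param threshold_fraction Fraction of the median population used as the
#'   threshold, in (0, 1]. Results are typically robust over 0.30-0.70.
#' @param threshold_value Optional absolute threshold overriding the
#'   median-based one (used e.g. to compare sessions under a common
#'   threshold).
#' @param zero_median How to treat a recording whose median bin is silent
#'   (common in sparse activity): `"zero"` (default) lets the threshold
#'   degenerate to 0 so avalanches become the classical maximal runs of
#'   non-zero activity, with a warning; `"empty"` returns an empty set.
#' @return An object of class `avalanche_set`: a list with `events` (a
#'   data.frame with columns `start_bin`, `end_bin`, `d_bins`, `d_s`, `size`,
#'   `censored`; `[start_bin, end_bin)` is half-open, 1-based), `profiles`
#'   (list of per-bin population counts within each avalanche),
#'   `threshold_fraction`, `threshold_value`, `bin_width_ms` and `n_avalanches`.
#' @examples
#' b <- binned_activity(c(0, 3, 5, 4, 0, 2, 0), 50)
#' a <- detect_avalanches(b, 0.4)
#' a$events[, c("size", "d_bins")]
#' @export
detect_avalanches <- function(binned, threshold_fraction = 0.4,
                              threshold_value = NULL,
                              zero_median = c("zero", "empty")) {
  stopifnot(inherits(binned, "binned_activity"))
  zero_median <- match.arg(zero_median)
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    stop("threshold_fraction must be in (0, 1]")
  }
  pop <- binned$population
  if (!length(pop)) stop("population vector is empty")
  if (is.null(threshold_value)) {
    med <- stats::median(pop)
    threshold_value <- threshold_fraction * med
    if (med == 0) {
      if (zero_median == "empty") {
        warning("median population is 0: degenerate threshold, no avalanches")
        return(empty_avalanche_set(binned, threshold_fraction,
                                   threshold_value))
      }
      if (any(pop > 0)) {
        warning("median population is 0: threshold degenerates to 0, ",
                "avalanches are maximal runs of non-zero activity")
      }
    }
  }
  above <- pop > threshold_value
  if (!any(above)) {
    warning("no bins above threshold: empty avalanche set")
    return(empty_avalanche_set(binned, threshold_fraction, threshold_value))
  }
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)
  starts <- run_start[keep]
  ends <- run_end[keep] # inclusive index of last supra bin
  sizes <- vapply(seq_along(starts),
                  function(i) sum(pop[starts[i]:ends[i]]), numeric(1))
  profiles <- lapply(seq_along(starts), function(i) pop[starts[i]:ends[i]])
  d_bins <- ends - starts + 1L
  events <- data.frame(
    start_bin = starts,
    end_bin = ends + 1L,
    d_bins = d_bins,
    d_s = d_bins * binned$bin_width_ms / 1000,
    size = sizes,
    censored = starts == 1L | ends == binned$n_bins)
  structure(
    list(events = events, profiles = profiles,
         threshold_fraction = threshold_fraction,
         threshold_value = threshold_value,
         bin_width_ms = binned$bin_width_ms,
         n_avalanches = nrow(events),
         session_id = binned$session_id),
    class = "avalanche_set")
}

empty_avalanche_set <- function(binned, threshold_fraction, threshold_value) {
  structure(
    list(events = data.frame(start_bin = integer(0), end_bin = integer(0),
                             d_bins = integer(0), d_s = numeric(0),
                             size = numeric(0), censored = logical(0)),
         profiles = list(),
         threshold_fraction = threshold_fraction,
         threshold_value = threshold_value,
         bin_width_ms = binned$bin_width_ms,
         n_avalanches = 0L,
         session_id = binned$session_id),
    class = "avalanche_set")
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat(sprintf(
    "avalanche_set '%s': %d avalanches (threshold %.3g = %.0f%% of median)\n",
    x$session_id, x$n_avalanches, x$threshold_value,
    100 * x$threshold_fraction))
  invisible(x)
}

#' Extract avalanche sizes and durations
#'
#' @param set An `avalanche_set` from [detect_avalanches()].
#' @return A list with integer vectors `sizes` (total spikes per avalanche)
#'   and `durations` (in bins), in detection order.
#' @export
avalanche_summaries <- function(set) {
  stopifnot(inherits(set, "avalanche_set"))
  list(sizes = as.integer(round(set$events$size)),
       durations = as.integer(set$events$d_bins))
}
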