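#' Construct a spike raster
#'
#' A spike raster holds per-channel spike times (in seconds) for one
#' recording session. Spike times must lie in `[0, duration_s]` and each
#' channel's times are stored sorted.
#'
#' @param spikes Named list of numeric vectors, one per channel, each the
#'   spike times of that channel in seconds. Names are the channel labels.
#' @param duration_s Total recording length in seconds. Defaults to the
#'   latest spike time.
#' @param session_id Optional session identifier string.
#' @return An object of class `spike_raster` with elements `session_id`,
#'   `channel_ids` (integer), `spikes` (list of sorted numeric vectors) and
#'   `duration_s`.
#' @examples
#' r <- spike_raster(list(`0` = c(0.01, 0.4), `1` = 0.06), duration_s = 1)
#' n_spikes(r)
#' @export
spike_raster <- function(spikes, duration_s = NULL, session_id = "session") {
  if (!is.list(spikes)) stop("`spikes` must be a list of numeric vectors")
  if (is.null(names(spikes))) names(spikes) <- seq_along(spikes) - 1L
  channel_ids <- suppressWarnings(as.integer(names(spikes)))
  if (anyNA(channel_ids)) stop("channel names must be integer labels")
  if (anyDuplicated(channel_ids)) stop("channel ids must be unique")
  spikes <- lapply(spikes, function(x) sort(as.numeric(x)))
  all_t <- unlist(spikes, use.names = FALSE)
  if (length(all_t) && any(!is.finite(all_t))) {
    stop("spike times must be finite")
  }
  if (length(all_t) && any(all_t < 0)) stop("spike times must be non-negative")
  if (is.null(duration_s)) {
    duration_s <- if (length(all_t)) max(all_t) else 0
  }
  if (length(all_t) && any(all_t > duration_s)) {
    stop("spike times exceed duration_s")
  }
  structure(
    list(session_id = session_id, channel_ids = channel_ids,
         spikes = spikes, duration_s = as.numeric(duration_s)),
    class = "spike_raster")
}

#' Total number of spikes in a raster
#' @param raster A `spike_raster`.
#' @return Integer spike count over all channels.
#' @export
n_spikes <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  sum(lengths(raster$spikes))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster '%s': %d channels, %d spikes, %.3f s\n",
              x$session_id, length(x$channel_ids), n_spikes(x), x$duration_s))
  invisible(x)
}

#' Load a spike table from disk
#'
#' Reads a `(channel, time_s)` spike table into a [spike_raster()]. The CSV
#' dialect has a header `channel,time_s`, one row per spike. Rows that fail
#' validation (negative, missing or non-numeric times) raise an error naming
#' the offending row rather than being silently dropped.
#'
#' @param path Path to the file.
#' @param format Input format; only `"csv"` is currently supported.
#' @param duration_s Recording length in seconds; defaults to the last spike.
#' @param session_id Session identifier; defaults to the file name.
#' @return A [spike_raster()].
#' @export
load_spike_table <- function(path, format = c("csv", "hdf5"),
                             duration_s = NULL, session_id = NULL) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stop("HDF5 input is not supported by this build; convert to the ",
         "channel,time_s CSV dialect")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(session_id)) {
    session_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- utils::read.csv(path, colClasses = c("integer", "numeric"))
  if (!all(c("channel", "time_s") %in% names(tab))) {
    stop("spike table must have columns 'channel' and 'time_s'")
  }
  if (nrow(tab) == 0L) {
    warning("empty spike table: raster has 0 spikes")
    return(spike_raster(structure(list(), names = character(0)),
                        duration_s = duration_s %||% 0,
                        session_id = session_id))
  }
  bad <- which(!is.finite(tab$time_s) | tab$time_s < 0 | is.na(tab$channel))
  if (length(bad)) {
    stop(sprintf("invalid spike time at row %d (time_s = %s)",
                 bad[1], format(tab$time_s[bad[1]])))
  }
  spk <- split(tab$time_s, tab$channel)
  spike_raster(spk, duration_s = duration_s, session_id = session_id)
}

#' Write a spike raster to a CSV table
#'
#' @param raster A [spike_raster()].
#' @param path Output path; the written file has header `channel,time_s`.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  tab <- data.frame(
    channel = rep(raster$channel_ids, lengths(raster$spikes)),
    time_s = unlist(raster$spikes, use.names = FALSE))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct binned population activity
#'
#' Low-level constructor; most users call [bin_spikes()] or
#' [simulate_branching()]. The population vector is the per-bin sum of
#' spike counts over channels ("network activity"); the full channels x bins
#' count matrix is optional, since the avalanche and branching-ratio
#' estimators operate on the population alone.
#'
#' @param population Integer vector of per-bin population counts.
#' @param bin_width_ms Bin width in milliseconds.
#' @param counts Optional channels x bins integer matrix whose column sums
#'   must equal `population`.
#' @param channel_ids Optional channel labels (rows of `counts`).
#' @param session_id Session identifier.
#' @return An object of class `binned_activity`.
#' @export
binned_activity <- function(population, bin_width_ms, counts = NULL,
                            channel_ids = NULL, session_id = "session") {
  population <- as.numeric(population)
  if (bin_width_ms <= 0) stop("bin_width_ms must be positive")
  if (any(population < 0)) stop("population counts must be non-negative")
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (ncol(counts) != length(population)) {
      stop("counts must have one column per bin")
    }
    if (!isTRUE(all.equal(unname(colSums(counts)), unname(population)))) {
      stop("population must equal the column sums of counts")
    }
    if (is.null(channel_ids)) channel_ids <- seq_len(nrow(counts)) - 1L
  }
  structure(
    list(counts = counts, population = population,
         bin_width_ms = as.numeric(bin_width_ms),
         n_bins = length(population),
         duration_s = length(population) * bin_width_ms / 1000,
         channel_ids = channel_ids, session_id = session_id),
    class = "binned_activity")
}

#' @export
print.binned_activity <- function(x, ...) {
  cat(sprintf(
    "binned_activity '%s': %d bins x %.0f ms, mean population %.2f%s\n",
    x$session_id, x$n_bins, x$bin_width_ms, mean(x$population),
    if (is.null(x$counts)) " (population only)" else
      sprintf(", %d channels", nrow(x$counts))))
  invisible(x)
}

#' Bin a spike raster into population activity
#'
#' Spikes are assigned to half-open bins `[t*delta, (t+1)*delta)`; a spike at
#' exactly `duration_s` falls in the last bin. The number of bins is
#' `ceiling(duration_s / delta)`, so a trailing partial bin is kept.
#'
#' @param raster A [spike_raster()].
#' @param bin_width_ms Bin width in milliseconds (default 50, the standard
#'   discretisation for MEA avalanche analysis).
#' @return A [binned_activity()] with the full channels x bins count matrix.
#' @examples
#' r <- spike_raster(list(`0` = 0.010, `1` = 0.060), duration_s = 1)
#' b <- bin_spikes(r, 50)
#' b$population[1:3]
#' @export
bin_spikes <- function(raster, bin_width_ms = 50) {
  stopifnot(inherits(raster, "spike_raster"))
  if (!is.numeric(bin_width_ms) || bin_width_ms <= 0) {
    stop("bin_width_ms must be a positive number")
  }
  delta <- bin_width_ms / 1000
  n_bins <- max(1L, as.integer(ceiling(raster$duration_s / delta)))
  n_ch <- length(raster$channel_ids)
  counts <- matrix(0L, nrow = n_ch, ncol = n_bins)
  for (i in seq_len(n_ch)) {
    tt <- raster$spikes[[i]]
    if (!length(tt)) next
    idx <- pmin(as.integer(floor(tt / delta)) + 1L, n_bins)
    tab <- tabulate(idx, nbins = n_bins)
    counts[i, ] <- tab
  }
  rownames(counts) <- raster$channel_ids
  binned_activity(colSums(counts), bin_width_ms, counts = counts,
                  channel_ids = raster$channel_ids,
                  session_id = raster$session_id)
}

#' Time-shuffle binned activity
#'
#' Applies one random permutation of bin indices jointly to all channels:
#' each per-bin spatial pattern (the joint count vector across channels) is
#' kept intact while the temporal order is randomised. This is the control
#' that preserves spatial correlations but destroys temporal structure; on
#' near-critical data it inflates the deviation from criticality.
#'
#' @param binned A [binned_activity()].
#' @param seed Optional integer seed for the permutation.
#' @return A [binned_activity()] with permuted bins.
#' @export
time_shuffle <- function(binned, seed = NULL) {
  stopifnot(inherits(binned, "binned_activity"))
  if (binned$n_bins < 2L) {
    warning("fewer than 2 bins: time_shuffle is a no-op")
    return(binned)
  }
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(binned$n_bins)
  binned_activity(binned$population[perm], binned$bin_width_ms,
                  counts = if (!is.null(binned$counts))
                    binned$counts[, perm, drop = FALSE],
                  channel_ids = binned$channel_ids,
                  session_id = binned$session_id)
}
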