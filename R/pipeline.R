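#' Default pipeline configuration
#'
#' The printed constants of the analysis: 50 ms bins, 40%-of-median
#' avalanche threshold (robustness sweep 0.30-0.70), 1000 surrogates at
#' significance 0.05, branching-ratio lag span 10, shape-collapse durations
#' 4-20 bins with the beta grid 1-3 by 0.01.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(bin_width_ms = 50, threshold_fraction = 0.4,
              threshold_sweep = c(0.3, 0.7), surrogates = 1000,
              significance = 0.05, k_max = 10,
              d_min_bins = 4, d_max_bins = 20,
              beta_grid = c(1, 3, 0.01), min_count = 4, min_events = 20,
              cv_folds = 5, cv_repeats = 10, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full avalanche-criticality pipeline over a session manifest
#'
#' For every manifest row the raster is loaded, binned, avalanches are
#' detected, criticality metrics and burst-pattern labels computed; the
#' resulting session table is then compared between conditions
#' (Alexander-Govern per metric), correlated with performance, and
#' classified (three classifiers x feature schemas) when both conditions
#' are present. Sessions failing a stage are reported and skipped; the run
#' continues.
#'
#' @param manifest data.frame (or path to a CSV) with columns `session_id`,
#'   `condition`, `hits`, `misses`, `raster_path`.
#' @param config List from [pipeline_config()].
#' @param hm_mode `"hits_over_misses"` (the verbatim reading of a hit/miss
#'   ratio) or `"hits_over_total"` (hits / (hits + misses)).
#' @param out_dir Optional directory; if given, `metrics.csv` and
#'   `report.json` are written there.
#' @return List with `metrics` (per-session data.frame), `comparisons`
#'   (Alexander-Govern per metric), `correlations` (each metric vs
#'   H/M ratio, uncorrected and BH-adjusted), `accuracy` (classification
#'   matrix or NULL), `failures`, `config`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         hm_mode = c("hits_over_misses", "hits_over_total"),
                         out_dir = NULL) {
  hm_mode <- match.arg(hm_mode)
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  need <- c("session_id", "condition", "hits", "misses", "raster_path")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) stop("manifest lacks columns: ",
                            paste(missing, collapse = ", "))
  rows <- list()
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    rec <- tryCatch({
      raster <- load_spike_table(row$raster_path,
                                 session_id = row$session_id)
      binned <- bin_spikes(raster, config$bin_width_ms)
      met <- suppressWarnings(criticality_metrics(
        binned, threshold_fraction = config$threshold_fraction,
        k_max = config$k_max, d_min_bins = config$d_min_bins,
        d_max_bins = config$d_max_bins, beta_grid = config$beta_grid,
        min_count = config$min_count, min_events = config$min_events))
      av <- suppressWarnings(
        detect_avalanches(binned, config$threshold_fraction))
      bp <- burst_pattern(av)
      out <- as.data.frame(met)
      out$condition <- row$condition
      out$hm_ratio <- if (hm_mode == "hits_over_misses") {
        row$hits / row$misses
      } else row$hits / (row$hits + row$misses)
      out$size_class <- bp$size_class
      out$rate_class <- bp$rate_class
      out$superburst_class <- bp$superburst_class
      out
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<- list(
        session_id = row$session_id, message = conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else NULL
  comparisons <- correlations <- accuracy <- NULL
  if (!is.null(metrics) && length(unique(metrics$condition)) == 2L) {
    split_by <- function(col) split(metrics[[col]], metrics$condition)
    comparisons <- lapply(c(dcc = "dcc", br = "br", sc_error = "sc_error",
                            hm_ratio = "hm_ratio"), function(col) {
      tryCatch(alexander_govern(lapply(split_by(col),
                                       function(x) x[is.finite(x)])),
               error = function(e) list(statistic = NA, p_value = NA,
                                        error = conditionMessage(e)))
    })
    correlations <- metric_performance_correlations(metrics)
    if (nrow(metrics) >= 10L &&
        all(table(metrics$condition) >= config$cv_folds)) {
      accuracy <- tryCatch(
        classification_matrix(metrics, folds = config$cv_folds,
                              repeats = config$cv_repeats,
                              seed = config$seed),
        error = function(e) NULL)
    }
  }
  result <- list(metrics = metrics, comparisons = comparisons,
                 correlations = correlations, accuracy = accuracy,
                 failures = failures, config = config, hm_mode = hm_mode)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(metrics)) {
      utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(config = config, hm_mode = hm_mode,
           comparisons = comparisons, correlations = correlations,
           accuracy = accuracy,
           failures = failures,
           r_version = R.version.string),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  result
}

#' Metric-vs-performance correlation table
#'
#' Pearson correlation of each criticality metric with the H/M performance
#' ratio, reporting uncorrected and Benjamini-Hochberg adjusted p-values.
#'
#' @param metrics Session table with columns `dcc`, `br`, `sc_error`,
#'   `hm_ratio`.
#' @return data.frame with columns `metric`, `r`, `p_value`, `p_adjusted`.
#' @export
metric_performance_correlations <- function(metrics) {
  cols <- c("dcc", "br", "sc_error")
  res <- lapply(cols, function(col) {
    ct <- tryCatch(correlate_metric(metrics[[col]], metrics$hm_ratio),
                   error = function(e) list(r = NA_real_,
                                            p_value = NA_real_))
    data.frame(metric = col, r = ct$r, p_value = ct$p_value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
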