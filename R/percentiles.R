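# Resolution-binned integer-percentile library used to put the continuous
# metrics of different units on one comparable scale.

# Default non-uniform resolution bin edges (Angstrom): 9 edges -> 10 bins.
default_bin_edges <- function() c(1.0, 1.3, 1.5, 1.8, 2.0, 2.3, 2.5, 3.0, 4.0)

# Metric polarity: TRUE when a higher raw value means a poorer residue.
default_metric_polarity <- function() {
  c(b_mean = TRUE, b_max = TRUE, fit_all = TRUE, fit_side = TRUE,
    rama_prob = FALSE, rot_score = TRUE)
}

#' Build a resolution-binned percentile library
#'
#' Routes records to resolution bins, then computes empirical quantile
#' thresholds at every integer percentile 1..99 per bin and metric
#' (type-7 quantiles: linear interpolation between order statistics). An
#' all-data entry over the unbinned stream serves models of unknown
#' resolution and empty bins.
#'
#' @param records data frame with columns `metric` (name), `value` (numeric),
#'   `resolution` (Angstrom; `NA` allowed, such records only feed the
#'   all-data entry).
#' @param bin_edges ascending resolutions splitting the resolution axis into
#'   `length(bin_edges) + 1` bins; the default 9 edges give 10 bins.
#' @param polarity named logical vector, `TRUE` where a higher raw value is
#'   worse; stored as metadata for display-side flipping.
#' @param provenance free-text note stored in metadata (e.g. corpus and
#'   deposition-date filters applied upstream).
#' @return object of class `PercentileLibrary`.
#' @export
build_percentile_library <- function(records,
                                     bin_edges = default_bin_edges(),
                                     polarity = default_metric_polarity(),
                                     provenance = "synthetic") {
  stopifnot(all(c("metric", "value", "resolution") %in% names(records)),
            !is.unsorted(bin_edges, strictly = TRUE))
  records <- records[is.finite(records$value), , drop = FALSE]
  metrics <- sort(unique(as.character(records$metric)))
  probs <- (1:99) / 100
  thresholds_of <- function(v) {
    if (length(v) == 0L) return(NULL)
    as.numeric(stats::quantile(v, probs, type = 7, names = FALSE))
  }
  n_bins <- length(bin_edges) + 1L
  bin_of <- findInterval(records$resolution, bin_edges) + 1L  # NA stays NA
  bins <- lapply(seq_len(n_bins), function(b) {
    inbin <- !is.na(bin_of) & bin_of == b
    out <- lapply(metrics, function(m) {
      thresholds_of(records$value[inbin & records$metric == m])
    })
    names(out) <- metrics
    out
  })
  all_data <- lapply(metrics, function(m) {
    thresholds_of(records$value[records$metric == m])
  })
  names(all_data) <- metrics
  structure(list(
    bin_edges = as.numeric(bin_edges),
    bins = bins,
    all_data = all_data,
    metadata = list(metrics = metrics,
                    polarity = polarity,
                    quantile_type = 7L,
                    provenance = provenance,
                    n_records = nrow(records))
  ), class = "PercentileLibrary")
}

#' Percentile of a metric value
#'
#' The largest integer percentile whose threshold is at or below `value`
#' (0 when below the 1st-percentile threshold). Resolution routes the query
#' to its bin; an absent resolution or an unusable (empty) bin falls back to
#' the all-data entry.
#'
#' @param lib a `PercentileLibrary`.
#' @param metric metric name known to the library.
#' @param value raw metric value.
#' @param resolution resolution in Angstrom, or `NA`.
#' @return integer in `[0, 100]`, `NA` for an `NA` value.
#' @export
percentile_of <- function(lib, metric, value, resolution = NA_real_) {
  if (!(metric %in% lib$metadata$metrics))
    stop("unknown metric in percentile library: ", metric)
  if (is.na(value)) return(NA_integer_)
  thr <- NULL
  if (!is.na(resolution)) {
    b <- findInterval(resolution, lib$bin_edges) + 1L
    thr <- lib$bins[[b]][[metric]]
  }
  if (is.null(thr)) thr <- lib$all_data[[metric]]
  if (is.null(thr)) return(NA_integer_)
  as.integer(sum(thr <= value))
}

# Display-scale percentile: always "higher = better". Flips where the raw
# metric's polarity is higher-is-worse.
display_percentile <- function(lib, metric, value, resolution = NA_real_) {
  p <- percentile_of(lib, metric, value, resolution)
  if (is.na(p)) return(NA_integer_)
  flip <- isTRUE(lib$metadata$polarity[[metric]])
  if (flip) 100L - p else p
}

#' Serialize / load a percentile library (JSON)
#'
#' Thresholds are written with full round-trip precision so regeneration and
#' reload preserve every threshold bit-exactly.
#'
#' @param lib a `PercentileLibrary`.
#' @param path file path.
#' @return the path (writer, invisibly) or a `PercentileLibrary` (reader).
#' @export
write_percentile_library <- function(lib, path) {
  # doubles are stored as %.17g strings: that representation round-trips
  # IEEE-754 values exactly, which plain JSON numbers do not guarantee
  enc <- function(v) if (is.null(v)) NULL else sprintf("%.17g", v)
  payload <- list(
    bin_edges = enc(lib$bin_edges),
    bins = lapply(lib$bins, function(b) lapply(b, enc)),
    all_data = lapply(lib$all_data, enc),
    metadata = list(metrics = lib$metadata$metrics,
                    polarity = as.list(lib$metadata$polarity),
                    quantile_type = lib$metadata$quantile_type,
                    provenance = lib$metadata$provenance,
                    n_records = lib$metadata$n_records)
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_percentile_library
#' @export
read_percentile_library <- function(path) {
  p <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                          simplifyVector = FALSE)
  fix_entry <- function(e) {
    lapply(e, function(v) if (is.null(v)) NULL else as.numeric(unlist(v)))
  }
  structure(list(
    bin_edges = as.numeric(unlist(p$bin_edges)),
    bins = lapply(p$bins, fix_entry),
    all_data = fix_entry(p$all_data),
    metadata = list(metrics = as.character(unlist(p$metadata$metrics)),
                    polarity = unlist(p$metadata$polarity),
                    quantile_type = p$metadata$quantile_type,
                    provenance = p$metadata$provenance,
                    n_records = p$metadata$n_records)
  ), class = "PercentileLibrary")
}
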