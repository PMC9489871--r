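#' Embed tabular demographics
#'
#' Min-max normalises each schema variable to \[0, 1\] using the declared
#' ranges, in schema order. Missing variables contribute 0; values outside
#' the declared range are clipped with a warning.
#'
#' @param demographics named numeric vector or list of raw values.
#' @param schema tibble with columns `name`, `min`, `max`
#'   (default [demographics_schema()], 6 variables).
#' @return Numeric vector of length `nrow(schema)`, named by variable.
#' @export
embed_tabular <- function(demographics, schema = demographics_schema()) {
  demographics <- unlist(demographics)
  out <- stats::setNames(numeric(nrow(schema)), schema$name)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (!nm %in% names(demographics)) next
    v <- demographics[[nm]]
    if (is.na(v)) next
    lo <- schema$min[i]; hi <- schema$max[i]
    if (v < lo || v > hi) {
      warn(paste0("Demographic `", nm, "` = ", v,
                  " outside declared range [", lo, ", ", hi, "]; clipped."))
      v <- min(max(v, lo), hi)
    }
    out[i] <- (v - lo) / (hi - lo)
  }
  out
}

#' Eleven summary statistics of one irregular time series
#'
#' Encodes a single clinical signal's trajectory up to the inference time
#' as a fixed 11-vector:
#' `n` (observation count), `max`, `min`, `mean`, `median`, population
#' `sd`, population `var`, `n_peaks` (strict local maxima,
#' `v[i-1] < v[i] > v[i+1]`; endpoints never count), `slope_mean` (mean of
#' per-step slopes dv/dt), `abs_change_mean` (mean of |dv|/dt, the
#' piece-wise change magnitude), and `trend`
#' (`(v_last - v_first)/(t_last - t_first)`). Steps with zero time gap are
#' skipped in the slope terms. An empty series gives the zero vector; a
#' single observation gives `[1, v, v, v, v, 0, 0, 0, 0, 0, 0]`.
#'
#' @param time,value numeric vectors of equal length; `time` must be
#'   sorted non-decreasing and `value` finite.
#' @return Named numeric vector of length 11.
#' @export
embed_timeseries_signal <- function(time, value) {
  nm <- c("n", "max", "min", "mean", "median", "sd", "var",
          "n_peaks", "slope_mean", "abs_change_mean", "trend")
  n <- length(value)
  if (length(time) != n) abort("`time` and `value` lengths differ.")
  if (n == 0) return(stats::setNames(numeric(11), nm))
  if (!all(is.finite(time)) || !all(is.finite(value))) {
    abort("Time-series values and times must be finite.")
  }
  if (is.unsorted(time)) abort("Series must be sorted by time.")
  if (n == 1) {
    return(stats::setNames(c(1, value, value, value, value, 0, 0, 0, 0, 0, 0),
                           nm))
  }
  pvar <- mean((value - mean(value))^2)
  peaks <- if (n >= 3) {
    mid <- 2:(n - 1)
    sum(value[mid] > value[mid - 1] & value[mid] > value[mid + 1])
  } else 0
  dt <- diff(time)
  dv <- diff(value)
  ok <- dt > 0
  slope_mean <- if (any(ok)) mean(dv[ok] / dt[ok]) else 0
  abs_change <- if (any(ok)) mean(abs(dv[ok]) / dt[ok]) else 0
  span <- time[n] - time[1]
  trend <- if (span > 0) (value[n] - value[1]) / span else 0
  stats::setNames(
    c(n, max(value), min(value), mean(value), stats::median(value),
      sqrt(pvar), pvar, peaks, slope_mean, abs_change, trend),
    nm)
}

#' Embed one time-series source
#'
#' Concatenates [embed_timeseries_signal()] blocks for every signal of a
#' registered time-series source, in the fixed order of
#' [timeseries_signals()]. Signals with no observations in the table
#' contribute an all-zero block, so the output length is always
#' `11 * n_signals` (99 for chart events, 242 for laboratory events, 110
#' for procedure events).
#'
#' @param events event table (`signal_name`, `time_hours`, `value`).
#' @param source `"ce"`, `"le"` or `"pe"`; or pass `signals` directly.
#' @param signals ordered character vector of signal names overriding the
#'   registry list (used by reduced test registries).
#' @return Named numeric vector of length `11 * length(signals)`.
#' @export
embed_timeseries_source <- function(events, source = NULL, signals = NULL) {
  if (is.null(signals)) {
    if (is.null(source)) abort("Provide `source` or `signals`.")
    signals <- timeseries_signals(source)
  }
  events <- as_event_table(events)
  by_sig <- split(events[c("time_hours", "value")], events$signal_name)
  blocks <- lapply(signals, function(sig) {
    tab <- by_sig[[sig]]
    if (is.null(tab)) return(embed_timeseries_signal(numeric(0), numeric(0)))
    ord <- order(tab$time_hours)
    embed_timeseries_signal(tab$time_hours[ord], tab$value[ord])
  })
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- as.vector(t(outer(signals,
                                  names(blocks[[1]]) %||%
                                    character(0), paste, sep = ".")))
  out
}
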