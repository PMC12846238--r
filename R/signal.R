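#' Uniformly sampled signal
#'
#' The common container for every channel the package handles: a vertical
#' heel coordinate, a vertical ground reaction force (vGRF), or any derived
#' dimensionless trace.  Sample `i` (1-based) lies at time
#' `start_time + (i - 1) / sampling_rate` on the recording's own clock;
#' distinct recordings (cameras vs. force platforms) carry distinct clocks
#' and are only comparable after synchronization.
#'
#' Non-finite samples are rejected at construction: tracking dropouts must
#' be handled upstream rather than silently propagated through filters and
#' detectors.
#'
#' @param values numeric vector of samples (length >= 1, all finite).
#' @param sampling_rate sampling rate in Hz, > 0.
#' @param start_time time of the first sample in seconds on this
#'   recording's own clock.
#' @param label short channel label, e.g. `"LHeel"` or `"Fz1"`.
#' @param units unit string: `"m"` for positions, `"N"` for forces, `""`
#'   for dimensionless traces.
#' @return An object of class `sampled_signal`.
#' @examples
#' s <- sampled_signal(sin(seq(0, 1, by = 0.01)), sampling_rate = 100)
#' signal_times(s)[1:5]
#' @export
sampled_signal <- function(values, sampling_rate, start_time = 0,
                           label = "signal", units = "") {
  values <- as.numeric(values)
  if (length(values) < 1L)
    gs_parameter_error("'values' must contain at least one sample")
  if (anyNA(values) || any(!is.finite(values)))
    gs_parameter_error(sprintf(
      "non-finite sample at index %d: gaps must be resolved before analysis",
      which(!is.finite(values))[1L]))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    gs_parameter_error("'sampling_rate' must be a single positive number (Hz)")
  if (!is.numeric(start_time) || length(start_time) != 1L ||
      !is.finite(start_time))
    gs_parameter_error("'start_time' must be a single finite number (s)")
  structure(
    list(values = values,
         sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time),
         label = as.character(label)[1L],
         units = as.character(units)[1L]),
    class = "sampled_signal")
}

#' @rdname sampled_signal
#' @param x a `sampled_signal`.
#' @export
is_sampled_signal <- function(x) inherits(x, "sampled_signal")

#' @rdname sampled_signal
#' @return `signal_times()`: numeric vector of per-sample times (s).
#' @export
signal_times <- function(x) {
  stopifnot(is_sampled_signal(x))
  x$start_time + (seq_along(x$values) - 1) / x$sampling_rate
}

#' @rdname sampled_signal
#' @return `signal_end_time()`: time of the last sample (s).
#' @export
signal_end_time <- function(x) {
  stopifnot(is_sampled_signal(x))
  x$start_time + (length(x$values) - 1) / x$sampling_rate
}

#' @rdname sampled_signal
#' @param index 1-based sample index.
#' @return `sample_time()`: time of sample `index` (s).
#' @export
sample_time <- function(x, index) {
  stopifnot(is_sampled_signal(x))
  x$start_time + (index - 1) / x$sampling_rate
}

# Replace the samples of a signal, keeping clock and metadata.
signal_with_values <- function(x, values, units = x$units, label = x$label) {
  sampled_signal(values, x$sampling_rate, x$start_time, label, units)
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s [%s]: %d samples @ %g Hz, t = %.4f..%.4f s\n",
              x$label, if (nzchar(x$units)) x$units else "dimensionless",
              length(x$values), x$sampling_rate,
              x$start_time, signal_end_time(x)))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$values)
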