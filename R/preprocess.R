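#' Low-pass filter specification
#'
#' Describes a Butterworth low-pass stage.  Two named defaults cover the
#' pipeline's immutable stages: [heel_cascade_spec()] — a cascade of two
#' 4th-order 3 Hz filters, each applied bidirectionally (zero phase) —
#' and [force_lowpass_spec()] — one 4th-order 30 Hz zero-phase filter for
#' the vGRF.
#'
#' @param order filter order (>= 1); 4 in both default stages.
#' @param cutoff_hz -3 dB cutoff in Hz; must stay below the Nyquist
#'   frequency of the signal it is applied to.
#' @param bidirectional apply forward then backward so the net phase shift
#'   is zero.  Event timing is the whole point of the pipeline, so both
#'   defaults are zero-phase.
#' @param passes number of cascaded applications of the same filter.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(order = 4L, cutoff_hz, bidirectional = TRUE,
                        passes = 1L) {
  order <- as.integer(order); passes <- as.integer(passes)
  if (is.na(order) || order < 1L)
    gs_parameter_error("'order' must be an integer >= 1")
  if (is.na(passes) || passes < 1L)
    gs_parameter_error("'passes' must be an integer >= 1")
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L || cutoff_hz <= 0)
    gs_parameter_error("'cutoff_hz' must be a single positive number")
  structure(list(order = order, cutoff_hz = as.numeric(cutoff_hz),
                 bidirectional = isTRUE(bidirectional), passes = passes),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
heel_cascade_spec <- function() filter_spec(4L, 3, TRUE, passes = 2L)

#' @rdname filter_spec
#' @export
force_lowpass_spec <- function() filter_spec(4L, 30, TRUE, passes = 1L)

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> Butterworth low-pass, order %d, %g Hz, %s, %d pass(es)\n",
              x$order, x$cutoff_hz,
              if (x$bidirectional) "bidirectional (zero-phase)" else "causal",
              x$passes))
  invisible(x)
}

# --- filtering core ---------------------------------------------------------

# One causal IIR pass with steady-state initialisation: the filter state is
# set to the steady-state response to a constant input equal to the first
# sample, so a constant signal passes through exactly (DC gain 1 to machine
# precision) and startup transients are minimised.  Implemented with
# stats::filter (C speed): FIR part assumes x[i] = x[1] for i <= 0, the
# recursive part is initialised at the matching steady-state output.
lfilter_ss <- function(b, a, x) {
  nb <- length(b); na_ <- length(a)
  x0 <- x[1L]
  y0 <- x0 * sum(b) / sum(a)
  xx <- if (nb > 1L) c(rep(x0, nb - 1L), x) else x
  u <- as.numeric(stats::filter(xx, b, method = "convolution", sides = 1))
  u <- u[(nb - 1L) + seq_along(x)]
  if (na_ > 1L)
    as.numeric(stats::filter(u, -a[-1L], method = "recursive",
                             init = rep(y0, na_ - 1L)))
  else u
}

# One zero-phase (forward + backward) pass with odd-reflection edge padding
# of 3 * order samples at each end.
zero_phase_pass <- function(b, a, x, pad) {
  n <- length(x)
  if (n <= pad)
    gs_parameter_error(sprintf(
      "signal too short for zero-phase padding: need more than %d samples, got %d",
      pad, n))
  left  <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n]  - x[seq(n - 1L, n - pad)]
  y <- lfilter_ss(b, a, c(left, x, right))
  y <- rev(lfilter_ss(b, a, rev(y)))
  y[pad + seq_len(n)]
}

#' Butterworth low-pass filtering of a sampled signal
#'
#' Applies the Butterworth stage described by `spec` to a signal.  Each
#' pass is forward+backward when `spec$bidirectional`, giving zero net
#' phase shift (no event-latency bias); edges are handled by odd
#' (point-mirrored) reflection padding of `3 * order` samples per end, so
#' the signal must be longer than `3 * order` samples.  Output length
#' equals input length and DC gain is exactly 1.
#'
#' @param x a [sampled_signal()].
#' @param spec a [filter_spec()].
#' @return Filtered [sampled_signal()] with unchanged clock and units.
#' @export
butterworth_lowpass <- function(x, spec) {
  stopifnot(is_sampled_signal(x), inherits(spec, "filter_spec"))
  nyquist <- x$sampling_rate / 2
  if (spec$cutoff_hz >= nyquist)
    gs_parameter_error(sprintf(
      "cutoff %g Hz is at or above the Nyquist frequency %g Hz",
      spec$cutoff_hz, nyquist))
  bf <- signal::butter(spec$order, spec$cutoff_hz / nyquist, type = "low")
  b <- bf$b; a <- bf$a
  pad <- 3L * spec$order
  v <- x$values
  for (p in seq_len(spec$passes)) {
    v <- if (spec$bidirectional) zero_phase_pass(b, a, v, pad)
         else lfilter_ss(b, a, v)
  }
  signal_with_values(x, v)
}

#' Analytic magnitude response of the digital Butterworth stage
#'
#' Exact discrete-time (bilinear-transform) magnitude response of the
#' filter stage described by `spec` at frequency `f_hz` for sampling rate
#' `fs_hz`, accounting for bidirectional application (magnitude squared
#' per pass) and the number of cascaded passes.  Used as the closed-form
#' oracle for attenuation tests.
#'
#' @param spec a [filter_spec()].
#' @param f_hz frequency at which to evaluate the response (Hz).
#' @param fs_hz sampling rate of the hypothetical signal (Hz).
#' @return Gain (dimensionless, 1 at DC).
#' @export
butterworth_gain <- function(spec, f_hz, fs_hz) {
  ratio <- tan(pi * f_hz / fs_hz) / tan(pi * spec$cutoff_hz / fs_hz)
  one_way <- 1 / sqrt(1 + ratio^(2 * spec$order))
  per_pass <- if (spec$bidirectional) one_way^2 else one_way
  per_pass^spec$passes
}

# --- elementwise stages -----------------------------------------------------

#' Min-max normalization
#'
#' Linearly rescales a signal so its minimum maps to 0 and its maximum to
#' 1.  A constant signal has no range and raises a degenerate-signal
#' error rather than returning NaN.
#'
#' @param x a [sampled_signal()] or plain numeric vector.
#' @return Same type as the input, dimensionless, in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (is_sampled_signal(x))
    return(signal_with_values(x, minmax_normalize(x$values), units = ""))
  lo <- min(x); hi <- max(x)
  if (hi <= lo)
    gs_degenerate_error("constant signal: min-max normalization undefined")
  (x - lo) / (hi - lo)
}

#' Centered running median
#'
#' Running median with an odd window; at the edges the window shrinks
#' symmetrically (no padding, no invented boundary values), so the output
#' has the input's length.
#'
#' @param x a [sampled_signal()] or numeric vector.
#' @param window odd integer window width >= 3.
#' @return Same type as the input.
#' @export
median_filter <- function(x, window = 5L) {
  if (is_sampled_signal(x))
    return(signal_with_values(x, median_filter(x$values, window)))
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L)
    gs_parameter_error("'window' must be an odd integer >= 3")
  n <- length(x)
  h <- (window - 1L) %/% 2L
  if (n >= window) {
    y <- as.numeric(stats::runmed(x, window, endrule = "keep"))
    edge <- c(seq_len(h), seq(n - h + 1L, n))
  } else {
    y <- x
    edge <- seq_len(n)
  }
  for (i in edge) {
    r <- min(i - 1L, n - i, h)
    y[i] <- stats::median(x[(i - r):(i + r)])
  }
  y
}

#' Heel-trajectory preprocessing cascade
#'
#' The smoothing chain applied to the vertical heel coordinate before
#' event detection: min-max normalization, then a 5-sample centered
#' median filter, then a cascade of two 4th-order 3 Hz bidirectional
#' Butterworth low-pass filters.  The median stage runs before the
#' low-pass so an isolated tracking spike is removed outright instead of
#' being smeared across neighbouring samples.  Filtering happens
#' after normalization, so ringing may push a few samples slightly outside
#' `[0, 1]`; they are deliberately not clamped (clamping would distort the
#' slopes the contact detector relies on).
#'
#' @param heel vertical heel coordinate as [sampled_signal()], nominally
#'   60 Hz (a differing rate triggers a warning, not an error).
#' @param spec Butterworth stage, default [heel_cascade_spec()].
#' @param median_window median-filter width, default 5.
#' @return Dimensionless preprocessed [sampled_signal()].
#' @export
heel_preprocess <- function(heel, spec = heel_cascade_spec(),
                            median_window = 5L) {
  stopifnot(is_sampled_signal(heel))
  if (abs(heel$sampling_rate - 60) > 1e-6)
    warning(sprintf("heel sampling rate is %g Hz (pipeline tuned for 60 Hz)",
                    heel$sampling_rate), call. = FALSE)
  out <- minmax_normalize(heel)
  out <- median_filter(out, median_window)
  butterworth_lowpass(out, spec)
}

#' vGRF preprocessing
#'
#' Low-pass filters a vertical force channel with a 4th-order 30 Hz
#' Butterworth filter, applied bidirectionally so loading-onset latency is
#' not biased.  Units (newtons) are preserved.
#'
#' @param vgrf vertical force channel as [sampled_signal()].
#' @param spec Butterworth stage, default [force_lowpass_spec()].
#' @return Filtered [sampled_signal()].
#' @export
force_preprocess <- function(vgrf, spec = force_lowpass_spec()) {
  stopifnot(is_sampled_signal(vgrf))
  butterworth_lowpass(vgrf, spec)
}
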