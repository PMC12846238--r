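#' Detector configurations
#'
#' `heel_detector_config()` parameterises the adaptive heel-contact
#' threshold: with `gmin` the global minimum of the preprocessed heel
#' trace and `post_max` its maximum after the stabilization period,
#' `threshold = (post_max - gmin) * threshold_factor + gmin`.  The factor
#' is 0.6 for single-leg tasks and 0.2 for bilateral tasks.  The
#' stabilization period (default 30 samples, 0.5 s at 60 Hz) excludes
#' setup transients at the start of the recording from the baseline
#' maximum.
#'
#' `force_detector_config()` parameterises the loading-onset threshold:
#' `threshold = baseline + sd * threshold_factor`, with `baseline` the
#' mean of the first `baseline_samples` samples (default 10) and `sd` the
#' population standard deviation of the whole trace (`sd_scope =
#' "signal"`, the default) or of the baseline segment only (`sd_scope =
#' "baseline"`).
#'
#' @param threshold_factor dimensionless factor in (0, 1) for the heel
#'   detector, or > 0 for the force detector (default 0.1).
#' @param stabilization_samples samples excluded from the start of the
#'   heel trace before taking the post-stabilization maximum.
#' @param baseline_samples number of initial resting samples averaged
#'   into the force baseline (>= 2).
#' @param sd_scope which segment the standard deviation is computed over.
#' @return A `heel_detector_config` / `force_detector_config` object.
#' @export
heel_detector_config <- function(threshold_factor = 0.2,
                                 stabilization_samples = 30L) {
  if (!is.numeric(threshold_factor) || length(threshold_factor) != 1L ||
      threshold_factor <= 0 || threshold_factor >= 1)
    gs_parameter_error("'threshold_factor' must lie strictly between 0 and 1")
  stabilization_samples <- as.integer(stabilization_samples)
  if (is.na(stabilization_samples) || stabilization_samples < 0L)
    gs_parameter_error("'stabilization_samples' must be a non-negative integer")
  structure(list(threshold_factor = as.numeric(threshold_factor),
                 stabilization_samples = stabilization_samples),
            class = "heel_detector_config")
}

#' @rdname heel_detector_config
#' @export
force_detector_config <- function(baseline_samples = 10L,
                                  threshold_factor = 0.1,
                                  sd_scope = c("signal", "baseline")) {
  baseline_samples <- as.integer(baseline_samples)
  if (is.na(baseline_samples) || baseline_samples < 2L)
    gs_parameter_error("'baseline_samples' must be an integer >= 2")
  if (!is.numeric(threshold_factor) || length(threshold_factor) != 1L ||
      threshold_factor <= 0)
    gs_parameter_error("'threshold_factor' must be > 0")
  structure(list(baseline_samples = baseline_samples,
                 threshold_factor = as.numeric(threshold_factor),
                 sd_scope = match.arg(sd_scope)),
            class = "force_detector_config")
}

# Population (divide-by-n) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Detected event
#'
#' Result of a detector: the 1-based sample index of the first qualifying
#' threshold crossing, its time on the source signal's own clock, and the
#' threshold/baseline values that produced it (kept for provenance and
#' report serialization, where indices are written 0-based).
#'
#' @param index 1-based sample index in the source signal.
#' @param signal the source [sampled_signal()].
#' @param threshold_value,baseline_value detector internals, in the
#'   signal's units.
#' @param detector `"heel_contact"` or `"force_onset"`.
#' @return An `event_detection` object with fields `index`, `time_s`,
#'   `threshold_value`, `baseline_value`, `detector`.
#' @export
event_detection <- function(index, signal, threshold_value, baseline_value,
                            detector = c("heel_contact", "force_onset")) {
  detector <- match.arg(detector)
  structure(list(index = as.integer(index),
                 time_s = sample_time(signal, index),
                 threshold_value = threshold_value,
                 baseline_value = baseline_value,
                 detector = detector),
            class = "event_detection")
}

#' @export
print.event_detection <- function(x, ...) {
  cat(sprintf("<event_detection> %s at sample %d (t = %.4f s), threshold %.6g (baseline %.6g)\n",
              x$detector, x$index, x$time_s, x$threshold_value,
              x$baseline_value))
  invisible(x)
}

# Indices of local minima of v: first-difference sign change from - to +,
# with plateaus (zero differences) resolved to the LAST sample of the
# plateau, so the ascent begins immediately after the returned index.
local_minima <- function(v) {
  d <- sign(diff(v))
  nz <- which(d != 0)
  if (length(nz) < 2L) return(integer())
  ds <- d[nz]
  k <- which(ds[-length(ds)] < 0 & ds[-1L] > 0)
  nz[k + 1L]
}

#' Heel-contact detection
#'
#' Detects the heel-contact instant on a preprocessed (dimensionless)
#' heel trace as the first sample that (a) lies after a local minimum of
#' the trace, (b) is on an ascending portion (`v[i] > v[i-1]`), and
#' (c) crosses the adaptive threshold from below
#' (`v[i] > threshold >= v[i-1]`).  The threshold is
#' `(post-stabilization maximum - global minimum) * factor + global
#' minimum`; see [heel_detector_config()].
#'
#' @param heel preprocessed heel trace (see [heel_preprocess()]).
#' @param cfg a [heel_detector_config()].
#' @return An [event_detection()] with `detector = "heel_contact"`.
#'   Signals a no-event error (class `grfsync_no_event_error`, carrying
#'   the computed threshold) when no qualifying crossing exists, and a
#'   degenerate-signal error when the post-stabilization maximum does not
#'   exceed the global minimum.
#' @export
detect_heel_contact <- function(heel, cfg = heel_detector_config()) {
  stopifnot(is_sampled_signal(heel), inherits(cfg, "heel_detector_config"))
  v <- heel$values
  n <- length(v)
  s <- cfg$stabilization_samples
  if (n <= s + 2L)
    gs_parameter_error(sprintf(
      "heel trace too short: %d samples with %d stabilization samples", n, s))
  gmin <- min(v)
  post_max <- max(v[(s + 1L):n])
  baseline <- post_max - gmin
  if (baseline <= 0)
    gs_degenerate_error("degenerate heel baseline: post-stabilization maximum does not exceed the global minimum")
  thr <- baseline * cfg$threshold_factor + gmin

  lm <- local_minima(v)
  if (!length(lm))
    gs_no_event_error("no local minimum followed by an ascent in the heel trace",
                      threshold_value = thr, baseline_value = baseline)
  j0 <- lm[1L]
  idx <- seq(j0 + 1L, n)
  hit <- v[idx] > v[idx - 1L] & v[idx] > thr & v[idx - 1L] <= thr
  if (!any(hit))
    gs_no_event_error("no ascending threshold crossing after a local minimum",
                      threshold_value = thr, baseline_value = baseline)
  i <- idx[which(hit)[1L]]
  event_detection(i, heel, thr, baseline, "heel_contact")
}

#' Force-onset detection
#'
#' Detects the onset of vertical loading on a (filtered) vGRF trace as
#' the first sample after the resting baseline segment that strictly
#' exceeds `baseline + sd * threshold_factor`; see
#' [force_detector_config()].  A constant trace has `sd = 0`, an
#' unexceedable threshold, and raises a no-event error.
#'
#' @param vgrf preprocessed force trace (see [force_preprocess()]).
#' @param cfg a [force_detector_config()].
#' @return An [event_detection()] with `detector = "force_onset"`.
#' @export
detect_force_onset <- function(vgrf, cfg = force_detector_config()) {
  stopifnot(is_sampled_signal(vgrf), inherits(cfg, "force_detector_config"))
  v <- vgrf$values
  n <- length(v)
  nb <- cfg$baseline_samples
  if (n <= nb)
    gs_parameter_error(sprintf(
      "force trace too short: %d samples with %d baseline samples", n, nb))
  baseline <- mean(v[seq_len(nb)])
  s <- switch(cfg$sd_scope,
              signal = sd_pop(v),
              baseline = sd_pop(v[seq_len(nb)]))
  thr <- baseline + s * cfg$threshold_factor
  idx <- seq(nb + 1L, n)
  hit <- v[idx] > thr
  if (!any(hit))
    gs_no_event_error("no force sample exceeds the adaptive onset threshold",
                      threshold_value = thr, baseline_value = baseline)
  i <- idx[which(hit)[1L]]
  event_detection(i, vgrf, thr, baseline, "force_onset")
}

#' Preliminary-step quality-control flag
#'
#' Movement trials sometimes contain an extra step onto the platform
#' before the target movement; the resulting transient force peak makes
#' the onset detector fire prematurely.  This advisory check segments the
#' vGRF into loading episodes — runs above the onset threshold, merged
#' when the signal fails to stay back under the threshold for at least
#' `quiet_gap_s` — and flags the trial when at least one episode precedes
#' the final one.  The start of the last episode is reported as the
#' candidate alternative onset so the user can re-run with a manual
#' override.
#'
#' @param vgrf the preprocessed force trace the onset was detected on.
#' @param onset the [event_detection()] from [detect_force_onset()]
#'   (supplies threshold and baseline).
#' @param quiet_gap_s minimum quiet time (s) separating two episodes.
#' @param min_episode_s episodes shorter than this are treated as noise
#'   and ignored.
#' @return A list with `extra_step` (logical), `n_episodes`,
#'   `alt_onset_index`, `alt_onset_time_s`, and the parameters used.
#' @export
detect_extra_step <- function(vgrf, onset, quiet_gap_s = 0.25,
                              min_episode_s = 0.05) {
  stopifnot(is_sampled_signal(vgrf), inherits(onset, "event_detection"))
  v <- vgrf$values
  fs <- vgrf$sampling_rate
  above <- v > onset$threshold_value
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ep_start <- starts[r$values]
  ep_end <- ends[r$values]
  # merge episodes separated by a quiet spell shorter than quiet_gap_s
  if (length(ep_start) > 1L) {
    gap <- (ep_start[-1L] - ep_end[-length(ep_end)] - 1L) / fs
    keep_break <- gap >= quiet_gap_s
    grp <- cumsum(c(TRUE, keep_break))
    ep_start <- tapply(ep_start, grp, min)
    ep_end <- tapply(ep_end, grp, max)
  }
  dur <- (ep_end - ep_start + 1L) / fs
  real <- dur >= min_episode_s
  ep_start <- ep_start[real]; ep_end <- ep_end[real]
  n_ep <- length(ep_start)
  flag <- n_ep >= 2L
  alt <- if (n_ep >= 1L) as.integer(ep_start[n_ep]) else NA_integer_
  list(extra_step = flag,
       n_episodes = n_ep,
       alt_onset_index = alt,
       alt_onset_time_s = if (is.na(alt)) NA_real_ else sample_time(vgrf, alt),
       quiet_gap_s = quiet_gap_s,
       min_episode_s = min_episode_s)
}
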