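#' Signed temporal offset between the two detected events
#'
#' `offset_s = force_event$time_s - heel_event$time_s`, each on its own
#' recording clock.  Negative values mean the force recording's clock is
#' ahead: the loading onset appears earlier on the force clock than the
#' heel contact does on the kinematic clock.
#'
#' @param heel_event heel-contact [event_detection()].
#' @param force_event force-onset [event_detection()].
#' @return Offset in seconds (signed).
#' @export
compute_offset <- function(heel_event, force_event) {
  stopifnot(inherits(heel_event, "event_detection"),
            inherits(force_event, "event_detection"))
  force_event$time_s - heel_event$time_s
}

#' Re-time the force stream onto the kinematic clock
#'
#' Shifting is a clock correction, not a resample: the samples are left
#' untouched and only `start_time` is adjusted by `-offset_s`, so that the
#' force-onset instant, read on the corrected clock, coincides exactly
#' with the heel-contact instant.  Any common-grid resampling is done
#' explicitly afterwards with [resample_signal()].
#'
#' @param vgrf force [sampled_signal()].
#' @param offset_s signed offset from [compute_offset()].
#' @return The same signal on the corrected clock.
#' @export
shift_force <- function(vgrf, offset_s) {
  stopifnot(is_sampled_signal(vgrf))
  sampled_signal(vgrf$values, vgrf$sampling_rate,
                 vgrf$start_time - offset_s, vgrf$label, vgrf$units)
}

#' Resample a signal onto a uniform grid at a target rate
#'
#' Linear interpolation onto a uniform grid spanning exactly the same
#' time interval as the input.  Both endpoints are preserved exactly; to
#' keep them on the grid the actual output rate is the closest achievable
#' to `target_rate` (`(n_out - 1) / span`), which is exact whenever the
#' span is an integer number of target periods.
#'
#' @param x a [sampled_signal()] with at least 2 samples.
#' @param target_rate target sampling rate in Hz (> 0).
#' @return Resampled [sampled_signal()].
#' @export
resample_signal <- function(x, target_rate) {
  stopifnot(is_sampled_signal(x))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    gs_parameter_error("'target_rate' must be a single positive number")
  if (length(x$values) < 2L)
    gs_parameter_error("cannot resample a single-sample signal")
  t <- signal_times(x)
  span <- t[length(t)] - t[1L]
  n_out <- max(2L, as.integer(round(span * target_rate)) + 1L)
  new_t <- seq(t[1L], t[length(t)], length.out = n_out)
  vals <- stats::approx(t, x$values, xout = new_t)$y
  sampled_signal(vals, (n_out - 1L) / span, t[1L], x$label, x$units)
}

#' Express a signal on the 0-100% movement-cycle scale
#'
#' Linear interpolation of the signal at `cycle_points` equally spaced
#' instants from `cycle_start_s` (0%) to `cycle_end_s` (100%), both of
#' which must lie within the signal's time span.
#'
#' @param x a [sampled_signal()].
#' @param cycle_start_s,cycle_end_s cycle bounds in seconds on the
#'   signal's clock, `cycle_end_s > cycle_start_s`.
#' @param cycle_points number of output points (default 101: 0-100% at
#'   1% steps).
#' @return Numeric vector of length `cycle_points`.
#' @export
time_normalize <- function(x, cycle_start_s, cycle_end_s,
                           cycle_points = 101L) {
  stopifnot(is_sampled_signal(x))
  cycle_points <- as.integer(cycle_points)
  if (is.na(cycle_points) || cycle_points < 2L)
    gs_parameter_error("'cycle_points' must be an integer >= 2")
  if (!(cycle_end_s > cycle_start_s))
    gs_parameter_error("'cycle_end_s' must exceed 'cycle_start_s'")
  tol <- 1e-9 / x$sampling_rate
  if (cycle_start_s < x$start_time - tol ||
      cycle_end_s > signal_end_time(x) + tol)
    gs_parameter_error(sprintf(
      "cycle bounds [%.4f, %.4f] s outside the signal span [%.4f, %.4f] s",
      cycle_start_s, cycle_end_s, x$start_time, signal_end_time(x)))
  grid <- seq(cycle_start_s, cycle_end_s, length.out = cycle_points)
  stats::approx(signal_times(x), x$values, xout = grid, rule = 2)$y
}

# --- whole-trial pipeline ---------------------------------------------------

sync_failure <- function(trial, reason, reason_class, provenance = list()) {
  structure(list(success = FALSE, task = trial$task,
                 reason = reason, reason_class = reason_class,
                 offset_s = NA_real_, qc = list(extra_step = FALSE),
                 provenance = provenance),
            class = "sync_result")
}

#' Synchronize one trial
#'
#' Runs the full event-based pipeline on a [trial_record()]:
#' heel preprocessing and contact detection on the evaluated heel
#' channel(s); force preprocessing and onset detection on the active
#' platform; signed offset; clock correction of the force stream;
#' optional resampling; preliminary-step QC; and 0-100% cycle
#' normalization of the preprocessed heel and aligned force curves (cycle
#' start = heel contact, cycle end = end of the shorter stream unless
#' overridden).
#'
#' In bilateral trials both heels are detected and the earlier contact is
#' used (ties resolved to the left channel).  Detection failures
#' (no-event, degenerate signal) are data, not crashes: they return a
#' failed `sync_result` carrying the reason, which [batch_synchronize()]
#' counts into its success rate.
#'
#' @param trial a [trial_record()].
#' @param config a [run_config()].
#' @param cycle_start_s,cycle_end_s optional explicit cycle bounds
#'   (seconds, kinematic clock) overriding the defaults.
#' @return A `sync_result`: `success`, `offset_s`, `heel_event`,
#'   `force_event`, `heel_events` (per analysed side), `shifted_vgrf`,
#'   `cycle_curves`, `qc`, `provenance`.
#' @export
synchronize_trial <- function(trial, config = run_config(),
                              cycle_start_s = NULL, cycle_end_s = NULL) {
  stopifnot(is_trial_record(trial), inherits(config, "run_config"))
  prov <- list(config = config_provenance(config),
               task = trial$task,
               laterality_mode = trial$laterality_mode,
               active_platform = trial$active_platform,
               index_base = 0L, time_units = "s")

  result <- tryCatch({
    sides <- switch(trial$laterality_mode,
                    bilateral = c("left", "right"),
                    single_leg = trial$evaluated_side)
    sides <- sides[vapply(sides, function(s)
      !is.null(trial[[paste0("heel_", s)]]), logical(1))]
    if (!length(sides))
      gs_parameter_error("no heel channel available for the evaluated side")

    hcfg <- heel_cfg_from(config, trial$laterality_mode)
    heel_pre <- lapply(sides, function(s)
      heel_preprocess(trial[[paste0("heel_", s)]],
                      config$heel_filter, config$median_window))
    names(heel_pre) <- sides
    heel_events <- lapply(heel_pre, detect_heel_contact, cfg = hcfg)
    pick <- which.min(vapply(heel_events, function(e) e$time_s, numeric(1)))
    heel_event <- heel_events[[pick]]
    heel_side <- sides[pick]

    fcfg <- force_cfg_from(config)
    vgrf_raw <- trial$vgrf[[trial$active_platform]]
    vgrf_pre <- force_preprocess(vgrf_raw, config$force_filter)
    force_event <- detect_force_onset(vgrf_pre, fcfg)
    qc <- detect_extra_step(vgrf_pre, force_event,
                            config$quiet_gap_s, config$min_episode_s)

    offset_s <- compute_offset(heel_event, force_event)
    shifted <- shift_force(vgrf_pre, offset_s)
    if (!is.null(config$resample_hz))
      shifted <- resample_signal(shifted, config$resample_hz)

    cs <- if (is.null(cycle_start_s)) heel_event$time_s else cycle_start_s
    ce <- if (is.null(cycle_end_s))
      min(signal_end_time(heel_pre[[1L]]), signal_end_time(shifted))
    else cycle_end_s
    curves <- c(
      lapply(heel_pre, time_normalize, cycle_start_s = cs,
             cycle_end_s = ce, cycle_points = config$cycle_points),
      list(vgrf = time_normalize(shifted, cs, ce, config$cycle_points)))
    names(curves)[seq_along(sides)] <- paste0("heel_", sides)

    prov$heel_side <- heel_side
    prov$heel_threshold <- heel_event$threshold_value
    prov$heel_baseline <- heel_event$baseline_value
    prov$heel_index <- heel_event$index
    prov$force_threshold <- force_event$threshold_value
    prov$force_baseline <- force_event$baseline_value
    prov$force_index <- force_event$index
    prov$cycle_start_s <- cs
    prov$cycle_end_s <- ce

    structure(list(success = TRUE, task = trial$task,
                   offset_s = offset_s,
                   heel_event = heel_event, heel_events = heel_events,
                   heel_side = heel_side,
                   force_event = force_event,
                   shifted_vgrf = shifted,
                   cycle_curves = curves,
                   qc = qc,
                   provenance = prov),
              class = "sync_result")
  },
  grfsync_no_event_error = function(e)
    sync_failure(trial, conditionMessage(e), "no_event", prov),
  grfsync_degenerate_error = function(e)
    sync_failure(trial, conditionMessage(e), "degenerate_signal", prov))
  result
}

#' @export
print.sync_result <- function(x, ...) {
  if (isTRUE(x$success))
    cat(sprintf("<sync_result> task=%s: offset %.4f s (heel %s @ %.4f s, force @ %.4f s)%s\n",
                x$task, x$offset_s, x$heel_side, x$heel_event$time_s,
                x$force_event$time_s,
                if (isTRUE(x$qc$extra_step)) " [QC: extra step]" else ""))
  else
    cat(sprintf("<sync_result> task=%s: FAILED (%s: %s)\n",
                x$task, x$reason_class, x$reason))
  invisible(x)
}

#' Synchronize a batch of trials
#'
#' Applies [synchronize_trial()] to every trial and aggregates the
#' outcomes: the success rate (failed detections are counted, not
#' raised), per-trial results with failure reasons, and a per-task table
#' of offset mean and SD over the successful trials.
#'
#' @param trials list of [trial_record()] objects.
#' @param config a [run_config()].
#' @return A `sync_batch` list: `results`, `n_trials`, `n_success`,
#'   `success_rate` (fraction), `success_pct`, `failures` (data frame of
#'   trial, task, reason), `offsets_s`, `task_table` (data frame task, n,
#'   mean_offset_s, sd_offset_s).
#' @export
batch_synchronize <- function(trials, config = run_config()) {
  if (!is.list(trials) || !length(trials))
    gs_parameter_error("'trials' must be a non-empty list of trial_record")
  results <- lapply(trials, synchronize_trial, config = config)
  ok <- vapply(results, function(r) isTRUE(r$success), logical(1))
  tasks <- vapply(results, function(r) r$task, character(1))
  offsets <- vapply(results, function(r) r$offset_s, numeric(1))

  failures <- data.frame(
    trial = which(!ok),
    task = tasks[!ok],
    reason_class = vapply(results[!ok], function(r) r$reason_class, character(1)),
    reason = vapply(results[!ok], function(r) r$reason, character(1)),
    stringsAsFactors = FALSE)

  tt <- if (any(ok)) {
    sp <- split(offsets[ok], tasks[ok])
    data.frame(task = names(sp),
               n = vapply(sp, length, integer(1)),
               mean_offset_s = vapply(sp, mean, numeric(1)),
               sd_offset_s = vapply(sp, function(z)
                 if (length(z) > 1L) stats::sd(z) else NA_real_, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(task = character(), n = integer(),
               mean_offset_s = numeric(), sd_offset_s = numeric())
  }

  structure(list(results = results,
                 n_trials = length(trials),
                 n_success = sum(ok),
                 success = ok,
                 success_rate = mean(ok),
                 success_pct = 100 * mean(ok),
                 failures = failures,
                 offsets_s = offsets,
                 task_table = tt),
            class = "sync_batch")
}

#' @export
print.sync_batch <- function(x, ...) {
  cat(sprintf("<sync_batch> %d/%d trials synchronized (%.1f%%)\n",
              x$n_success, x$n_trials, x$success_pct))
  if (nrow(x$task_table)) {
    cat("Per-task offsets (s):\n")
    print(x$task_table, row.names = FALSE)
  }
  if (nrow(x$failures)) {
    cat("Failures:\n")
    print(x$failures, row.names = FALSE)
  }
  invisible(x)
}
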