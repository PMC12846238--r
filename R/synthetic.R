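#' Synthetic-trial specification
#'
#' Parameterises a simulated movement trial with known ground truth: a
#' vertical heel trajectory (elevated plateau, raised-cosine descent
#' reaching its minimum at `contact_time_s`, brisk partial rebound after
#' contact) on the kinematic clock, and a vGRF trace (quiescent baseline,
#' raised-cosine rise to body weight at contact, slow squat-cycle
#' loading oscillation) on a force clock offset from the kinematic clock
#' by exactly `true_offset_s`.  The physical contact happens once; the
#' two recordings simply time-stamp it differently, which is the
#' situation the synchronization pipeline must undo.
#'
#' The raised-cosine shapes are smooth by construction, so the heel trace
#' has a unique contact minimum and a well-defined ascent, and the timing
#' constants are chosen to mimic a brisk functional-task contact:
#' descent over 0.5 s, heel rebound over 0.08 s to 70% of the drop
#' height, loading rise over 0.2 s; with the pipeline's filters these give
#' the two detectors matched latencies, so the recovered offset is an
#' unbiased estimate of the injected one.
#'
#' @param true_offset_s injected clock offset in seconds (negative: the
#'   force clock runs ahead, the convention observed in uncoupled
#'   camera/platform recordings).
#' @param fs_kin,fs_force sampling rates (Hz), defaults 60 and 1000.
#' @param duration_s trial length (s) on both clocks.
#' @param contact_time_s contact instant on the kinematic clock (s).
#' @param body_weight_n plateau vertical force (N); default 608 N
#'   (a 62 kg subject).
#' @param heel_drop_amplitude heel descent amplitude (m).
#' @param heel_base_m heel marker height at ground contact (m).
#' @param descent_s,rise_s,rise_level heel waveform: descent duration,
#'   rebound duration, and rebound level as a fraction of the drop.
#'   `rise_level` defaults to 0.7 for bilateral trials and 0.85 for
#'   single-leg trials so the rebound clears the respective detector
#'   threshold (0.2 / 0.6).
#' @param force_rise_s loading-rise duration (s).
#' @param resting_load_n constant resting force (N) before onset, to
#'   exercise the baseline-mean logic (default 0: unloaded platform).
#' @param noise_sd_kin,noise_sd_force white-noise SD as a fraction of
#'   each channel's range (heel drop / body weight).
#' @param extra_step simulate a preliminary-step force transient before
#'   the main loading (the documented failure mode).
#' @param extra_step_time_s center of the transient on the force clock;
#'   default 0.8 s before the main onset.
#' @param extra_step_peak_n,extra_step_width_s transient peak (N,
#'   default half body weight) and full width (s).
#' @param laterality_mode,task,evaluated_side trial metadata.
#' @param seed integer seed making the trial fully deterministic.
#' @return A `synthetic_trial_spec` list.
#' @export
synthetic_trial_spec <- function(true_offset_s = -1.0,
                                 fs_kin = 60, fs_force = 1000,
                                 duration_s = 7, contact_time_s = 3,
                                 body_weight_n = 608,
                                 heel_drop_amplitude = 0.15,
                                 heel_base_m = 0.02,
                                 descent_s = 0.5, rise_s = 0.08,
                                 rise_level = NULL,
                                 force_rise_s = 0.2,
                                 resting_load_n = 0,
                                 noise_sd_kin = 0.02,
                                 noise_sd_force = 0.02,
                                 extra_step = FALSE,
                                 extra_step_time_s = NULL,
                                 extra_step_peak_n = NULL,
                                 extra_step_width_s = 0.3,
                                 laterality_mode = c("bilateral", "single_leg"),
                                 task = "squat",
                                 evaluated_side = NULL,
                                 seed = 1L) {
  laterality_mode <- match.arg(laterality_mode)
  if (is.null(rise_level))
    rise_level <- if (laterality_mode == "bilateral") 0.7 else 0.85
  if (is.null(evaluated_side))
    evaluated_side <- if (laterality_mode == "bilateral") "both" else "left"
  if (!(contact_time_s > 0 && contact_time_s < duration_s))
    gs_parameter_error("'contact_time_s' must lie inside (0, duration_s)")
  if (fs_kin <= 0 || fs_force <= 0)
    gs_parameter_error("sampling rates must be positive")
  if (noise_sd_kin < 0 || noise_sd_force < 0)
    gs_parameter_error("noise fractions must be >= 0")
  if (contact_time_s - descent_s <= 0)
    gs_parameter_error("descent must start after the recording begins")
  onset_force_clock <- contact_time_s + true_offset_s
  if (onset_force_clock <= 0.05 || onset_force_clock >= duration_s - 0.2)
    gs_parameter_error(
      "force onset (contact_time_s + true_offset_s) must leave a resting baseline and a loaded tail inside the recording")
  if (extra_step) {
    if (is.null(extra_step_time_s))
      extra_step_time_s <- max(extra_step_width_s / 2 + 0.05,
                               onset_force_clock - 0.8)
    if (is.null(extra_step_peak_n))
      extra_step_peak_n <- 0.5 * body_weight_n
    if (extra_step_time_s + extra_step_width_s / 2 >= onset_force_clock)
      gs_parameter_error("the preliminary step must end before the main loading onset")
    if (extra_step_time_s - extra_step_width_s / 2 <= 0.02)
      gs_parameter_error("the preliminary step must start after the recording begins")
  }
  structure(list(
    true_offset_s = true_offset_s, fs_kin = fs_kin, fs_force = fs_force,
    duration_s = duration_s, contact_time_s = contact_time_s,
    body_weight_n = body_weight_n,
    heel_drop_amplitude = heel_drop_amplitude, heel_base_m = heel_base_m,
    descent_s = descent_s, rise_s = rise_s, rise_level = rise_level,
    force_rise_s = force_rise_s, resting_load_n = resting_load_n,
    noise_sd_kin = noise_sd_kin, noise_sd_force = noise_sd_force,
    extra_step = isTRUE(extra_step),
    extra_step_time_s = extra_step_time_s,
    extra_step_peak_n = extra_step_peak_n,
    extra_step_width_s = extra_step_width_s,
    laterality_mode = laterality_mode, task = task,
    evaluated_side = evaluated_side, seed = as.integer(seed)),
    class = "synthetic_trial_spec")
}

# Noiseless heel profile (metres) at kinematic-clock times t.
heel_profile <- function(t, spec) {
  base <- spec$heel_base_m
  A <- spec$heel_drop_amplitude
  tc <- spec$contact_time_s
  D <- spec$descent_s
  R <- spec$rise_s
  L <- spec$rise_level
  h <- rep(base + A, length(t))
  desc <- t >= tc - D & t < tc
  h[desc] <- base + A * 0.5 * (1 + cos(pi * (t[desc] - (tc - D)) / D))
  post <- t >= tc
  x <- pmin((t[post] - tc) / R, 1)
  h[post] <- base + L * A * 0.5 * (1 - cos(pi * x))
  h
}

# Noiseless vGRF profile (newtons) at force-clock times t.
force_profile <- function(t, spec) {
  bw <- spec$body_weight_n
  on <- spec$contact_time_s + spec$true_offset_s
  Rf <- spec$force_rise_s
  f <- rep(spec$resting_load_n, length(t))
  rise <- t >= on & t < on + Rf
  f[rise] <- spec$resting_load_n +
    bw * 0.5 * (1 - cos(pi * (t[rise] - on) / Rf))
  loaded <- t >= on + Rf
  f[loaded] <- spec$resting_load_n + bw +
    0.25 * bw * sin(2 * pi * 0.4 * (t[loaded] - on - Rf))
  if (spec$extra_step) {
    c0 <- spec$extra_step_time_s
    w <- spec$extra_step_width_s
    bump <- abs(t - c0) < w / 2
    f[bump] <- f[bump] + spec$extra_step_peak_n *
      0.5 * (1 + cos(2 * pi * (t[bump] - c0) / w))
  }
  f
}

#' Generate one synthetic trial with ground truth
#'
#' Builds the [trial_record()] described by a [synthetic_trial_spec()],
#' fully deterministic given `spec$seed` (noise is drawn inside a scoped
#' RNG so the caller's random state is untouched).  Bilateral trials get
#' two heel channels with the same contact and independent noise;
#' single-leg trials give the contralateral heel a gentle sway with no
#' ground contact.
#'
#' @param spec a [synthetic_trial_spec()].
#' @return List with `trial` (a [trial_record()]) and `truth`: the exact
#'   injected offset, contact/onset times on their own clocks, the
#'   nearest sample indices, and the extra-step window if present.
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  withr::with_seed(spec$seed, {
    n_kin <- as.integer(round(spec$duration_s * spec$fs_kin)) + 1L
    t_kin <- (seq_len(n_kin) - 1) / spec$fs_kin
    h <- heel_profile(t_kin, spec)
    noise_k <- spec$noise_sd_kin * spec$heel_drop_amplitude
    mk_heel <- function(label)
      sampled_signal(h + stats::rnorm(n_kin, 0, noise_k),
                     spec$fs_kin, 0, label, "m")
    if (spec$laterality_mode == "bilateral") {
      heel_left <- mk_heel("LHeel")
      heel_right <- mk_heel("RHeel")
    } else {
      sway <- spec$heel_base_m + spec$heel_drop_amplitude *
        (0.6 + 0.1 * sin(2 * pi * 0.3 * t_kin)) +
        stats::rnorm(n_kin, 0, noise_k)
      if (spec$evaluated_side == "left") {
        heel_left <- mk_heel("LHeel")
        heel_right <- sampled_signal(sway, spec$fs_kin, 0, "RHeel", "m")
      } else {
        heel_right <- mk_heel("RHeel")
        heel_left <- sampled_signal(sway, spec$fs_kin, 0, "LHeel", "m")
      }
    }

    n_f <- as.integer(round(spec$duration_s * spec$fs_force)) + 1L
    t_f <- (seq_len(n_f) - 1) / spec$fs_force
    fvals <- force_profile(t_f, spec) +
      stats::rnorm(n_f, 0, spec$noise_sd_force * spec$body_weight_n)
    vgrf <- sampled_signal(fvals, spec$fs_force, 0, "Fz1", "N")

    trial <- trial_record(heel_left = heel_left, heel_right = heel_right,
                          vgrf = list(plate1 = vgrf),
                          task = spec$task,
                          laterality_mode = spec$laterality_mode,
                          evaluated_side = spec$evaluated_side,
                          active_platform = "plate1")
    onset_force_clock <- spec$contact_time_s + spec$true_offset_s
    truth <- list(
      true_offset_s = spec$true_offset_s,
      contact_time_s = spec$contact_time_s,
      contact_index_kin = which.min(abs(t_kin - spec$contact_time_s)),
      onset_time_force_clock = onset_force_clock,
      onset_index_force = which(t_f >= onset_force_clock)[1L],
      extra_step = spec$extra_step,
      extra_step_time_s = if (spec$extra_step) spec$extra_step_time_s else NULL,
      seed = spec$seed)
    list(trial = trial, truth = truth)
  })
}

#' Generate a reproducible bank of synthetic trials
#'
#' Draws `n` trials from `base_spec` with selected parameters randomized
#' uniformly over given ranges and an optional fraction of trials
#' corrupted by a preliminary-step transient.  Everything is driven by
#' one seed, so two banks built with the same arguments are identical.
#'
#' @param n number of trials (>= 1).
#' @param base_spec a [synthetic_trial_spec()] providing all fixed
#'   parameters.
#' @param randomize named list of 2-vectors `c(min, max)`; each named
#'   spec field is drawn uniformly per trial.  Default: offsets uniform
#'   in `[-2, 2]` s, contact time uniform in `[2.6, 3.4]` s.
#' @param extra_step_fraction fraction of trials (rounded) given an
#'   extra-step transient, assigned at random positions in the bank.
#' @param seed integer master seed.
#' @return List of `n` elements, each `list(trial, truth)` as returned
#'   by [generate_trial()].
#' @export
generate_bank <- function(n, base_spec = synthetic_trial_spec(),
                          randomize = list(true_offset_s = c(-2, 2),
                                           contact_time_s = c(2.6, 3.4)),
                          extra_step_fraction = 0, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) gs_parameter_error("'n' must be an integer >= 1")
  if (length(randomize)) {
    if (is.null(names(randomize)) || any(!nzchar(names(randomize))))
      gs_parameter_error("'randomize' entries must be named spec fields")
    for (rng in randomize)
      if (!is.numeric(rng) || length(rng) != 2L || rng[2L] < rng[1L])
        gs_parameter_error("each 'randomize' entry must be c(min, max) with max >= min")
  }
  withr::with_seed(as.integer(seed), {
    draws <- lapply(randomize, function(rng)
      stats::runif(n, rng[1L], rng[2L]))
    trial_seeds <- sample.int(.Machine$integer.max, n)
    n_extra <- round(extra_step_fraction * n)
    extra_idx <- if (n_extra > 0L) sample.int(n, n_extra) else integer()
  })
  lapply(seq_len(n), function(i) {
    args <- unclass(base_spec)
    for (nm in names(draws)) args[[nm]] <- draws[[nm]][i]
    args$seed <- trial_seeds[i]
    args$extra_step <- i %in% extra_idx
    args$extra_step_time_s <- NULL
    args$extra_step_peak_n <- NULL
    generate_trial(do.call(synthetic_trial_spec, args))
  })
}
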