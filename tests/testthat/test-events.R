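# The worked piecewise-linear trace (181 samples at 60 Hz): constant 1.0
# through sample 61 (1-based), linear descent reaching 0.0 at sample 121,
# linear ascent reaching 1.0 at sample 181.
vee_trace <- function() {
  c(rep(1, 61), (59:0) / 60, (1:60) / 60)
}

test_that("heel-contact detection matches the closed-form trace", {
  heel <- sampled_signal(vee_trace(), 60)
  cfg <- heel_detector_config(0.2, 30L)
  ev <- detect_heel_contact(heel, cfg)
  # baseline = 1, threshold = 0.2; first sample strictly above 0.2 on the
  # ascent after the minimum at sample 121 (1-based) is sample 134
  expect_equal(ev$baseline_value, 1)
  expect_equal(ev$threshold_value, 0.2)
  expect_identical(ev$index, 134L)
  expect_equal(ev$time_s, 133 / 60)
  expect_identical(ev$index, oracle_heel_contact(heel$values, 0.2, 30L))
  # first-crossing contract
  expect_gt(heel$values[ev$index], ev$threshold_value)
  expect_lte(heel$values[ev$index - 1], ev$threshold_value)

  # single-leg factor 0.6 fires later (threshold monotonicity)
  ev6 <- detect_heel_contact(heel, heel_detector_config(0.6, 30L))
  expect_gt(ev6$index, ev$index)

  expect_error(
    detect_heel_contact(sampled_signal(seq(1, 0, length.out = 120), 60), cfg),
    class = "grfsync_no_event_error")
  expect_error(
    detect_heel_contact(sampled_signal(c(rep(1, 50), seq(1, 0, length.out = 70)), 60),
                        heel_detector_config(0.2, 119L)),
    class = "grfsync_parameter_error")
})

test_that("no-event errors carry the computed threshold", {
  v <- c(rep(1, 40), seq(1, 0.9, length.out = 40), seq(0.9, 0.95, length.out = 40))
  # ascent never exceeds baseline*0.6 + min
  err <- tryCatch(
    detect_heel_contact(sampled_signal(v, 60), heel_detector_config(0.6, 10L)),
    grfsync_no_event_error = function(e) e)
  expect_s3_class(err, "grfsync_no_event_error")
  expect_true(is.numeric(err$threshold_value))
})

test_that("force-onset detection follows the adaptive-threshold rule", {
  ramp <- c(rep(0, 100), seq(0, 700, length.out = 100))
  f <- sampled_signal(ramp, 1000, units = "N")
  ev <- detect_force_onset(f)
  expect_identical(ev$index, oracle_force_onset(ramp))
  expect_equal(ev$baseline_value, 0)

  # constant trace: SD = 0, threshold unexceedable
  expect_error(detect_force_onset(sampled_signal(rep(600, 300), 1000)),
               class = "grfsync_no_event_error")

  # step function: detected at the step
  step <- c(rep(0, 49), rep(700, 100))
  expect_identical(detect_force_onset(sampled_signal(step, 1000))$index, 50L)
})

test_that("detectors agree exactly with the literal loop oracles", {
  set.seed(33)
  n_cases <- 300
  for (k in seq_len(n_cases)) {
    v <- random_detector_signal(sample(60:150, 1), quantize = k %% 2 == 0)
    stab <- sample(0:20, 1)
    factor <- runif(1, 0.1, 0.9)
    got <- tryCatch(
      detect_heel_contact(sampled_signal(v, 60),
                          heel_detector_config(factor, stab))$index,
      grfsync_error = function(e) NA_integer_)
    expect_identical(got, oracle_heel_contact(v, factor, stab))

    scope <- if (k %% 3 == 0) "baseline" else "signal"
    gotf <- tryCatch(
      detect_force_onset(sampled_signal(v, 1000),
                         force_detector_config(10L, 0.1, scope))$index,
      grfsync_error = function(e) NA_integer_)
    expect_identical(gotf, oracle_force_onset(v, 10L, 0.1, scope))
  }
})

test_that("heel threshold factor is monotone on contact-shaped traces", {
  # on a trace with a single valley and a monotone ascent (the detector's
  # domain), a higher threshold factor can only fire later
  set.seed(44)
  t <- (0:240) / 60
  for (k in 1:50) {
    tc <- runif(1, 1.5, 2.5)
    depth <- runif(1, 0.5, 1)
    width <- runif(1, 0.4, 1)
    v <- 1 - depth * exp(-((t - tc) / width)^2)
    idx <- sapply(c(0.1, 0.25, 0.4, 0.6, 0.8), function(f)
      tryCatch(detect_heel_contact(sampled_signal(v, 60),
                                   heel_detector_config(f, 5L))$index,
               grfsync_error = function(e) NA_integer_))
    idx <- idx[!is.na(idx)]
    if (length(idx) > 1) expect_true(all(diff(idx) >= 0))
  }
})

test_that("force onset is translation-equivariant under baseline prepending", {
  # constant-baseline signal, SD over the baseline segment: prepending k
  # baseline-valued samples shifts the detection by exactly k
  base <- c(rep(5, 30), seq(5, 400, length.out = 100))
  cfg <- force_detector_config(10L, 0.1, sd_scope = "baseline")
  i0 <- detect_force_onset(sampled_signal(base, 1000), cfg)$index
  for (k in c(1L, 7L, 25L)) {
    ik <- detect_force_onset(sampled_signal(c(rep(5, k), base), 1000), cfg)$index
    expect_identical(ik, i0 + k)
  }
})

test_that("extra-step QC segments loading episodes correctly", {
  # preliminary bump then sustained loading -> flagged, alt onset at main rise
  g <- generate_trial(quick_spec(extra_step = TRUE, seed = 7))
  f <- force_preprocess(g$trial$vgrf$plate1)
  onset <- detect_force_onset(f)
  qc <- detect_extra_step(f, onset)
  expect_true(qc$extra_step)
  expect_equal(qc$n_episodes, 2L)
  expect_equal(qc$alt_onset_time_s, g$truth$onset_time_force_clock,
               tolerance = 0.05)

  # clean trial -> single episode, no flag
  gc <- generate_trial(quick_spec(seed = 8))
  fc <- force_preprocess(gc$trial$vgrf$plate1)
  qcc <- detect_extra_step(fc, detect_force_onset(fc))
  expect_false(qcc$extra_step)

  # bump that never returns under threshold -> one continuous episode
  v <- c(rep(0, 500), seq(0, 300, length.out = 100), rep(300, 200),
         seq(300, 600, length.out = 100), rep(600, 500))
  fs <- sampled_signal(v, 1000, units = "N")
  on2 <- detect_force_onset(fs)
  qc2 <- detect_extra_step(fs, on2)
  expect_false(qc2$extra_step)
})
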