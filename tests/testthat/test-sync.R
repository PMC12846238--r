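test_that("offset arithmetic and clock shifting follow the sign convention", {
  heel <- sampled_signal(vee_demo <- c(rep(1, 60), 1 - (1:60) / 60, (1:60) / 60), 60)
  mk_event <- function(t, sig) {
    idx <- round((t - sig$start_time) * sig$sampling_rate) + 1L
    event_detection(idx, sig, 0.2, 1, "heel_contact")
  }
  f <- sampled_signal(rep(0, 1000), 1000)
  h2 <- mk_event(2.00, heel)
  f062 <- event_detection(621L, f, 1, 0, "force_onset")  # t = 0.62 s
  expect_equal(compute_offset(h2, f062), -1.38)
  expect_equal(compute_offset(h2, event_detection(2001L,
    sampled_signal(rep(0, 2500), 1000), 1, 0, "force_onset")), 0)
  h1 <- mk_event(1.00, heel)
  f15 <- event_detection(1501L, sampled_signal(rep(0, 2000), 1000), 1, 0, "force_onset")
  expect_equal(compute_offset(h1, f15), 0.5)

  shifted <- shift_force(f, -1.38)
  expect_equal(shifted$start_time, f$start_time + 1.38)
  expect_equal(shifted$values, f$values)
  expect_equal(shift_force(f, 0), f)
})

test_that("re-detecting the onset on the shifted clock lands on heel contact", {
  g <- generate_trial(quick_spec(true_offset_s = -1.2, seed = 5))
  res <- synchronize_trial(g$trial)
  expect_true(res$success)
  onset2 <- detect_force_onset(res$shifted_vgrf)
  expect_equal(onset2$time_s, res$heel_event$time_s, tolerance = 1e-9)
})

test_that("resampling preserves constants, lines and low-frequency content", {
  const <- sampled_signal(rep(4.2, 1001), 1000)
  rc <- resample_signal(const, 60)
  expect_true(all(abs(rc$values - 4.2) < 1e-12))

  ramp <- sampled_signal(seq(0, 10, length.out = 1001), 1000)
  rr <- resample_signal(ramp, 60)
  expect_equal(rr$values, seq(0, 10, length.out = length(rr$values)),
               tolerance = 1e-12)
  expect_equal(rr$values[1], 0)
  expect_equal(rr$values[length(rr$values)], 10)

  t <- seq(0, 2, by = 1e-3)
  sine <- sampled_signal(sin(2 * pi * t), 1000)
  rs <- resample_signal(sine, 60)
  expect_lt(max(abs(rs$values - sin(2 * pi * signal_times(rs)))), 1e-3)

  expect_error(resample_signal(sampled_signal(1, 10), 60),
               class = "grfsync_parameter_error")
})

test_that("time normalization interpolates the cycle onto a fixed grid", {
  ramp <- sampled_signal(seq(0, 10, length.out = 601), 60)
  curve <- time_normalize(ramp, 2, 8, 101L)
  expect_length(curve, 101)
  expect_equal(curve[1], 2)  # ramp(2 s) = 2
  expect_equal(curve, seq(ramp$values[121], ramp$values[481], length.out = 101),
               tolerance = 1e-12)
  const <- sampled_signal(rep(7, 601), 60)
  expect_equal(time_normalize(const, 0, 10, 51L), rep(7, 51))
  expect_error(time_normalize(ramp, -1, 5), class = "grfsync_parameter_error")
  expect_error(time_normalize(ramp, 5, 2), class = "grfsync_parameter_error")
})

test_that("synchronize_trial recovers injected offsets and reports failures as data", {
  g <- generate_trial(quick_spec(true_offset_s = -1.0, noise_sd_kin = 0,
                                 noise_sd_force = 0))
  res <- synchronize_trial(g$trial)
  expect_true(res$success)
  expect_lt(abs(res$offset_s - (-1.0)), 1 / 60)
  expect_named(res$cycle_curves, c("heel_left", "heel_right", "vgrf"))
  expect_true(all(lengths(res$cycle_curves) == 101))
  expect_false(res$qc$extra_step)
  expect_identical(res$provenance$heel_index, res$heel_event$index)

  flat <- g$trial
  flat$heel_left <- sampled_signal(rep(0.02, length(flat$heel_left$values)), 60)
  flat$heel_right <- flat$heel_left
  resf <- suppressWarnings(synchronize_trial(flat))
  expect_false(resf$success)
  expect_identical(resf$reason_class, "degenerate_signal")

  ge <- generate_trial(quick_spec(extra_step = TRUE, seed = 12))
  rese <- synchronize_trial(ge$trial)
  expect_true(rese$success)
  expect_true(rese$qc$extra_step)
  expect_false(is.na(rese$qc$alt_onset_time_s))
})

test_that("offset is equivariant under an added constant clock delay", {
  g <- generate_trial(quick_spec(true_offset_s = -0.5, seed = 9))
  base <- synchronize_trial(g$trial)
  for (d in c(-0.75, 0.4)) {
    delayed <- g$trial
    fsig <- delayed$vgrf$plate1
    delayed$vgrf$plate1 <- sampled_signal(fsig$values, fsig$sampling_rate,
                                          fsig$start_time + d,
                                          fsig$label, fsig$units)
    res <- synchronize_trial(delayed)
    expect_equal(res$offset_s - base$offset_s, d, tolerance = 1e-9)
  }
})

test_that("synchronizing an already-synchronized trial is idempotent", {
  g <- generate_trial(quick_spec(true_offset_s = -1.5, seed = 10))
  first <- synchronize_trial(g$trial)
  realigned <- g$trial
  realigned$vgrf$plate1 <- shift_force(realigned$vgrf$plate1, first$offset_s)
  second <- synchronize_trial(realigned)
  expect_lt(abs(second$offset_s), 1 / 60 + 1e-9)
})

test_that("batch synchronization aggregates successes, failures and offsets", {
  bank <- generate_bank(10, quick_spec(noise_sd_kin = 0, noise_sd_force = 0),
                        randomize = list(), seed = 3)
  trials <- lapply(bank, `[[`, "trial")
  batch <- batch_synchronize(trials)
  expect_equal(batch$success_pct, 100)
  expect_equal(batch$n_success, 10L)
  # noiseless identical trials: offsets all equal the injected -1.0 s
  expect_equal(batch$task_table$mean_offset_s, -1.0, tolerance = 1 / 60)
  expect_lte(batch$task_table$sd_offset_s, 1 / 60)
  expect_error(batch_synchronize(list()), class = "grfsync_parameter_error")
})
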