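test_that("min-max normalization maps range to [0,1] and is idempotent", {
  s <- sampled_signal(c(2, 4, 6), 60)
  expect_equal(minmax_normalize(s)$values, c(0, 0.5, 1))
  expect_error(minmax_normalize(sampled_signal(c(5, 5, 5), 60)),
               class = "grfsync_degenerate_error")
  set.seed(11)
  for (k in 1:20) {
    v <- rnorm(50)
    once <- minmax_normalize(v)
    expect_equal(once, (v - min(v)) / (max(v) - min(v)))
    expect_equal(minmax_normalize(once), once, tolerance = 1e-12)
    expect_equal(range(once), c(0, 1))
  }
})

test_that("Butterworth stages preserve DC, length and parameter contracts", {
  const <- sampled_signal(rep(0.73, 400), 60)
  out <- butterworth_lowpass(const, heel_cascade_spec())
  expect_equal(out$values, rep(0.73, 400), tolerance = 1e-9)
  expect_length(out$values, 400)

  f600 <- sampled_signal(rep(600, 3000), 1000, label = "Fz1", units = "N")
  outf <- force_preprocess(f600)
  expect_equal(outf$values, rep(600, 3000), tolerance = 1e-9 * 600)
  expect_identical(outf$units, "N")

  expect_error(butterworth_lowpass(sampled_signal(rnorm(100), 50),
                                   filter_spec(4, 30)),
               class = "grfsync_parameter_error")
  expect_error(butterworth_lowpass(sampled_signal(rnorm(10), 60),
                                   heel_cascade_spec()),
               class = "grfsync_parameter_error")
  expect_error(filter_spec(4, -3), class = "grfsync_parameter_error")
})

test_that("stopband and passband gains match the analytic digital response", {
  fs <- 60
  t <- seq(0, 60, by = 1 / fs)
  spec <- heel_cascade_spec()
  win <- which(t >= 5 & t < 55)  # integer periods of both test tones

  y10 <- butterworth_lowpass(sampled_signal(sin(2 * pi * 10 * t), fs), spec)
  a10 <- sine_amplitude(y10$values[win], 10, fs, t0 = t[win[1]])
  expect_lt(a10, 0.01)
  expect_equal(a10, butterworth_gain(spec, 10, fs), tolerance = 0.01)

  y05 <- butterworth_lowpass(sampled_signal(sin(2 * pi * 0.5 * t), fs), spec)
  a05 <- sine_amplitude(y05$values[win], 0.5, fs, t0 = t[win[1]])
  expect_gt(a05, 0.99)
  expect_equal(a05, butterworth_gain(spec, 0.5, fs), tolerance = 0.01)

  # force stage: 200 Hz rejected, 1 Hz passed at 1000 Hz
  fsf <- 1000
  tf <- seq(0, 8, by = 1 / fsf)
  winf <- which(tf >= 1 & tf < 7)
  y200 <- force_preprocess(sampled_signal(sin(2 * pi * 200 * tf), fsf))
  expect_lt(sine_amplitude(y200$values[winf], 200, fsf, tf[winf[1]]), 0.01)
  y1 <- force_preprocess(sampled_signal(sin(2 * pi * 1 * tf), fsf))
  expect_gt(sine_amplitude(y1$values[winf], 1, fsf, tf[winf[1]]), 0.99)
})

test_that("bidirectional filtering is zero-phase on symmetric pulses", {
  fs <- 60
  n <- 601
  for (center in c(200, 301, 450)) {
    pulse <- exp(-((seq_len(n) - center) / 12)^2)
    y <- butterworth_lowpass(sampled_signal(pulse, fs), heel_cascade_spec())
    expect_identical(which.max(y$values), as.integer(center))
  }
})

test_that("median filter equals the brute-force windowed median", {
  expect_equal(median_filter(c(0, 0, 9, 0, 0), 5), rep(0, 5))
  mono <- seq(1, 30)
  expect_equal(median_filter(mono, 5), mono)  # sorted windows keep center
  expect_error(median_filter(1:10, 4), class = "grfsync_parameter_error")

  set.seed(21)
  for (k in 1:200) {
    x <- rnorm(sample(7:60, 1))
    w <- sample(c(3, 5, 7), 1)
    expect_equal(median_filter(x, w), oracle_median_filter(x, w))
  }
})

test_that("heel cascade removes isolated outliers and stays near [0,1]", {
  sp <- quick_spec(noise_sd_kin = 0, noise_sd_force = 0)
  g <- generate_trial(sp)
  heel <- g$trial$heel_left
  clean <- heel_preprocess(heel)
  expect_gte(min(clean$values), -0.05)
  expect_lte(max(clean$values), 1.05)

  # downward spike on the plateau: stays inside the signal's range so the
  # min-max mapping is unchanged and only the spike itself differs
  spiked <- heel
  spiked$values[100] <- spiked$values[100] - 0.5 * diff(range(heel$values))
  dirty <- heel_preprocess(spiked)
  expect_lt(abs(dirty$values[100] - clean$values[100]), 1e-3)

  expect_error(heel_preprocess(sampled_signal(rep(0.1, 300), 60)),
               class = "grfsync_degenerate_error")
})
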