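# Independent brute-force oracles: literal loop implementations of the
# detection rules and metrics, kept deliberately naive so they share no
# code with the package internals.

# Heel-contact rule, written as an explicit sample-by-sample scan.
# Returns the 1-based index of the first qualifying crossing, or NA.
oracle_heel_contact <- function(v, factor, stab) {
  n <- length(v)
  gmin <- min(v)
  post_max <- max(v[(stab + 1):n])
  baseline <- post_max - gmin
  if (baseline <= 0) return(NA_integer_)
  thr <- baseline * factor + gmin
  minima <- integer()
  last_dir <- 0L
  for (i in 2:n) {
    d <- v[i] - v[i - 1]
    if (d > 0) {
      if (last_dir < 0L) minima <- c(minima, i - 1L)  # plateau end = i-1
      last_dir <- 1L
    } else if (d < 0) {
      last_dir <- -1L
    } # d == 0: plateau, direction unchanged
  }
  if (!length(minima)) return(NA_integer_)
  for (i in (minima[1] + 1L):n) {
    if (v[i] > v[i - 1] && v[i] > thr && v[i - 1] <= thr) return(i)
  }
  NA_integer_
}

# Force-onset rule: first sample after the baseline segment strictly
# above baseline + factor * population SD.
oracle_force_onset <- function(v, nb = 10L, factor = 0.1,
                               scope = c("signal", "baseline")) {
  scope <- match.arg(scope)
  n <- length(v)
  baseline <- sum(v[1:nb]) / nb
  seg <- if (scope == "signal") v else v[1:nb]
  s <- sqrt(sum((seg - sum(seg) / length(seg))^2) / length(seg))
  thr <- baseline + factor * s
  for (i in (nb + 1L):n) if (v[i] > thr) return(i)
  NA_integer_
}

# Centered running median with shrinking windows, one index at a time.
oracle_median_filter <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    r <- min(i - lo, hi - i)
    out[i] <- median(sort(x[(i - r):(i + r)]))
  }
  out
}

# Two-pass Pearson r / RMSE / MAE with explicit accumulation loops.
oracle_curve_metrics <- function(a, b) {
  n <- length(a)
  ma <- 0; mb <- 0
  for (i in 1:n) { ma <- ma + a[i]; mb <- mb + b[i] }
  ma <- ma / n; mb <- mb / n
  sab <- 0; saa <- 0; sbb <- 0; se <- 0; sae <- 0
  for (i in 1:n) {
    da <- a[i] - ma; db <- b[i] - mb
    sab <- sab + da * db; saa <- saa + da * da; sbb <- sbb + db * db
    e <- a[i] - b[i]
    se <- se + e * e; sae <- sae + abs(e)
  }
  list(r = sab / sqrt(saa * sbb), rmse = sqrt(se / n), mae = sae / n)
}

# Single-frequency amplitude via lock-in quadrature over a window that
# should span an integer number of periods.
sine_amplitude <- function(y, f_hz, fs_hz, t0 = 0) {
  t <- t0 + (seq_along(y) - 1) / fs_hz
  2 * sqrt(mean(y * sin(2 * pi * f_hz * t))^2 +
           mean(y * cos(2 * pi * f_hz * t))^2)
}

# Random heel-like / force-like test signals for detector equivalence;
# half are quantized to create exact plateaus.
random_detector_signal <- function(n = 120L, quantize = FALSE) {
  v <- cumsum(rnorm(n))
  v <- v + seq(0, runif(1, -2, 2), length.out = n)
  if (quantize) v <- round(v, 1)
  v
}

# Shared helper: a clean bilateral synthetic trial spec with overrides.
quick_spec <- function(...) synthetic_trial_spec(...)
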