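#' Amplitude normalization of a cycle curve
#'
#' Maps a fixed-length curve linearly onto `[0, 1]` (its own minimum to
#' 0, its own maximum to 1).  Normalization is per curve, so curve
#' agreement can be judged independently of absolute magnitude.
#'
#' @param curve numeric vector with `max > min`.
#' @return Numeric vector in `[0, 1]`.
#' @export
amplitude_normalize <- function(curve) {
  if (!is.numeric(curve) || length(curve) < 2L)
    gs_parameter_error("'curve' must be a numeric vector of length >= 2")
  minmax_normalize(as.numeric(curve))
}

#' Agreement metrics between two normalized curves
#'
#' Pearson correlation, root-mean-square error and mean absolute error
#' between two equal-length curves (typically amplitude- and
#' time-normalized vGRF cycles from two measurement systems).  When either
#' curve has zero variance the correlation is undefined: `r` is returned
#' as `NA` with `degenerate = TRUE` while RMSE and MAE are still
#' computed.
#'
#' @param a,b numeric vectors of equal length (>= 2).
#' @return An `agreement_metrics` object: `r`, `rmse`, `mae`, `n_points`,
#'   `degenerate`.
#' @export
compare_curves <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b))
    gs_parameter_error("curves must be numeric vectors")
  if (length(a) != length(b))
    gs_parameter_error(sprintf("curve lengths differ: %d vs %d",
                               length(a), length(b)))
  if (length(a) < 2L)
    gs_parameter_error("curves must contain at least 2 points")
  d <- a - b
  rmse <- sqrt(mean(d^2))
  mae <- mean(abs(d))
  degenerate <- stats::var(a) == 0 || stats::var(b) == 0
  r <- if (degenerate) NA_real_ else stats::cor(a, b)
  structure(list(r = r, rmse = rmse, mae = mae,
                 n_points = length(a), degenerate = degenerate),
            class = "agreement_metrics")
}

#' @export
print.agreement_metrics <- function(x, ...) {
  cat(sprintf("<agreement_metrics> r = %s, RMSE = %.4f, MAE = %.4f (n = %d)%s\n",
              if (is.na(x$r)) "NA (degenerate)" else sprintf("%.4f", x$r),
              x$rmse, x$mae, x$n_points,
              if (x$degenerate) " [zero-variance curve]" else ""))
  invisible(x)
}

#' Per-repetition agreement report
#'
#' Computes [compare_curves()] for every reference/test curve pair and
#' summarises the columns as mean +/- SD (sample SD, n-1) across
#' repetitions, plus the percentage of valid pairs with r > 0.80.
#' Degenerate (zero-variance) pairs are excluded from the r summary but
#' stay in the table and are counted, not hidden.
#'
#' @param pairs list of pairs; each element is a list or 2-element list
#'   with components `ref` and `test` (or unnamed, in that order).
#' @param amplitude_normalize normalize each curve to `[0, 1]` before
#'   comparison (default `TRUE`, the validation convention).
#' @param r_threshold threshold for the "high agreement" percentage.
#' @return A `repetition_report` list: `table` (data frame repetition,
#'   r, rmse, mae, degenerate), `summary` (means and SDs), `n_pairs`,
#'   `n_degenerate`, `pct_r_above`.
#' @export
repetition_report <- function(pairs, amplitude_normalize = TRUE,
                              r_threshold = 0.80) {
  if (!is.list(pairs) || !length(pairs))
    gs_parameter_error("'pairs' must be a non-empty list of curve pairs")
  metrics <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    ref <- if (!is.null(p$ref)) p$ref else p[[1L]]
    test <- if (!is.null(p$test)) p$test else p[[2L]]
    if (amplitude_normalize) {
      ok_ref <- max(ref) > min(ref)
      ok_test <- max(test) > min(test)
      if (ok_ref) ref <- minmax_normalize(as.numeric(ref))
      if (ok_test) test <- minmax_normalize(as.numeric(test))
    }
    compare_curves(ref, test)
  })
  tab <- data.frame(
    repetition = seq_along(pairs),
    r = vapply(metrics, function(m) m$r, numeric(1)),
    rmse = vapply(metrics, function(m) m$rmse, numeric(1)),
    mae = vapply(metrics, function(m) m$mae, numeric(1)),
    degenerate = vapply(metrics, function(m) m$degenerate, logical(1)))
  valid_r <- tab$r[!tab$degenerate]
  summ <- list(
    r_mean = if (length(valid_r)) mean(valid_r) else NA_real_,
    r_sd = if (length(valid_r) > 1L) stats::sd(valid_r) else NA_real_,
    rmse_mean = mean(tab$rmse), rmse_sd = if (nrow(tab) > 1L) stats::sd(tab$rmse) else NA_real_,
    mae_mean = mean(tab$mae), mae_sd = if (nrow(tab) > 1L) stats::sd(tab$mae) else NA_real_)
  structure(list(table = tab, summary = summ,
                 n_pairs = nrow(tab),
                 n_degenerate = sum(tab$degenerate),
                 r_threshold = r_threshold,
                 pct_r_above = if (length(valid_r))
                   100 * mean(valid_r > r_threshold) else NA_real_),
            class = "repetition_report")
}

#' @export
print.repetition_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<repetition_report> %d repetitions (%d degenerate)\n",
              x$n_pairs, x$n_degenerate))
  cat(sprintf("  r    = %.4f +/- %.4f\n", s$r_mean, s$r_sd))
  cat(sprintf("  RMSE = %.4f +/- %.4f\n", s$rmse_mean, s$rmse_sd))
  cat(sprintf("  MAE  = %.4f +/- %.4f\n", s$mae_mean, s$mae_sd))
  cat(sprintf("  %.0f%% of valid repetitions with r > %.2f\n",
              x$pct_r_above, x$r_threshold))
  invisible(x)
}
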