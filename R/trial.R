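#' Movement-trial record
#'
#' Bundles the channels of one functional-movement trial: the vertical heel
#' coordinate of each side (camera clock, nominally 60 Hz) and one or more
#' vertical force channels (force-platform clock, nominally 1000 Hz),
#' together with the task metadata the detectors need.
#'
#' Bilateral tasks (e.g. squats) load both limbs, so `evaluated_side` must
#' be `"both"`; single-leg tasks (steps, lunges) analyse the heel of the
#' evaluated limb against the platform that limb lands on.
#'
#' @param heel_left,heel_right vertical heel coordinate as
#'   [sampled_signal()] (either may be `NULL` if that side was not
#'   tracked, but every analysed side must be present).
#' @param vgrf named list of [sampled_signal()] vertical force channels,
#'   one per platform.
#' @param task free-text task label, e.g. `"squat_60"`.
#' @param laterality_mode `"bilateral"` or `"single_leg"`; selects the
#'   heel-contact threshold factor (0.2 vs 0.6).
#' @param evaluated_side `"left"`, `"right"` or `"both"`.
#' @param active_platform name (into `vgrf`) of the platform carrying the
#'   analysed contact; defaults to the first channel.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(heel_left = NULL, heel_right = NULL, vgrf,
                         task = "unspecified",
                         laterality_mode = c("bilateral", "single_leg"),
                         evaluated_side = NULL,
                         active_platform = NULL) {
  laterality_mode <- match.arg(laterality_mode)
  if (is.null(evaluated_side))
    evaluated_side <- if (laterality_mode == "bilateral") "both" else "left"
  evaluated_side <- match.arg(evaluated_side, c("left", "right", "both"))
  if (laterality_mode == "bilateral" && evaluated_side != "both")
    gs_parameter_error("bilateral trials must set evaluated_side = 'both'")
  if (laterality_mode == "single_leg" && evaluated_side == "both")
    gs_parameter_error("single-leg trials must evaluate one side")

  heels <- Filter(Negate(is.null), list(left = heel_left, right = heel_right))
  if (!length(heels))
    gs_parameter_error("at least one heel channel is required")
  for (h in heels)
    if (!is_sampled_signal(h))
      gs_parameter_error("heel channels must be sampled_signal objects")
  rates <- vapply(heels, function(h) h$sampling_rate, numeric(1))
  if (length(unique(rates)) != 1L)
    gs_parameter_error("all heel channels must share one sampling rate")

  if (is_sampled_signal(vgrf)) vgrf <- list(plate1 = vgrf)
  if (!is.list(vgrf) || !length(vgrf))
    gs_parameter_error("'vgrf' must be a non-empty list of sampled_signal")
  if (is.null(names(vgrf)) || any(!nzchar(names(vgrf))))
    names(vgrf) <- paste0("plate", seq_along(vgrf))
  for (f in vgrf)
    if (!is_sampled_signal(f))
      gs_parameter_error("force channels must be sampled_signal objects")
  frates <- vapply(vgrf, function(f) f$sampling_rate, numeric(1))
  if (length(unique(frates)) != 1L)
    gs_parameter_error("all force channels must share one sampling rate")

  if (is.null(active_platform)) active_platform <- names(vgrf)[1L]
  if (!active_platform %in% names(vgrf))
    gs_config_error(sprintf(
      "active_platform '%s' not among force channels (%s)",
      active_platform, paste(names(vgrf), collapse = ", ")))

  structure(
    list(heel_left = heel_left, heel_right = heel_right, vgrf = vgrf,
         task = as.character(task)[1L],
         laterality_mode = laterality_mode,
         evaluated_side = evaluated_side,
         active_platform = active_platform),
    class = "trial_record")
}

#' @rdname trial_record
#' @param x object to test.
#' @export
is_trial_record <- function(x) inherits(x, "trial_record")

#' @export
print.trial_record <- function(x, ...) {
  sides <- c(if (!is.null(x$heel_left)) "left", if (!is.null(x$heel_right)) "right")
  cat(sprintf("<trial_record> task=%s, %s (%s), heels: %s, platforms: %s (active: %s)\n",
              x$task, x$laterality_mode, x$evaluated_side,
              paste(sides, collapse = "+"),
              paste(names(x$vgrf), collapse = ", "), x$active_platform))
  invisible(x)
}
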