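#' Pipeline run configuration
#'
#' Bundles every tunable of the synchronization pipeline with its
#' documented default.  The effective (merged) configuration is embedded
#' verbatim in every report, because the threshold factors and filter
#' settings are the scientific content of a run and must be auditable.
#'
#' Defaults: heel-contact threshold factor 0.2 (bilateral) / 0.6
#' (single-leg), 30-sample stabilization period; force-onset baseline of
#' 10 samples with factor 0.1 on the whole-trace population SD; heel
#' cascade 2 x (4th order, 3 Hz, bidirectional); force low-pass 4th
#' order, 30 Hz, bidirectional; 101 cycle points (0-100% at 1% steps);
#' no resampling; TRC vertical axis `"y"`.
#'
#' @param ... named overrides of the defaults listed by
#'   `run_config()` with no arguments.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    laterality_mode = "bilateral",
    heel_threshold_single_leg = 0.6,
    heel_threshold_bilateral = 0.2,
    stabilization_samples = 30L,
    force_baseline_samples = 10L,
    force_threshold_factor = 0.1,
    force_sd_scope = "signal",
    heel_filter = heel_cascade_spec(),
    force_filter = force_lowpass_spec(),
    median_window = 5L,
    cycle_points = 101L,
    resample_hz = NULL,
    quiet_gap_s = 0.25,
    min_episode_s = 0.05,
    vertical_axis = "y",
    heel_marker_left = "LHeel",
    heel_marker_right = "RHeel",
    force_sampling_rate = 1000,
    force_column_map = list(plate1 = "Fz1"),
    active_platform = NULL,
    evaluated_side = NULL,
    task = "unspecified"
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      gs_config_error("all configuration overrides must be named")
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      gs_config_error(sprintf("unknown configuration key(s): %s",
                              paste(unknown, collapse = ", ")))
    defaults[names(overrides)] <- overrides
  }
  structure(defaults, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML mapping and merges it over the built-in defaults
#' (precedence: defaults < YAML < explicit arguments elsewhere).  Filter
#' specs may be given as mappings with keys `order`, `cutoff_hz`,
#' `bidirectional`, `passes`.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @param ... further overrides applied after the file.
#' @return A [run_config()].
#' @export
load_config <- function(path = NULL, ...) {
  cfg <- run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      gs_config_error(sprintf("configuration file not found: %s", path))
    y <- yaml::read_yaml(path)
    if (!is.list(y)) gs_config_error("configuration file must be a YAML mapping")
    for (k in c("heel_filter", "force_filter"))
      if (!is.null(y[[k]]) && is.list(y[[k]]))
        y[[k]] <- do.call(filter_spec, y[[k]])
    unknown <- setdiff(names(y), names(cfg))
    if (length(unknown))
      gs_config_error(sprintf("unknown configuration key(s) in %s: %s",
                              path, paste(unknown, collapse = ", ")))
    cfg[names(y)] <- y
  }
  dots <- list(...)
  if (length(dots)) cfg <- do.call(run_config, utils::modifyList(
    unclass(cfg)[setdiff(names(cfg), "")], dots))
  cfg
}

# Detector configs implied by a run_config for a given laterality.
heel_cfg_from <- function(config, laterality_mode) {
  factor <- if (identical(laterality_mode, "single_leg"))
    config$heel_threshold_single_leg else config$heel_threshold_bilateral
  heel_detector_config(factor, config$stabilization_samples)
}

force_cfg_from <- function(config) {
  force_detector_config(config$force_baseline_samples,
                        config$force_threshold_factor,
                        config$force_sd_scope)
}

# Serializable view of a config (filter specs flattened).
config_provenance <- function(config) {
  out <- unclass(config)
  out$heel_filter <- unclass(out$heel_filter)
  out$force_filter <- unclass(out$force_filter)
  out
}
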