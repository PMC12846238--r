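#' Read a TRC marker-trajectory file
#'
#' Parses the standard tab-delimited TRC layout: a `PathFileType` line,
#' a metadata header naming at least `DataRate`, `NumFrames` and
#' `NumMarkers`, a marker-name row, an axis row (`X1 Y1 Z1 ...`), then
#' one row per frame (`Frame#`, `Time`, three columns per marker).  Each
#' marker is returned as a triplet of [sampled_signal()]s on the
#' kinematic clock, with the sampling rate taken from `DataRate`.
#'
#' @param path TRC file path.
#' @param units unit string attached to the coordinate signals.
#' @return Named list (one element per marker) of lists with components
#'   `x`, `y`, `z`; attributes `data_rate` and `units`.
#' @export
read_trc <- function(path, units = "m") {
  if (!file.exists(path)) gs_io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L)
    gs_format_error(sprintf("%s: too short to be a TRC file", path))
  hdr_names <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  hdr_vals <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  need <- c("DataRate", "NumFrames", "NumMarkers")
  if (!all(need %in% hdr_names))
    gs_format_error(sprintf(
      "%s: line 2 must declare DataRate, NumFrames and NumMarkers (got: %s)",
      path, lines[2L]))
  hdr <- stats::setNames(as.list(hdr_vals[match(need, hdr_names)]), need)
  data_rate <- suppressWarnings(as.numeric(hdr$DataRate))
  n_frames <- suppressWarnings(as.integer(hdr$NumFrames))
  n_markers <- suppressWarnings(as.integer(hdr$NumMarkers))
  if (is.na(data_rate) || is.na(n_frames) || is.na(n_markers))
    gs_format_error(sprintf("%s: non-numeric header values on line 3: %s",
                            path, lines[3L]))
  marker_row <- strsplit(lines[4L], "\t", fixed = TRUE)[[1L]]
  markers <- marker_row[-(1:2)]
  markers <- markers[nzchar(trimws(markers))]
  if (length(markers) != n_markers)
    gs_format_error(sprintf(
      "%s: header declares %d markers but line 4 names %d",
      path, n_markers, length(markers)))

  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != n_frames)
    gs_format_error(sprintf(
      "%s: header declares %d frames but file contains %d data rows",
      path, n_frames, length(data_lines)))
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  ncol_expect <- 2L + 3L * n_markers
  mat <- matrix(NA_real_, nrow = n_frames, ncol = ncol_expect)
  for (i in seq_len(n_frames)) {
    f <- fields[[i]]
    if (length(f) < ncol_expect)
      gs_format_error(sprintf("%s: data row %d has %d fields, expected %d",
                              path, i, length(f), ncol_expect))
    vals <- suppressWarnings(as.numeric(f[seq_len(ncol_expect)]))
    if (anyNA(vals))
      gs_format_error(sprintf("%s: non-numeric value in data row %d", path, i))
    mat[i, ] <- vals
  }
  start_time <- mat[1L, 2L]
  out <- stats::setNames(vector("list", n_markers), markers)
  for (m in seq_len(n_markers)) {
    base <- 2L + 3L * (m - 1L)
    out[[m]] <- list(
      x = sampled_signal(mat[, base + 1L], data_rate, start_time,
                         paste0(markers[m], "_X"), units),
      y = sampled_signal(mat[, base + 2L], data_rate, start_time,
                         paste0(markers[m], "_Y"), units),
      z = sampled_signal(mat[, base + 3L], data_rate, start_time,
                         paste0(markers[m], "_Z"), units))
  }
  attr(out, "data_rate") <- data_rate
  attr(out, "units") <- units
  out
}

#' Write a TRC marker-trajectory file
#'
#' Inverse of [read_trc()]: writes the standard five-line header followed
#' by the frame rows.  Used by the synthetic-trial writer and by the test
#' fixtures.
#'
#' @param path output path.
#' @param markers named list; each element is a list with numeric `x`,
#'   `y`, `z` vectors (or [sampled_signal()]s) of equal length.
#' @param data_rate sampling rate written to `DataRate` (Hz).
#' @param start_time time of the first frame (s).
#' @param units unit string written to the header.
#' @return `path`, invisibly.
#' @export
write_trc <- function(path, markers, data_rate, start_time = 0, units = "m") {
  as_vec <- function(v) if (is_sampled_signal(v)) v$values else as.numeric(v)
  cols <- lapply(markers, function(m)
    list(x = as_vec(m$x), y = as_vec(m$y), z = as_vec(m$z)))
  n <- unique(unlist(lapply(cols, function(m) lengths(m))))
  if (length(n) != 1L)
    gs_parameter_error("all marker coordinate vectors must share one length")
  nm <- length(cols)
  l1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
  l2 <- paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames"),
              collapse = "\t")
  l3 <- paste(c(format(data_rate), format(data_rate), n, nm, units,
                format(data_rate), 1L, n), collapse = "\t")
  l4 <- paste(c("Frame#", "Time",
                unlist(lapply(names(cols), function(s) c(s, "", "")))),
              collapse = "\t")
  l5 <- paste(c("", "",
                unlist(lapply(seq_len(nm), function(m)
                  paste0(c("X", "Y", "Z"), m)))),
              collapse = "\t")
  times <- start_time + (seq_len(n) - 1) / data_rate
  body <- vapply(seq_len(n), function(i) {
    vals <- unlist(lapply(cols, function(m) c(m$x[i], m$y[i], m$z[i])))
    paste(c(i, sprintf("%.6f", times[i]), sprintf("%.8g", vals)),
          collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(l1, l2, l3, l4, l5, body), con)
  invisible(path)
}

# Guess the field delimiter of a delimited text file from its header line.
detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  counts <- vapply(c("," = ",", ";" = ";", "\t" = "\t"), function(d)
    lengths(regmatches(first, gregexpr(d, first, fixed = TRUE))), integer(1))
  if (all(counts == 0L)) return(",")  # single-column file
  c(",", ";", "\t")[which.max(counts)]
}

#' Read force-platform channels from a delimited text export
#'
#' Reads the vertical-force columns named by `column_map` from a
#' comma-, semicolon- or tab-delimited export (the delimiter is
#' auto-detected from the header line; the decimal mark is assumed to be
#' a point).  Force exports frequently omit a usable time column, so the
#' sampling rate is a required input rather than being inferred.
#'
#' @param path file path.
#' @param column_map named list/vector mapping logical channel names
#'   (e.g. `plate1`) to file header names (e.g. `Fz1`).
#' @param sampling_rate sampling rate of the export (Hz).
#' @param start_time time of the first row (s) on the platform clock.
#' @return Named list of [sampled_signal()]s (units newtons), one per
#'   mapped channel.
#' @export
read_force_csv <- function(path, column_map = list(plate1 = "Fz1"),
                           sampling_rate = 1000, start_time = 0) {
  if (!file.exists(path)) gs_io_error(sprintf("file not found: %s", path))
  if (!length(column_map) || is.null(names(column_map)))
    gs_config_error("'column_map' must map logical channel names to headers")
  sep <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  headers <- names(df)
  out <- vector("list", length(column_map))
  names(out) <- names(column_map)
  for (k in names(column_map)) {
    col <- as.character(column_map[[k]])
    if (!col %in% headers)
      gs_config_error(sprintf(
        "column '%s' (channel '%s') not found in %s; available headers: %s",
        col, k, path, paste(headers, collapse = ", ")))
    raw <- df[[col]]
    vals <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(vals) & nzchar(trimws(raw)))
    if (length(bad) || anyNA(vals))
      gs_format_error(sprintf(
        "%s: non-numeric value in column '%s' at data row %d",
        path, col, if (length(bad)) bad[1L] else which(is.na(vals))[1L]))
    out[[k]] <- sampled_signal(vals, sampling_rate, start_time, col, "N")
  }
  out
}

# --- reports ----------------------------------------------------------------

event_to_list <- function(e) {
  if (is.null(e)) return(NULL)
  list(index_0based = e$index - 1L, time_s = e$time_s,
       threshold_value = e$threshold_value,
       baseline_value = e$baseline_value, detector = e$detector)
}

#' Write / read a machine-readable synchronization report
#'
#' Serializes a `sync_result` to JSON: the signed offset, both event
#' detections (indices 0-based, times in seconds), the thresholds and
#' baselines used, QC flags, cycle curves, and the full provenance
#' (effective configuration).  Numeric fields are written at full
#' precision, so a write/read round trip preserves them to better than
#' 1e-9 relative error.  No wall-clock content is written: rerunning the
#' same analysis yields a bit-identical report.
#'
#' @param result a `sync_result` from [synchronize_trial()].
#' @param path output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_sync_report <- function(result, path) {
  stopifnot(inherits(result, "sync_result"))
  rep <- list(
    schema = list(index_base = 0L, time_units = "s",
                  generator = "grfsync sync report v1"),
    success = isTRUE(result$success),
    task = result$task,
    offset_s = result$offset_s,
    heel_event = event_to_list(result$heel_event),
    force_event = event_to_list(result$force_event),
    heel_side = result$heel_side,
    qc = result$qc,
    reason = result$reason,
    reason_class = result$reason_class,
    cycle_curves = result$cycle_curves,
    provenance = result$provenance)
  rep <- Filter(Negate(is.null), rep)
  ok <- tryCatch({
    suppressWarnings(
      jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null"))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    gs_io_error(sprintf("cannot write report to %s: %s", path,
                        conditionMessage(ok)))
  invisible(path)
}

#' @rdname write_sync_report
#' @export
read_sync_report <- function(path) {
  if (!file.exists(path)) gs_io_error(sprintf("file not found: %s", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Write a shifted force channel as an OpenSim storage (MOT) file
#'
#' Exports one or more force channels on the corrected clock in the
#' OpenSim storage dialect (header block ending in `endheader`, `time`
#' as the first column) for downstream musculoskeletal processing.
#'
#' @param signals a [sampled_signal()] or named list of them, sharing
#'   one clock and rate.
#' @param path output path.
#' @param name dataset name written in the header.
#' @return `path`, invisibly.
#' @export
write_mot <- function(signals, path, name = "grfsync_forces") {
  if (is_sampled_signal(signals)) {
    signals <- stats::setNames(list(signals), signals$label)
  }
  stopifnot(length(signals) >= 1L)
  n <- length(signals[[1L]]$values)
  t <- signal_times(signals[[1L]])
  header <- c(name,
              "version=1",
              sprintf("nRows=%d", n),
              sprintf("nColumns=%d", length(signals) + 1L),
              "inDegrees=no",
              "endheader",
              paste(c("time", names(signals)), collapse = "\t"))
  body <- vapply(seq_len(n), function(i)
    paste(sprintf("%.8f", c(t[i], vapply(signals, function(s)
      s$values[i], numeric(1)))), collapse = "\t"), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write a synthetic trial to disk in the pipeline's input formats
#'
#' Writes the heel channels as a TRC file (vertical axis = Y), the force
#' channel as a comma-delimited export with an `Fz1` header, and the
#' ground truth as JSON, so simulated trials are consumable unchanged by
#' the file-based entry points.
#'
#' @param generated `list(trial, truth)` from [generate_trial()].
#' @param dir output directory (created if missing).
#' @param stem file-name stem; produces `<stem>.trc`,
#'   `<stem>_force.csv`, `<stem>_truth.json`.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_trial_files <- function(generated, dir, stem = "trial") {
  trial <- generated$trial
  truth <- generated$truth
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trc <- file.path(dir, paste0(stem, ".trc"))
  csv <- file.path(dir, paste0(stem, "_force.csv"))
  tj <- file.path(dir, paste0(stem, "_truth.json"))

  zeros <- rep(0, length(trial$heel_left$values))
  write_trc(trc,
            markers = list(
              LHeel = list(x = zeros, y = trial$heel_left, z = zeros),
              RHeel = list(x = zeros, y = trial$heel_right, z = zeros)),
            data_rate = trial$heel_left$sampling_rate,
            start_time = trial$heel_left$start_time)

  f <- trial$vgrf[[trial$active_platform]]
  utils::write.csv(data.frame(Fz1 = sprintf("%.8g", f$values)),
                   csv, row.names = FALSE, quote = FALSE)

  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(trc = trc, force = csv, truth = tj))
}
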