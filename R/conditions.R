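# Classed conditions so callers (and batch mode) can distinguish failure
# kinds without string matching.

gs_error <- function(class, message, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "grfsync_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), extra)
  )
  stop(cond)
}

gs_format_error     <- function(message, ...) gs_error("grfsync_format_error", message, ...)
gs_config_error     <- function(message, ...) gs_error("grfsync_config_error", message, ...)
gs_parameter_error  <- function(message, ...) gs_error("grfsync_parameter_error", message, ...)
gs_degenerate_error <- function(message, ...) gs_error("grfsync_degenerate_error", message, ...)
gs_no_event_error   <- function(message, ...) gs_error("grfsync_no_event_error", message, ...)
gs_io_error         <- function(message, ...) gs_error("grfsync_io_error", message, ...)
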