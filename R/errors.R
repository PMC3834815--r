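# Classed conditions so callers (and the CLI) can map failures to exit codes
# without string-matching messages.

stop_stackprobe <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "stackprobe_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

abort_config <- function(msg) stop_stackprobe("stackprobe_config_error", msg)
abort_format <- function(msg) stop_stackprobe("stackprobe_format_error", msg)
abort_grid <- function(msg) stop_stackprobe("stackprobe_grid_error", msg)
abort_fit <- function(msg) stop_stackprobe("stackprobe_fit_error", msg)
abort_state <- function(msg) stop_stackprobe("stackprobe_state_error", msg)
abort_data <- function(msg) stop_stackprobe("stackprobe_data_error", msg)
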