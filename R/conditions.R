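# Classed conditions used across the package. Every error carries
# "o17_error" plus a specific subclass so callers (and the command-line
# wrapper, which maps subclasses to exit codes) can dispatch on them.

abort_o17 <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "o17_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_validation <- function(message) abort_o17(message, "o17_validation_error")
abort_protocol   <- function(message) abort_o17(message, "o17_protocol_error")
abort_io         <- function(message) abort_o17(message, "o17_io_error")
abort_numerical  <- function(message) abort_o17(message, "o17_numerical_error")

warn_o17 <- function(message, class = "o17_warning") {
  warning(structure(
    class = c(class, "o17_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
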