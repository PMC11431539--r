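# shared condition helper: every package error carries a subclass so callers
# (and the CLI) can distinguish config, data, domain and degenerate failures.
abort <- function(message, class) {
  stop(structure(
    class = c(class, "postopsat_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

warn <- function(message, class = "postopsat_warning") {
  warning(structure(
    class = c(class, "postopsat_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
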