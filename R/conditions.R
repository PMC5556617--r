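# Typed error conditions. Every error raised by this package inherits from
# "stabsel_error" plus a specific subclass so callers (and stability_all())
# can route degenerate cases instead of parsing messages.

stabsel_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "stabsel_error"), ...)
}

stop_empty_set <- function(message = "Selected feature sets must be nonempty.", ...) {
  stabsel_abort(message, "stabsel_error_empty_set", ...)
}

stop_degenerate <- function(message, ...) {
  stabsel_abort(message, "stabsel_error_degenerate_selection", ...)
}

stop_undefined_correlation <- function(message, ...) {
  stabsel_abort(message, "stabsel_error_undefined_correlation", ...)
}

stop_shape <- function(message, ...) {
  stabsel_abort(message, "stabsel_error_shape", ...)
}

stop_single_class <- function(message = "The class label must contain both classes.", ...) {
  stabsel_abort(message, "stabsel_error_single_class", ...)
}

stop_config <- function(message, ...) {
  stabsel_abort(message, "stabsel_error_config", ...)
}

stop_format <- function(message, ...) {
  stabsel_abort(message, "stabsel_error_format", ...)
}

stop_backend <- function(message, ...) {
  stabsel_abort(message, "stabsel_error_backend", ...)
}
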