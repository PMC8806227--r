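# Classed conditions so callers (and the pipeline driver) can distinguish
# configuration mistakes, malformed files, and data that carries no signal.

ph_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "pairhazard_error"), ...)
}

abort_config    <- function(message, ...) ph_abort(message, "ph_config_error", ...)
abort_format    <- function(message, ...) ph_abort(message, "ph_format_error", ...)
abort_parse     <- function(message, ...) ph_abort(message, "ph_parse_error", ...)
abort_domain    <- function(message, ...) ph_abort(message, "ph_domain_error", ...)
abort_alignment <- function(message, ...) ph_abort(message, "ph_alignment_error", ...)
abort_lookup    <- function(message, ...) ph_abort(message, "ph_lookup_error", ...)
abort_no_signal <- function(message, ...) ph_abort(message, "ph_no_signal_error", ...)
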