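# Typed conditions used across the package. Every user-facing failure mode has
# a class so callers (and the CLI exit-code mapping) can dispatch on it.

nt_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "noveltank_error")))
}

nt_input_error <- function(msg, ...) nt_error(msg, "noveltank_input_error", ...)
nt_format_error <- function(msg, ...) nt_error(msg, "noveltank_format_error", ...)
nt_config_error <- function(msg, ...) nt_error(msg, "noveltank_config_error", ...)
nt_window_error <- function(msg, ...) nt_error(msg, "noveltank_window_error", ...)
nt_design_error <- function(msg, ...) nt_error(msg, "noveltank_design_error", ...)
nt_chemistry_error <- function(msg, ...) nt_error(msg, "noveltank_chemistry_error", ...)
nt_degenerate_data_error <- function(msg, ...) nt_error(msg, "noveltank_degenerate_data_error", ...)

nt_tracking_init_error <- function(msg, counts = NULL) {
  nt_error(msg, "noveltank_tracking_init_error", detection_counts = counts)
}
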