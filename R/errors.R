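# Condition helpers. Every user-facing failure carries a spo2cam_error_<kind>
# class so callers (and the tests) can match on the failure mode rather than
# on message text.

abort_spo2 <- function(kind, msg, ...) {
  rlang::abort(msg, class = c(paste0("spo2cam_error_", kind), "spo2cam_error"), ...)
}

stop_invalid_parameter <- function(msg) abort_spo2("invalid_parameter", msg)
stop_insufficient_length <- function(msg) abort_spo2("insufficient_length", msg)
stop_degenerate_signal <- function(msg) abort_spo2("degenerate_signal", msg)
stop_shape <- function(msg) abort_spo2("shape", msg)
stop_detection_failure <- function(msg) abort_spo2("detection_failure", msg)
stop_data <- function(msg) abort_spo2("data", msg)
stop_alignment <- function(msg) abort_spo2("alignment", msg)
stop_state <- function(msg) abort_spo2("state", msg)
stop_config <- function(msg) abort_spo2("config", msg)
stop_leakage <- function(msg) abort_spo2("leakage", msg)
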