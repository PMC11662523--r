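# Structured error conditions. Three failure families are distinguished so
# that callers (and tests) can react to bad configuration, malformed files
# and invalid values separately.

hm_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "heatmort_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

hm_config_error <- function(msg) hm_stop(msg, "heatmort_config_error")
hm_format_error <- function(msg) hm_stop(msg, "heatmort_format_error")
hm_value_error  <- function(msg) hm_stop(msg, "heatmort_value_error")
hm_fit_error    <- function(msg) hm_stop(msg, "heatmort_fit_error")
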