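# Classed conditions so callers (and the CLI) can distinguish user/input
# problems from geometry degeneracies and internal faults.

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("plifr_input_error", "plifr_error")))
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("plifr_config_error", "plifr_input_error",
                                "plifr_error")))
}

stop_geometry <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("plifr_geometry_error", "plifr_error")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("plifr_data_error", "plifr_error")))
}
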