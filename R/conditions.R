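# Classed error constructors so callers (and tests) can distinguish
# configuration, file-format, data, and consistency failures.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("evlfq_config_error", "evlfq_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("evlfq_format_error", "evlfq_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("evlfq_data_error", "evlfq_error")))
}

stop_consistency <- function(...) {
  stop(errorCondition(paste0(...), class = c("evlfq_consistency_error", "evlfq_error")))
}
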