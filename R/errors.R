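# Classed conditions so callers/tests can distinguish failure modes.

bcg_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("bcgsleep_", class, "_error"),
                                     "bcgsleep_error")))
}

bcg_warn <- function(msg) {
  warning(warningCondition(msg, class = "bcgsleep_warning"))
}
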