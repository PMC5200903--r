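# Structured error conditions so callers can distinguish failure modes
# (invalid_fraction, degenerate_cell, ...) without matching message text.

tos_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("toscore_", class), "toscore_error"),
                      call = call))
}

tos_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("toscore_", class), "toscore_warning")))
}
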