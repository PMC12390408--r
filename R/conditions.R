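# classed conditions so callers can distinguish failure modes
fk_stop <- function(msg, type = "error", call = sys.call(-1L)) {
  stop(errorCondition(msg,
                      class = c(paste0("freezekin_", type), "freezekin_error"),
                      call = call))
}

fk_warn <- function(msg, type = "warning") {
  warning(warningCondition(msg,
                           class = c(paste0("freezekin_", type),
                                     "freezekin_warning")))
}
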