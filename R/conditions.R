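# structured conditions so the CLI can map failures to exit codes
stop_sbgndiff <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "sbgndiff_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}
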