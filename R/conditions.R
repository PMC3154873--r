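# classed conditions so callers (and the CLI, which maps them to exit
# codes) can distinguish parse errors, capability refusals, and
# precondition violations from programming errors

stop_parse <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("polydyn_parse_error", "error", "condition"),
                      call = call))
}

stop_refusal <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("polydyn_refusal", "error", "condition"),
                      call = call))
}

stop_precondition <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("polydyn_precondition", "error", "condition"),
                      call = call))
}
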