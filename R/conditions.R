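# Condition helpers: every user-facing failure is a classed condition so
# callers (and tests) can distinguish parse errors from typing errors from
# contract violations.

ljt_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ljtyping_error"), call = call))
}

stop_parse    <- function(msg) ljt_stop(msg, "ljtyping_parse_error")
stop_input    <- function(msg) ljt_stop(msg, "ljtyping_input_error")
stop_typing   <- function(msg) ljt_stop(msg, "ljtyping_typing_error")
stop_domain   <- function(msg) ljt_stop(msg, "ljtyping_domain_error")
stop_contract <- function(msg) ljt_stop(msg, "ljtyping_contract_error")
stop_config   <- function(msg) ljt_stop(msg, "ljtyping_config_error")
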