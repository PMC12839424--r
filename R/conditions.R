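# Classed error conditions so callers (and the CLI) can dispatch on failure kind.

vs_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "varstruct_error"), call = call))
}

vs_warn <- function(msg, class = "varstruct_warning") {
  warning(warningCondition(msg, class = c(class, "varstruct_warning")))
}
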