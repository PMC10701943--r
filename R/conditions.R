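# Classed conditions so callers can branch on failure mode rather than
# matching message text. All classes carry the "batchEB_error" /
# "batchEB_warning" umbrella class.

stop_batchEB <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "batchEB_error")))
}

warn_batchEB <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(class, "batchEB_warning")))
}
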