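# Classed conditions so callers (and the CLI) can react to specific failures.

cc_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "cc_error")))
}

cc_warn <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "cc_warning")))
}

#' @noRd
cc_assert <- function(cond, class, message) {
  if (!isTRUE(cond)) cc_error(class, message)
  invisible(TRUE)
}
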