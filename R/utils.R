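# Shared error helpers. All user-facing errors are classed so callers (and the
# CLI) can distinguish input problems from configuration problems.

abort_input <- function(msg, ..., class = character()) {
  rlang::abort(msg, class = c(class, "mate_input_error"), ...)
}

abort_config <- function(msg, ..., class = character()) {
  rlang::abort(msg, class = c(class, "mate_config_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_input(sprintf("`%s` must be a single finite number.", name),
                class = "mate_range_error")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort_input(sprintf(
      "`%s` = %g is out of range %s%g, %g%s.", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), class = "mate_range_error")
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
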