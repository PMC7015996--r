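`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "dopplerprint_error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, class = "invalid_config") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_("'%s' must be a single finite number", name, class = class)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  if (!lo_ok || x > upper)
    stop_("'%s' = %g out of range %s%g, %g]", name, x,
          if (strict_lower) "(" else "[", lower, upper, class = class)
  invisible(x)
}

check_count <- function(x, name, lower = 1L, class = "validation_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < lower)
    stop_("'%s' must be an integer >= %d", name, lower, class = class)
  as.integer(x)
}
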