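#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Commercial rounding: half away from zero, unlike base round()'s banker's
# rounding. Report tables and integer copy calls both use this convention.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_validation <- function(msg, ...) {
  abort(msg, class = "fermbalance_validation_error", ...)
}

stop_lookup <- function(msg, ...) {
  abort(msg, class = "fermbalance_lookup_error", ...)
}

check_number <- function(x, name, min = -Inf, strict = FALSE, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop_validation(sprintf("`%s` must be numeric.", name))
  }
  if (!allow_na && anyNA(x)) {
    stop_validation(sprintf("`%s` contains missing values.", name))
  }
  bad <- if (strict) x <= min else x < min
  if (any(bad, na.rm = TRUE)) {
    stop_validation(sprintf(
      "`%s` must be %s %s (got %s).",
      name, if (strict) ">" else ">=", format(min),
      paste(format(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}
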