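# internal helpers shared across modules

# relative (ppm) distance between m/z values
ppm_distance <- function(a, b) abs(a - b) / b * 1e6

# OLS slope of y ~ x via the closed form; NA when x has no spread
ols_slope <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) return(NA_real_)
  stats::cov(x, y) / vx
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok) {
    rlang::abort(sprintf(
      "`%s` must be a single finite number in %s%s, %s]",
      name, if (strict_lower) "(" else "[", format(lower), format(upper)
    ))
  }
  invisible(x)
}

# format m/z values as stable feature identifiers
format_mz <- function(mz) sprintf("mz_%.5f", mz)

# normalize ionization mode spellings to "positive"/"negative"
normalize_mode <- function(mode) {
  m <- tolower(trimws(as.character(mode)))
  m[m %in% c("pos", "p", "+", "positive")] <- "positive"
  m[m %in% c("neg", "n", "-", "negative")] <- "negative"
  bad <- !m %in% c("positive", "negative")
  if (any(bad)) {
    rlang::abort(sprintf(
      "unrecognised ionization mode value(s): %s",
      paste(unique(mode[bad]), collapse = ", ")
    ))
  }
  m
}
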