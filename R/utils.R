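# internal helpers shared across modules

# Evaluate a polynomial with coefficients b0..bn (ascending powers) at x.
poly_eval <- function(coefs, x) {
  y <- rep(coefs[length(coefs)], length(x))
  for (k in rev(seq_len(length(coefs) - 1L))) y <- y * x + coefs[k]
  y
}

# Coefficients of the derivative polynomial (ascending powers).
poly_deriv_coefs <- function(coefs) {
  n <- length(coefs)
  if (n <= 1L) return(0)
  coefs[-1L] * seq_len(n - 1L)
}

stop_myomech <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_myomech("'%s' must be a single non-missing number", name)
  ok <- if (allow_equal) x >= lower && x <= upper else x > lower && x < upper
  if (!ok)
    stop_myomech("'%s' = %g outside allowed range [%g, %g]", name, x,
                 lower, upper)
  invisible(x)
}

require_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_myomech("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", "))
  invisible(df)
}

# md5 of an R object via its serialized JSON, for provenance records
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE,
                              null = "null"), f)
  unname(tools::md5sum(f))
}
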