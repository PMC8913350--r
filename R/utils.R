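# Internal validation helpers shared across modules.

abort_schema <- function(msg) {
  rlang::abort(msg, class = c("lipidheart_schema_error", "lipidheart_error"))
}

abort_domain <- function(msg) {
  rlang::abort(msg, class = c("lipidheart_domain_error", "lipidheart_error"))
}

abort_config <- function(msg) {
  rlang::abort(msg, class = c("lipidheart_config_error", "lipidheart_error"))
}

# Columns must exist; `what` names the offending argument in the error.
assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_schema(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_numeric_columns <- function(df, cols, what) {
  bad <- cols[!vapply(df[cols], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort_schema(sprintf(
      "column(s) of `%s` must be numeric: %s",
      what, paste(bad, collapse = ", ")
    ))
  }
  invisible(df)
}

# Scalar numeric bounds check for config fields; errors name the field.
assert_number <- function(x, field, lower = -Inf, upper = Inf,
                          allow_zero_len = FALSE) {
  if (length(x) == 0 && allow_zero_len) return(invisible(x))
  if (!is.numeric(x) || anyNA(x)) {
    abort_config(sprintf("`%s` must be numeric and non-missing", field))
  }
  if (any(x < lower) || any(x > upper)) {
    abort_config(sprintf(
      "`%s` must lie in [%s, %s]", field, format(lower), format(upper)
    ))
  }
  invisible(x)
}

assert_count <- function(x, field, lower = 1) {
  assert_number(x, field, lower = lower)
  if (any(x != as.integer(x))) {
    abort_config(sprintf("`%s` must be a whole number", field))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
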