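# internal helpers

# stop with a consistent error class so callers/tests can condition on it
rb_abort <- function(msg, class = "recombinr_error") {
  rlang::abort(msg, class = class)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rb_abort(sprintf("%s is missing required column(s): %s",
                     what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# canonical unordered genome-pair key, used to join per-pair tables
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
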