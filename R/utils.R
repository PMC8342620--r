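# shared internal helpers

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_scalar_number <- function(x, what, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", what, min, max))
  }
  invisible(x)
}

# deterministic child seed derived from a master seed; kept < 2^31
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1299721 + offset * 7919) %% 2147483647L)
}
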