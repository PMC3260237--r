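# internal validation helpers

assert_fraction <- function(x, name, allow_one = TRUE, allow_zero = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!all(is.finite(x) & lo_ok & hi_ok)) {
    abort(sprintf("`%s` must be %s fraction%s %s",
                  name,
                  if (allow_zero) "a" else "a positive",
                  if (length(x) > 1) "s" else "",
                  if (allow_one) "in [0, 1]" else "in [0, 1)"))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (!all(is.finite(x) & x >= min & abs(x - round(x)) < 1e-8)) {
    abort(sprintf("`%s` must be an integer count >= %s", name, min))
  }
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!all(is.finite(x) & x > 0)) {
    abort(sprintf("`%s` must be positive and finite", name))
  }
  invisible(x)
}

# 2x2 table from matrix or four counts, rows = groups, cols = outcomes
as_table_2x2 <- function(x) {
  if (is.matrix(x) && all(dim(x) == c(2L, 2L))) {
    m <- x
  } else if (is.numeric(x) && length(x) == 4L) {
    m <- matrix(x, nrow = 2L, byrow = TRUE)
  } else {
    abort("expected a 2x2 matrix or a length-4 numeric vector (row-wise)")
  }
  if (any(m < 0) || any(abs(m - round(m)) > 1e-8)) {
    abort("2x2 table cells must be non-negative integers")
  }
  storage.mode(m) <- "double"
  m
}
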