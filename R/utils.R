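# internal argument checks ---------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE,
                                 finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("`%s` must be > %s", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("`%s` must be >= %s", name, lower), call. = FALSE)
  invisible(x)
}

assert_numeric_vec <- function(x, name, len = NULL, lower = -Inf,
                               strict = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("`%s` must be finite numeric", name), call. = FALSE)
  if (!is.null(len) && length(x) != len)
    stop(sprintf("`%s` must have length %d", name, len), call. = FALSE)
  if (strict && any(x <= lower))
    stop(sprintf("all elements of `%s` must be > %s", name, lower),
         call. = FALSE)
  if (!strict && any(x < lower))
    stop(sprintf("all elements of `%s` must be >= %s", name, lower),
         call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  assert_scalar_number(x, name, lower = lower)
  if (x != as.integer(x))
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  invisible(as.integer(x))
}
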