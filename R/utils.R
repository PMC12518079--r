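# internal assertion / messaging helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ith <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_ith <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_ith(fmt, ...)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# recycle a scalar to length n, or validate a length-n vector
recycle_to <- function(x, n, what) {
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  assert_that(length(x) == n, "'%s' must have length 1 or %d, got %d", what, n, length(x))
  as.numeric(x)
}
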