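#' @keywords internal
"_PACKAGE"

## Stage seeds are derived from one global seed by fixed offsets so that
## individual stages are independently reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647L)
}

log_msg <- function(...) {
  message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_fraction <- function(x, name, allow_one = FALSE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok)
    stopf("`%s` must be a fraction in [0, %s)", name, if (allow_one) "1]" else "1")
  invisible(x)
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stopf("`%s` must be a positive integer", name)
  invisible(as.integer(x))
}
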