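# internal validation helpers

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x)))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  assert_number(x, name, lower = lower)
  if (x != as.integer(x)) stopf("'%s' must be an integer count", name)
  invisible(as.integer(x))
}

assert_prob <- function(x, name) assert_number(x, name, lower = 0, upper = 1)

assert_increasing <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x))
    stopf("'%s' must be a numeric vector without NA", name)
  if (any(diff(x) <= 0)) stopf("'%s' must be strictly increasing", name)
  if (positive && any(x <= 0)) stopf("'%s' must be positive", name)
  invisible(x)
}

# run `expr` under an explicit, restored RNG state (one stream per call)
with_rng <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
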