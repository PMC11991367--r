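# internal validation helpers

.check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  invisible(x)
}

.check_count <- function(x, name, lower = 1L) {
  .check_number(x, name, lower = lower)
  if (x != as.integer(x))
    stop(sprintf("`%s` must be an integer count", name), call. = FALSE)
  as.integer(x)
}

.check_signal <- function(x, name = "x") {
  if (!is.numeric(x) || length(x) == 0L)
    stop(sprintf("`%s` must be a non-empty numeric vector", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite samples", name), call. = FALSE)
  as.numeric(x)
}

# signals are stored row-wise; accept a vector as a one-row matrix
.as_signal_matrix <- function(x, name = "x") {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric vector or matrix", name), call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# derive a reproducible 31-bit child seed from a master seed and a counter
.child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483647
}
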