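# Internal helpers shared across modules.

# Deterministic derivation of sub-seeds from a user seed. Keeps results
# reproducible while giving independent streams to independent steps.
# Always returns a positive integer < 2^31.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  if (length(offs) == 0) offs <- 0
  val <- as.numeric(seed) %% 2147483587
  for (o in offs) {
    val <- (val * 48271 + as.numeric(o) * 7919 + 1) %% 2147483587
  }
  as.integer(val + 1)
}

stop_bad <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_bad("`%s` must be a single finite number", name)
  }
  if (x < min || x > max) {
    stop_bad("`%s` must be in [%s, %s], got %s", name, min, max, x)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  check_number(x, name, min = min)
  if (x != round(x)) stop_bad("`%s` must be an integer, got %s", name, x)
  invisible(as.integer(x))
}

# Uniform draw over a range given as c(lo, hi).
runif_range <- function(n, range) {
  runif(n, min = range[1], max = range[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
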