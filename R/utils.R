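`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; a NULL seed uses the current stream.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_mq <- function(...) stop(..., call. = FALSE)

assert_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop_mq(sprintf("`%s` must be a %s scalar", name,
                    if (strict) "positive" else "non-negative"))
  }
  invisible(x)
}

# Deterministic per-subject seed derived from a cohort seed; stays within
# 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% .Machine$integer.max)
}
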