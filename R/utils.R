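# Internal helpers shared across modules.

# Round-half-up to the nearest integer (diary reports heap at whole values;
# base round() uses banker's rounding, which would split x.5 ties).
round_half_up <- function(x) floor(x + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic per-(unit, step) seed derived from a base seed; kept below
# 2^31 so it is a valid R integer seed.
derive_seed <- function(base_seed, i = 0L, j = 0L) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L)
  as.integer((abs(base_seed) + 1000003 * abs(i) + 7919 * abs(j)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_scalar_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
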