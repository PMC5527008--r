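# Classed conditions so callers can distinguish failure modes programmatically.
stop_classed <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "admespace_error")))
}

# TRUE where x equals v, NA-safe (NA compares FALSE).
eqv <- function(x, v) !is.na(x) & x == v

is_ternary <- function(x) is.numeric(x) && all(x %in% c(-1, 0, 1))

# Derive a stream-specific 32-bit seed from a base seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
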