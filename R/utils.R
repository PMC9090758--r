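`%||%` <- function(a, b) if (is.null(a)) b else a

# Seed all R-level randomness for a call; derived seeds stay below 2^31.
local_rng <- function(seed) {
  set.seed(as.integer(abs(seed) %% 2147483629))
  invisible(NULL)
}

# Deterministic child seed from a master seed and an index (e.g. subject).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 214783) %% 2147483629)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_fields <- function(cond, ...) {
  if (cond) stop(paste0(...), call. = FALSE)
}
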