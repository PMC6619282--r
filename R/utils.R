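`%||%` <- function(a, b) if (is.null(a)) b else a

## log(sum(exp(x))) without overflow; -Inf for empty/all -Inf input
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Deterministic 31-bit seed derived from a string and a base seed, so that
## grid cells get reproducible, order-invariant random streams.
derive_seed <- function(base_seed, key) {
  h <- 0
  for (ch in utf8ToInt(paste0(key))) h <- (h * 31 + ch) %% 2147483647L
  as.integer((as.numeric(base_seed) + h) %% 2147483647L)
}

stop_domain <- function(...) stop(..., call. = FALSE)
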