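# internal helpers shared across modules

# round half away from zero (edge budgets); base round() is banker's rounding
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# clip correlations strictly inside (-1, 1) so atanh stays finite
clip_r <- function(r, eps = 1e-7) {
  pmin(pmax(r, -1 + eps), 1 - eps)
}

# derive a per-unit substream seed from a global seed; stays below 2^31
substream_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 69621) %% 2147483587)
}

# upper-triangle edge enumeration of an n x n matrix, column-major
upper_edges <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)))
  list(
    i = ((idx - 1L) %% n) + 1L,
    j = ((idx - 1L) %/% n) + 1L,
    idx = idx
  )
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
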