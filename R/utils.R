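`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stable 32-bit FNV-1a hash of a character scalar, as 8 hex digits.
# Used for config fingerprints in run manifests.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # multiply by the FNV prime mod 2^32 without double-precision overflow
    h_lo <- h %% 65536
    h_hi <- (h - h_lo) / 65536
    h <- (h_lo * 16777619 + ((h_hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}
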