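# Small internal helpers shared across modules.

#' Running mean over a fixed window
#'
#' @param x numeric vector.
#' @param w window width (number of elements); must satisfy `1 <= w <= length(x)`.
#' @return numeric vector of length `length(x) - w + 1`; element `j` is the mean
#'   of `x[j:(j + w - 1)]`.
#' @keywords internal
running_mean <- function(x, w) {
  stopifnot(w >= 1, w <= length(x))
  cs <- cumsum(c(0, x))
  (cs[(w + 1):(length(x) + 1)] - cs[1:(length(x) - w + 1)]) / w
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used for provenance manifests; collision resistance is not required.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits (kept as doubles throughout)
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # 32-bit multiply by 16777619 without overflow: split into 16-bit halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Derive a stream of child seeds from one master seed
#'
#' Deterministic integer seeds (kept below 2^31) for the independent
#' stochastic stages of a run.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) + 104729 * seq_len(n)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a
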