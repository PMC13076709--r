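# Internal helpers shared across modules.

#' Derive a child RNG seed from a base seed and run indices
#'
#' Child seeds for individual simulated acquisitions are derived with a
#' Lehmer-style integer mix so that (session, repeat) pairs map to distinct,
#' stable seeds. All arithmetic stays below 2^53 so the result is exact in
#' double precision, and the returned seed is always a valid 31-bit integer.
#'
#' @param base_seed integer base seed of the study.
#' @param session_idx 1-based session index.
#' @param repeat_idx 1-based repeat index.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, session_idx, repeat_idx) {
  m <- 2147483647
  h <- as.double(abs(as.integer(base_seed))) %% m
  for (v in c(as.double(session_idx), as.double(repeat_idx))) {
    # 48271 is the MINSTD multiplier; h * 48271 < 2^47 stays exact
    h <- (h * 48271 + v * 12345 + 1) %% m
  }
  as.integer(h)
}

# 32-bit FNV-1a over a character scalar; used for config fingerprints in the
# run manifest (no cryptographic intent, just a stable identifier). The
# multiply is split into 16-bit halves so every intermediate stays exact in
# double precision.
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  M <- 16777619
  for (b in bytes) {
    h <- xor_u32(h, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * M) %% 65536) * 65536 + lo * M) %% 4294967296
  }
  # h fits in 32 bits; format via two 16-bit halves (sprintf %x needs ints)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of two values treated as unsigned 32-bit, computed in doubles
xor_u32 <- function(a, b) {
  r <- 0
  p <- 1
  for (i in 1:32) {
    ba <- a %% 2
    bb <- b %% 2
    r <- r + p * ((ba + bb) %% 2)
    a <- (a - ba) / 2
    b <- (b - bb) / 2
    p <- p * 2
  }
  r
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
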