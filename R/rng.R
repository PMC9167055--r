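# Counter-based RNG.
#
# The engine owns one deterministic stream per (work item, input instance),
# keyed by (global seed, neuron index, input index); a draw within a stream is
# keyed by the step counter. Because a draw is a pure function of its keys,
# results are independent of worker count and of work-item execution order.
#
# The mixer is a 32-bit multiply-xor-shift hash (murmur3 finalizer constants)
# implemented over doubles and bitwOps; R lacks native unsigned 64-bit
# integers, so 32-bit products are formed via 16-bit half multiplication.

#' @keywords internal
#' (a * b) mod 2^32 for a, b in [0, 2^32), exact in doubles.
.fb_mul32 <- function(a, b) {
  alo <- a %% 65536; ahi <- (a - alo) / 65536
  blo <- b %% 65536; bhi <- (b - blo) / 65536
  lo <- alo * blo
  mid <- (alo * bhi + ahi * blo) %% 65536
  (lo + mid * 65536) %% 4294967296
}

#' @keywords internal
#' x XOR (x >> n) for x in [0, 2^32). Doubles split into 16-bit words to avoid
#' signed 32-bit integer overflow.
.fb_xorshift <- function(x, n) {
  .fb_xor32(x, floor(x / 2^n))
}

#' @keywords internal
.fb_xor32 <- function(a, b) {
  alo <- a %% 65536; ahi <- (a - alo) / 65536
  blo <- b %% 65536; bhi <- (b - blo) / 65536
  lo <- bitwXor(as.integer(alo), as.integer(blo))
  hi <- bitwXor(as.integer(ahi), as.integer(bhi))
  as.double(hi) * 65536 + as.double(lo)
}

#' @keywords internal
#' 32-bit avalanche mix (murmur3 fmix32). Vectorized over x.
fb_mix32 <- function(x) {
  x <- x %% 4294967296
  x <- .fb_xorshift(x, 16)
  x <- .fb_mul32(x, 2246822507)   # 0x85ebca6b
  x <- .fb_xorshift(x, 13)
  x <- .fb_mul32(x, 3266489909)   # 0xc2b2ae35
  x <- .fb_xorshift(x, 16)
  x
}

#' @keywords internal
#' Stream key for (seed, neuron index, input index). Vectorized.
fb_rng_stream <- function(seed, neuron, input) {
  fb_mix32(fb_mix32(fb_mix32(seed %% 4294967296) + neuron %% 4294967296) +
             input %% 4294967296)
}

#' @keywords internal
#' Uniform draw in [0, 1) for stream(s) at a given step. Vectorized over
#' `stream`; also over `step` if same length.
fb_rng_uniform <- function(stream, step) {
  fb_mix32(stream + fb_mix32(step %% 4294967296)) / 4294967296
}
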