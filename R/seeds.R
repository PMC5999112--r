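#' @title Deterministic seed streams
#' @description A master seed expands into named child streams (one per
#'   plume field, one per flight, ...) via a counter-based integer hash, so
#'   adding flights or fields never perturbs the draws of existing ones.
#'   All hashing is done on 32-bit halves to stay exact in doubles.
#' @name seed-streams
NULL

# 32-bit unsigned arithmetic on doubles --------------------------------------

.u32 <- function(x) x %% 4294967296

# (a * b) mod 2^32 without exceeding 2^53: split a into 16-bit halves.
.mul32 <- function(a, b) {
  hi <- a %/% 65536
  lo <- a %% 65536
  .u32((.u32(hi * b) * 65536) + lo * b)
}

.xor32 <- function(a, b) {
  # bitwXor needs signed 32-bit integers; map [0, 2^32) -> int and back
  ai <- if (a >= 2147483648) a - 4294967296 else a
  bi <- if (b >= 2147483648) b - 4294967296 else b
  r <- bitwXor(as.integer(ai), as.integer(bi))
  if (r < 0) r + 4294967296 else r
}

.shr32 <- function(a, n) a %/% (2^n)

# One round of an xorshift-multiply mixer (splitmix-style finalizer).
.mix32 <- function(h) {
  h <- .xor32(h, .shr32(h, 16))
  h <- .mul32(h, 2246822519)
  h <- .xor32(h, .shr32(h, 13))
  h <- .mul32(h, 3266489917)
  .xor32(h, .shr32(h, 16))
}

#' Derive a child seed from a master seed and a stream label
#'
#' @param master Integer master seed.
#' @param ... Stream coordinates: character labels and/or integer counters,
#'   e.g. `child_seed(1, "field", 3)` or `child_seed(1, "flight", 3, 42)`.
#' @return An integer in `[0, 2^31 - 1]`, suitable for [set.seed()].
#' @examples
#' child_seed(1, "field", 1)
#' child_seed(1, "flight", 1, 17)
#' @export
child_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  h <- .u32(2166136261 + .u32(master))
  for (part in list(...)) {
    if (is.character(part)) {
      for (ch in utf8ToInt(part)) {
        h <- .xor32(h, ch)
        h <- .mul32(h, 16777619)   # FNV-1a step
      }
    } else {
      h <- .xor32(h, .u32(part))
      h <- .mix32(h)
    }
  }
  h <- .mix32(h)
  as.integer(h %% 2147483647)
}

#' FNV-1a hash of a character string
#'
#' Used to fingerprint run manifests so that replayed outputs can be matched
#' to the configuration that produced them.
#'
#' @param x A character scalar.
#' @return Hexadecimal hash string (32-bit FNV-1a).
#' @export
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  h <- 2166136261
  for (ch in utf8ToInt(x)) {
    h <- .xor32(h, ch)
    h <- .mul32(h, 16777619)
  }
  # h is a double in [0, 2^32): format as hex via 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
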