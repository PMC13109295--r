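# Internal numeric helpers: counter-based deterministic randomness and
# small vector-geometry utilities shared across modules.

# Exact 32-bit modular multiply using doubles (split into 16-bit halves so
# every intermediate stays below 2^53).
.mulmod32 <- function(a, b) {
  a <- a %% 4294967296
  a1 <- a %/% 65536
  a0 <- a %% 65536
  (((a1 * b) %% 65536) * 65536 + a0 * b) %% 4294967296
}

#' Counter-based uniform deviate
#'
#' A stateless hash of `(seed, iteration, position)` mapped to (0, 1).
#' Used for every stochastic production-rule choice so that a draw at one
#' string position is independent of edits elsewhere in the grammar or
#' string: the same counter always yields the same deviate.
#'
#' @param seed,iteration,position non-negative integers identifying the draw.
#' @return a double strictly inside (0, 1), identical across platforms.
#' @keywords internal
counter_uniform <- function(seed, iteration, position) {
  h <- seed %% 4294967296
  h <- (.mulmod32(h + iteration + 1, 2654435761) + 374761393) %% 4294967296
  h <- (.mulmod32(h + position + 1, 2246822519) + 668265263) %% 4294967296
  h <- .mulmod32(h, 3266489917)
  # swap 16-bit halves so high bits feed the final scramble
  h <- (h %/% 65536 + (h %% 65536) * 65536) %% 4294967296
  h <- .mulmod32(h, 2654435761)
  (h + 0.5) / 4294967296
}

# Deterministically split a master seed into a child seed < 2^31.
split_seed <- function(seed, index, stream = 0L) {
  floor(counter_uniform(seed, stream, index) * 2147483647)
}

# Weighted successor choice from a uniform deviate; zero-weight entries are
# never selected because u lies strictly inside (0, 1).
choose_weighted <- function(weights, u) {
  cw <- cumsum(weights) / sum(weights)
  findInterval(u, cw, left.open = FALSE) + 1L
}

.norm3 <- function(v) sqrt(sum(v * v))

.unit3 <- function(v) {
  n <- .norm3(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# FNV-1a style text hash (content fingerprint for provenance records).
text_hash <- function(text) {
  bytes <- utf8ToInt(paste(text, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- .mulmod32(bitwXor(as.integer(h %% 2147483648), as.integer(b)) +
                     (if (h >= 2147483648) 2147483648 else 0), 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
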