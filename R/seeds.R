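# 32-bit arithmetic on doubles: R integers overflow at 2^31, so the mixer
# works on nonnegative doubles < 2^32 split into 16-bit halves.

TWO32 <- 4294967296

mul32 <- function(a, b) {
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  (lo * b + ((hi * b) %% 65536) * 65536) %% TWO32
}

xor32 <- function(a, b) {
  alo <- a %% 65536; ahi <- (a - alo) / 65536
  blo <- b %% 65536; bhi <- (b - blo) / 65536
  bitwXor(ahi, bhi) * 65536 + bitwXor(alo, blo)
}

shr32 <- function(a, n) floor(a / 2^n)

#' Derive a stream seed from a master seed
#'
#' Deterministically maps a (master seed, stream index) pair to an
#' independent-looking 31-bit seed using a splitmix/murmur-style integer
#' mixer. All randomness in the package (bootstrap replicates, per-locus
#' simulation) derives its stream seeds through this function, so runs are
#' reproducible and individual streams can be regenerated in isolation.
#'
#' @param seed Master seed (single non-negative integer).
#' @param index Stream index (single non-negative integer).
#' @return A single integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' mix_seed(42, 1)
#' mix_seed(42, 2)
#' @export
mix_seed <- function(seed, index) {
  stopifnot(length(seed) == 1, length(index) == 1, seed >= 0, index >= 0)
  h <- (mul32(seed %% TWO32, 2654435761) + mul32(index %% TWO32, 2246822519)) %% TWO32
  h <- xor32(h, shr32(h, 16))
  h <- mul32(h, 2246822507) # 0x85ebca6b
  h <- xor32(h, shr32(h, 13))
  h <- mul32(h, 3266489909) # 0xc2b2ae35
  h <- xor32(h, shr32(h, 16))
  as.integer(h %% 2147483645 + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
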