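# Digital Sobol low-discrepancy sequence (31-bit, Gray-code construction)
# with direction numbers from the published Joe & Kuo (2008) table, first 32
# dimensions, and random digital-shift scrambling.

SOBOL_POLY <- c(1L, 3L, 7L, 11L, 13L, 19L, 25L, 37L, 41L, 47L, 55L, 59L,
                61L, 67L, 91L, 97L, 103L, 109L, 115L, 131L, 137L, 143L,
                145L, 157L, 167L, 171L, 185L, 191L, 193L, 203L, 211L, 213L)

SOBOL_MINIT <- list(
  NULL, 1L, c(1L, 3L), c(1L, 3L, 1L), c(1L, 1L, 1L), c(1L, 1L, 3L, 3L),
  c(1L, 3L, 5L, 13L), c(1L, 1L, 5L, 5L, 17L), c(1L, 1L, 5L, 5L, 5L),
  c(1L, 1L, 7L, 11L, 19L), c(1L, 1L, 5L, 1L, 1L), c(1L, 1L, 1L, 3L, 11L),
  c(1L, 3L, 5L, 5L, 31L), c(1L, 3L, 3L, 9L, 7L, 49L),
  c(1L, 1L, 1L, 15L, 21L, 21L), c(1L, 3L, 1L, 13L, 27L, 49L),
  c(1L, 1L, 1L, 15L, 7L, 5L), c(1L, 3L, 1L, 15L, 13L, 25L),
  c(1L, 1L, 5L, 5L, 19L, 61L), c(1L, 3L, 7L, 11L, 23L, 15L, 103L),
  c(1L, 3L, 7L, 13L, 13L, 15L, 69L), c(1L, 1L, 3L, 13L, 7L, 35L, 63L),
  c(1L, 3L, 5L, 9L, 1L, 25L, 53L), c(1L, 3L, 1L, 13L, 9L, 35L, 107L),
  c(1L, 3L, 1L, 5L, 27L, 61L, 31L), c(1L, 1L, 5L, 11L, 19L, 41L, 61L),
  c(1L, 3L, 5L, 3L, 3L, 13L, 69L), c(1L, 1L, 7L, 13L, 1L, 19L, 1L),
  c(1L, 3L, 7L, 5L, 13L, 19L, 59L), c(1L, 1L, 3L, 9L, 25L, 29L, 41L),
  c(1L, 3L, 5L, 13L, 23L, 1L, 55L), c(1L, 3L, 7L, 3L, 13L, 59L, 17L))

SOBOL_NBITS <- 31L

# per-dimension direction-number vectors (length nbits), as 31-bit integers
sobol_directions <- function(d) {
  if (d < 1 || d > length(SOBOL_POLY))
    stop("Sobol sequence supports 1..", length(SOBOL_POLY), " dimensions")
  nb <- SOBOL_NBITS
  V <- matrix(0L, nb, d)
  V[, 1] <- as.integer(2^(nb - seq_len(nb)))       # van der Corput
  for (j in seq_len(d)[-1]) {
    p <- SOBOL_POLY[j]
    s <- floor(log2(p))
    m <- SOBOL_MINIT[[j]]
    v <- integer(nb)
    v[seq_len(s)] <- as.integer(m * 2^(nb - seq_len(s)))
    if (nb > s) {
      for (i in (s + 1):nb) {
        vi <- bitwXor(v[i - s], bitwShiftR(v[i - s], s))
        if (s > 1) {
          for (k in seq_len(s - 1)) {
            if (bitwAnd(bitwShiftR(p, s - k), 1L) == 1L)
              vi <- bitwXor(vi, v[i - k])
          }
        }
        v[i] <- vi
      }
    }
    V[, j] <- v
  }
  V
}

#' Scrambled Sobol low-discrepancy points
#'
#' Generates the first `n` points of a digital Sobol sequence in `d`
#' dimensions (Gray-code order, 31-bit precision, direction numbers from the
#' published Joe-Kuo table), randomized by a per-dimension digital shift
#' (XOR with a random 31-bit word). Values lie strictly inside (0, 1).
#'
#' @param n Number of points (>= 1).
#' @param d Dimension (1..32).
#' @param seed Integer seed for the digital shift; `NULL` for the
#'   unscrambled sequence.
#' @return `n x d` matrix in (0, 1).
#' @export
sobol_points <- function(n, d, seed = NULL) {
  stopifnot(n >= 1)
  V <- sobol_directions(d)
  nb <- SOBOL_NBITS
  # sequence indices 0..n-1 (so the first 2^m points form a digital net);
  # Gray-code update flips direction number ctz(i) between point i-1 and i
  ctz <- integer(n)
  ii <- seq_len(n)
  for (b in seq_len(ceiling(log2(n + 1)) + 1)) {
    ctz[ii %% 2^b == 2^(b - 1)] <- b - 1L
  }
  X <- matrix(0L, n, d)
  x <- integer(d)
  for (i in seq_len(n - 1)) {
    x <- bitwXor(x, V[ctz[i] + 1L, ])
    X[i + 1L, ] <- x
  }
  shift <- if (is.null(seed)) integer(d) else
    with_seed(seed, as.integer(floor(runif(d) * (2^nb - 1))))
  U <- matrix(0, n, d)
  for (j in seq_len(d)) U[, j] <- bitwXor(X[, j], shift[j])
  (U + 0.5) / 2^nb
}
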