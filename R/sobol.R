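# Gray-code Sobol sequence with Joe-Kuo direction numbers.
#
# Direction-number initialisation (primitive polynomial degree s, encoded
# coefficients a, initial odd integers m) for dimensions 2..10; dimension 1
# uses m_k = 1 for all k. 30 output bits, so every coordinate is a multiple
# of 2^-30 in [0, 1).
.sobol_init <- list(
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L))
)

.sobol_bits <- 30L

# integer direction numbers v_k = m_k * 2^(bits - k) for one dimension
.sobol_directions <- function(dim_j) {
  L <- .sobol_bits
  m <- integer(L)
  if (dim_j == 1L) {
    m[] <- 1L
  } else {
    e <- .sobol_init[[dim_j - 1L]]
    s <- e$s
    m[seq_len(s)] <- e$m
    if (L > s) {
      for (k in (s + 1L):L) {
        val <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
        if (s > 1L) {
          for (i in seq_len(s - 1L)) {
            if (bitwAnd(bitwShiftR(e$a, s - 1L - i), 1L) == 1L) {
              val <- bitwXor(val, bitwShiftL(m[k - i], i))
            }
          }
        }
        m[k] <- val
      }
    }
  }
  vapply(seq_len(L), function(k) bitwShiftL(m[k], L - k), integer(1L))
}

#' Sobol low-discrepancy sequence on the unit hypercube
#'
#' Generates the first `n_points` points of the standard (unscrambled) Sobol
#' sequence in `[0, 1)^dim`, skipping the initial all-zero point. The
#' sequence is fully deterministic: two calls with the same arguments return
#' identical matrices, and the first `2^k` points of a longer call are a
#' prefix of it.
#'
#' @param n_points number of points (at least 1).
#' @param dim dimension, between 1 and 10 (the span of the built-in
#'   direction numbers).
#' @return An `n_points` by `dim` numeric matrix with entries in `[0, 1)`.
#' @references Sobol', I.M. (1967) On the distribution of points in a cube
#'   and the approximate evaluation of integrals; direction numbers after
#'   Joe & Kuo (2008).
#' @examples
#' sobol_sequence(8, 2)
#' @export
sobol_sequence <- function(n_points, dim) {
  stopifnot(is.numeric(n_points), length(n_points) == 1L, n_points >= 1,
            is.numeric(dim), length(dim) == 1L, dim >= 1)
  n_points <- as.integer(n_points)
  dim <- as.integer(dim)
  if (dim > length(.sobol_init) + 1L) {
    stop("dim > ", length(.sobol_init) + 1L,
         " exceeds the available direction numbers", call. = FALSE)
  }
  V <- vapply(seq_len(dim), .sobol_directions, integer(.sobol_bits))
  X <- matrix(0, n_points, dim)
  x <- integer(dim)
  for (i in seq_len(n_points)) {
    # Gray-code update: flip direction c, the 1-based position of the
    # rightmost zero bit of i - 1 (point 0, the origin, is skipped).
    j <- i - 1L
    c <- 1L
    while (bitwAnd(j, 1L) == 1L) {
      j <- bitwShiftR(j, 1L)
      c <- c + 1L
    }
    x <- bitwXor(x, V[c, ])
    X[i, ] <- x
  }
  X / 2^.sobol_bits
}
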