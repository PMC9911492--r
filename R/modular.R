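# Exact arithmetic over prime fields GF(p).
#
# Rank is discontinuous, so floating-point SVD alone cannot certify it.  When
# model parameters are rational, every flattening entry is rational with a
# common structure, and the rank of the flattening over Q can be certified by
# computing it over GF(p): specialization can only lower rank, so
# rank_p <= rank_Q, with equality for all primes outside a finite bad set.
# Two independent primes plus the SVD estimate are used in concert.
#
# Primes are chosen below 2^25 so that products of two residues (< 2^50) and
# short sums of such products stay exactly representable in doubles.

FR_PRIMES <- c(33554393, 33554467)

mod_reduce <- function(x, p) x %% p

# modular exponentiation by squaring (exact in doubles for p < 2^25)
mod_pow <- function(a, e, p) {
  a <- a %% p
  result <- 1
  while (e > 0) {
    if (e %% 2 == 1) result <- (result * a) %% p
    a <- (a * a) %% p
    e <- e %/% 2
  }
  result
}

mod_inv <- function(a, p) {
  a <- a %% p
  if (a == 0) stop("division by zero in GF(p)")
  mod_pow(a, p - 2, p)
}

# rational a/b -> residue in GF(p); vectorized over a with scalar b
mod_rat <- function(num, den, p) {
  (mod_reduce(num, p) * mod_inv(den, p)) %% p
}

# matrix product over GF(p); inner dimension must be small (< 8) so that the
# accumulated dot products stay below 2^53
mod_matmul <- function(A, B, p) {
  if (ncol(A) >= 8) stop("inner dimension too large for exact modular product")
  (A %*% B) %% p
}

#' Matrix rank over a prime field
#'
#' Gaussian elimination of a residue matrix modulo `p`.  For a matrix of
#' rationals reduced mod `p`, the result is a certified lower bound on the
#' rank over the rationals, equal to it for all but finitely many primes.
#' @param M numeric matrix of residues in `0..p-1`.
#' @param p prime modulus (< 2^25).
#' @return integer rank.
#' @export
mod_rank <- function(M, p = FR_PRIMES[1L]) {
  M <- M %% p
  n <- nrow(M); m <- ncol(M)
  rank <- 0L
  row <- 1L
  for (col in seq_len(m)) {
    if (row > n) break
    piv <- which(M[row:n, col] != 0)
    if (!length(piv)) next
    piv <- row + piv[1L] - 1L
    if (piv != row) { tmp <- M[row, ]; M[row, ] <- M[piv, ]; M[piv, ] <- tmp }
    inv <- mod_inv(M[row, col], p)
    M[row, ] <- (M[row, ] * inv) %% p
    for (i in seq_len(n)) {
      if (i != row && M[i, col] != 0) {
        M[i, ] <- (M[i, ] - M[i, col] * M[row, ]) %% p
      }
    }
    rank <- rank + 1L
    row <- row + 1L
  }
  rank
}
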