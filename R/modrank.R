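# Exact linear algebra for rank decisions.
#
# Ranks are never computed in floating point.  Two routes:
#  * Bareiss fraction-free elimination over the integers, exact as long as
#    every intermediate minor stays below 2^49 (doubles are exact integers
#    up to 2^53); used for small tropical matrices.
#  * Gaussian elimination over a prime field F_p with p < sqrt(2^53), so all
#    products of residues are exact in doubles.  A rank over F_p lower-bounds
#    the rank over Q; computing over two independent primes and taking the
#    maximum makes an undershoot practically impossible.

#  largest primes below floor(sqrt(2^53)) = 94906265; verified prime
MOD_PRIMES <- c(94906249, 94906219)

mod_inv <- function(a, p) {
  # extended Euclid; a in [1, p)
  t <- 0; newt <- 1; r <- p; newr <- a
  while (newr != 0) {
    q <- (r - r %% newr) / newr
    tmp <- t - q * newt; t <- newt; newt <- tmp
    tmp <- r - q * newr; r <- newr; newr <- tmp
  }
  if (r > 1) stop("element not invertible")
  if (t < 0) t <- t + p
  t
}

#' Exact matrix rank over a prime field
#'
#' Gaussian elimination over F_p using double arithmetic (all intermediates
#' below 2^53, hence exact).
#'
#' @param A numeric matrix of integers (any size of entries; reduced mod p).
#' @param p prime modulus below 94906266.
#' @return integer rank.
#' @export
rank_modp <- function(A, p = MOD_PRIMES[1L]) {
  A <- as.matrix(A) %% p
  nr <- nrow(A); nc <- ncol(A)
  if (nr == 0L || nc == 0L) return(0L)
  if (nr > nc) A <- t(A)            # eliminate over the short dimension
  nr <- nrow(A); nc <- ncol(A)
  rank <- 0L
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    piv <- which(A[row:nr, col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) { tmp <- A[row, ]; A[row, ] <- A[piv, ]; A[piv, ] <- tmp }
    inv <- mod_inv(A[row, col], p)
    A[row, ] <- (A[row, ] * inv) %% p
    if (row < nr) {
      below <- (row + 1L):nr
      fac <- A[below, col]
      nz <- which(fac != 0)
      if (length(nz)) {
        rows <- below[nz]
        A[rows, ] <- (A[rows, , drop = FALSE] -
                        outer(fac[nz], A[row, ])) %% p
      }
    }
    rank <- rank + 1L
    row <- row + 1L
  }
  rank
}

#' Exact integer matrix rank via Bareiss elimination
#'
#' Fraction-free elimination; every intermediate entry is a minor of the
#' input.  Errors if entries would exceed the exact-double range, in which
#' case callers fall back to two-prime modular rank.
#'
#' @param A matrix of (small) integers.
#' @return integer rank.
#' @export
rank_bareiss <- function(A) {
  A <- as.matrix(A) * 1.0
  nr <- nrow(A); nc <- ncol(A)
  if (nr == 0L || nc == 0L) return(0L)
  if (nr > nc) A <- t(A)
  nr <- nrow(A); nc <- ncol(A)
  rank <- 0L; row <- 1L; prev <- 1
  for (col in seq_len(nc)) {
    if (row > nr) break
    piv <- which(A[row:nr, col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) { tmp <- A[row, ]; A[row, ] <- A[piv, ]; A[piv, ] <- tmp }
    if (row < nr) {
      below <- (row + 1L):nr
      newA <- (A[below, , drop = FALSE] * A[row, col] -
                 outer(A[below, col], A[row, ])) / prev
      if (any(abs(newA) > 2^49) || any(newA != round(newA)))
        stop("bareiss overflow")
      A[below, ] <- newA
    }
    prev <- A[row, col]
    rank <- rank + 1L
    row <- row + 1L
  }
  rank
}

# exact rank over Q: Bareiss when safe, else max over two prime fields
exact_rank <- function(A) {
  r <- tryCatch(rank_bareiss(A), error = function(e) NULL)
  if (!is.null(r)) return(list(rank = r, field = "QQ (Bareiss)"))
  list(rank = max(rank_modp(A, MOD_PRIMES[1L]), rank_modp(A, MOD_PRIMES[2L])),
       field = sprintf("Fp (p = %d, %d)", MOD_PRIMES[1L], MOD_PRIMES[2L]))
}
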