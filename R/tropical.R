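#' Tropical lower-bound certificate
#'
#' For a weight vector lambda on the parameter axes, every coordinate of the
#' parameterization selects the exponent vector of the monomial minimizing
#' the inner product with lambda.  The matrix A_lambda of selected exponent
#' vectors (one column per coordinate) has rank bounded above by the variety
#' dimension; ranks are computed exactly over the rationals.  A coordinate
#' where the minimum is attained by two or more monomials is reported as a
#' tie and disqualifies lambda as a certificate (the caller may perturb).
#'
#' @param param a `gb_param`.
#' @param lambda numeric vector over the parameter axes (length
#'   `param$n_params`, or named by parameter name).  Integer or rational
#'   entries; comparisons are exact.
#' @return object of class `tropical_certificate` with fields `lambda`,
#'   `A_matrix`, `rank`, `ties` (coordinate indices), `field`.
#' @export
tropical_lower_bound <- function(param, lambda) {
  lambda <- resolve_point(param, lambda)
  N <- nrow(param$labellings)
  nt <- length(param$trees)
  W <- matrix(0, nt, N)
  for (t in seq_len(nt)) {
    P <- param$pidx[[t]]
    W[t, ] <- colSums(matrix(lambda[P], nrow = nrow(P)))
  }
  choice <- apply(W, 2L, which.min)
  ties <- which(vapply(seq_len(N), function(j)
    sum(W[, j] == min(W[, j])) > 1L, TRUE))
  A <- matrix(0L, param$n_params, N)
  for (t in seq_len(nt)) {
    sel <- which(choice == t)
    if (length(sel) == 0L) next
    P <- param$pidx[[t]]
    for (r in seq_len(nrow(P)))
      A[cbind(P[r, sel], sel)] <- A[cbind(P[r, sel], sel)] + 1L
  }
  rk <- exact_rank(A)
  structure(list(lambda = lambda, A_matrix = A, rank = rk$rank,
                 ties = ties, field = rk$field),
            class = "tropical_certificate")
}

#' @export
print.tropical_certificate <- function(x, ...) {
  cat(sprintf("Tropical certificate: rank A_lambda = %d (%s), %d tie(s)\n",
              x$rank, x$field, length(x$ties)))
  invisible(x)
}

#' Witness weight vectors for contracted sunlets
#'
#' Reproduces the weight vectors used to certify sunlet dimensions: for
#' |G| > 2 (and n >= 4), lambda has -2 on the identity-orbit parameter of
#' the cycle edge e_{n+2} and 1 on every parameter of the reticulation edge
#' e_{n+1}; for G = Z/2, lambda has 1 on both parameters of e_{n+1} and 2 on
#' the identity parameter of e_{n+3}.  The n = 3 case is unsupported (the
#' construction degenerates; whether the 3-sunlet reaches the expected
#' dimension for |G| > 4 is an open conjecture).
#'
#' @param n sunlet size (n >= 4; n = 4 with G = Z/2 is allowed but the
#'   certificate is known not to reach the expected dimension).
#' @param model a `gb_model`.
#' @return named numeric vector over the parameters of
#'   `make_sunlet(n, contracted = TRUE)`.
#' @export
sunlet_witness_lambda <- function(n, model) {
  if (n < 4L)
    stop("unsupported witness: the construction breaks for n = 3")
  l1 <- model$l + 1L
  m <- 2L * n - 1L
  lambda <- numeric(m * l1)
  pidx <- function(edge_num, orbit) (edge_num - 1L) * l1 + orbit
  if (model$group$order > 2L) {
    lambda[pidx(n + 2L, 1L)] <- -2
    lambda[pidx(n + 1L, seq_len(l1))] <- 1
  } else {
    lambda[pidx(n + 1L, 1:2)] <- 1
    lambda[pidx(n + 3L, 1L)] <- 2
  }
  net <- make_sunlet(n, contracted = TRUE)
  param_names <- as.vector(t(outer(
    net$edges$id, element_label(model$group, model$reps),
    function(e, g) paste0(e, "^", g))))
  stats::setNames(lambda, param_names)
}

#' Rank of the reduced block B of a sunlet tropical certificate
#'
#' Performs the standard reduction of A_lambda for a contracted n-sunlet
#' under a witness lambda: restrict columns to leaf labellings with g1 != 0;
#' replace the rows of edge 2 by their difference with edge n+2 and the
#' rows of edge n by their difference with edge 2n-1; restrict rows to the
#' parameters of edges 1, 2, n and n+1; return the exact rank of the block.
#'
#' @param param a `gb_param` built on `make_sunlet(n, contracted = TRUE)`.
#' @param lambda witness weights, as from [sunlet_witness_lambda()].
#' @return integer rank of the block.
#' @export
submatrix_B_rank <- function(param, lambda) {
  cert <- tropical_lower_bound(param, lambda)
  if (length(cert$ties))
    stop("witness lambda produced ties at ", length(cert$ties),
         " coordinate(s); cannot certify")
  n <- length(param$leaf_order)
  l1 <- param$model$l + 1L
  A <- cert$A_matrix
  g1 <- param$labellings[, match("1", param$leaf_order)]
  cols <- which(g1 != 1L)
  rows_of_edge <- function(k) (k - 1L) * l1 + seq_len(l1)
  A[rows_of_edge(2L), ] <- A[rows_of_edge(2L), ] - A[rows_of_edge(n + 2L), ]
  A[rows_of_edge(n), ] <- A[rows_of_edge(n), ] - A[rows_of_edge(2L * n - 1L), ]
  keep <- c(rows_of_edge(1L), rows_of_edge(2L), rows_of_edge(n),
            rows_of_edge(n + 1L))
  B <- A[keep, cols, drop = FALSE]
  exact_rank(B)$rank
}
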