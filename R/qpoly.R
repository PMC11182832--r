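# Polynomials in the Fourier coordinates q_{g1...gn}.
#
# A coordinate is identified by its key: the concatenated element labels of
# the leaf labelling (fixed width per group, e.g. "0011" for Z/2 on four
# leaves, "001011" for the Klein four-group on three leaves).  A monomial is
# the "*"-joined sorted multiset of its factor keys; a polynomial is a named
# numeric vector of coefficients on monomials.  No term orders are needed:
# the package never runs Groebner computations.

lab_key <- function(group, idx) {
  if (any(group$factors > 10))
    stop("coordinate keys require all invariant factors <= 10")
  paste(element_label(group, idx), collapse = "")
}

key_to_idx <- function(group, key) {
  w <- length(group$factors)
  if (nchar(key) %% w != 0L) stop("malformed coordinate key: ", key)
  n <- nchar(key) %/% w
  labs <- element_label(group, seq_len(group$order))
  chunks <- substring(key, w * (seq_len(n) - 1L) + 1L, w * seq_len(n))
  idx <- match(chunks, labs)
  if (anyNA(idx)) stop("malformed coordinate key: ", key)
  idx
}

#' Build a polynomial in Fourier coordinates
#'
#' @param coefs numeric coefficients.
#' @param monomials list of character vectors; each vector holds the
#'   coordinate keys of one monomial's factors (with multiplicity).
#' @return object of class `qpoly` (named coefficient vector; like terms
#'   merged, zeros dropped).
#' @export
qpoly <- function(coefs, monomials) {
  keys <- vapply(monomials, function(f) paste(sort(f), collapse = "*"), "")
  v <- tapply(coefs, keys, sum)
  v <- v[v != 0]
  structure(as.numeric(v), names = names(v), class = "qpoly")
}

#' @export
print.qpoly <- function(x, ...) {
  if (length(x) == 0L) { cat("0\n"); return(invisible(x)) }
  cat(render_qpoly(x), "\n")
  invisible(x)
}

#' Render a q-coordinate polynomial as plain text
#'
#' Matches the subscript notation of the literature:
#' `q_0000*q_1111 - q_0011*q_1100`.
#'
#' @param x a `qpoly`.
#' @return character string.
#' @export
render_qpoly <- function(x) {
  if (length(x) == 0L) return("0")
  terms <- vapply(seq_along(x), function(i) {
    mono <- paste(paste0("q_", strsplit(names(x)[i], "*", fixed = TRUE)[[1L]]),
                  collapse = "*")
    co <- unname(x[i])
    sign <- if (co < 0) " - " else " + "
    mag <- if (abs(co) == 1) "" else paste0(abs(co), "*")
    paste0(sign, mag, mono)
  }, "")
  out <- paste(terms, collapse = "")
  sub("^ \\+ ", "", sub("^ - ", "-", out))
}

qp_monomials <- function(x)
  lapply(names(x), function(k) strsplit(k, "*", fixed = TRUE)[[1L]])

qp_add <- function(a, b) {
  keys <- union(names(a), names(b))
  v <- stats::setNames(numeric(length(keys)), keys)
  v[names(a)] <- v[names(a)] + as.numeric(a)
  v[names(b)] <- v[names(b)] + as.numeric(b)
  v <- v[v != 0]
  structure(as.numeric(v), names = names(v), class = "qpoly")
}

qp_scale <- function(a, s) {
  if (s == 0) return(structure(numeric(0), names = character(0),
                               class = "qpoly"))
  structure(as.numeric(a) * s, names = names(a), class = "qpoly")
}

qp_is_zero <- function(a) length(a) == 0L

qp_equal <- function(a, b) qp_is_zero(qp_add(a, qp_scale(b, -1)))
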