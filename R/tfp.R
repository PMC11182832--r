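# Toric fiber products along a cut edge.
#
# Cutting a level-1 network at a (non-reticulation) cut edge e splits the
# coordinate ring: glued coordinates q_{g1...gn} factor as a product of a
# "+"-piece coordinate (cut leaf last) and a "-"-piece coordinate (cut leaf
# first).  The multigrading by the B-orbit of the cut-edge label makes the
# glued ideal the toric fiber product of the piece ideals over the degree
# set {E_[g]}, of size l + 1.

#' Multidegree of a glued coordinate
#'
#' The degree of q_{g1...gn} with respect to a cut is the B-orbit of the sum
#' of the labels on the designated (plus) side of the cut.
#'
#' @param lab integer vector of element indices (a leaf labelling).
#' @param plus_positions positions of the plus-side leaves within `lab`.
#' @param model a `gb_model`.
#' @return orbit index (1 = identity orbit).
#' @export
multidegree <- function(lab, plus_positions, model) {
  s <- group_sum_idx(model$group,
                     matrix(lab[plus_positions], ncol = 1L))
  model$orbit_of[s]
}

# degree of a piece coordinate: plus pieces carry the cut leaf last, minus
# pieces first; both equal the orbit of the cut-edge label
piece_degree <- function(key, side, model) {
  idx <- key_to_idx(model$group, key)
  cut <- if (side == "plus") model$group$neg[idx[length(idx)]] else idx[1L]
  model$orbit_of[cut]
}

#' Quadratic gluing binomials (Quad_B)
#'
#' For every pair of glued coordinates of equal multidegree, the binomial
#' obtained by swapping their minus-side labellings lies in the kernel of
#' the gluing monomial map.  Pairs whose swap is degenerate (identical
#' monomials) are excluded; pairs whose swapped labellings would be
#' inconsistent (possible only for nontrivial B) are skipped.
#'
#' @param n number of leaves of the glued network.
#' @param n_plus number of plus-side leaves (positions 1..n_plus).
#' @param model a `gb_model`.
#' @return list of `qpoly` binomials.
#' @export
quad_b_generators <- function(n, n_plus, model) {
  group <- model$group
  labs <- consistent_labellings(n, group)
  keys <- apply(labs, 1L, function(r) lab_key(group, r))
  degs <- apply(labs, 1L, function(r) multidegree(r, seq_len(n_plus), model))
  out <- list()
  for (d in unique(degs)) {
    idx <- which(degs == d)
    if (length(idx) < 2L) next
    for (a in seq_len(length(idx) - 1L)) for (b in (a + 1L):length(idx)) {
      gi <- labs[idx[a], ]; gj <- labs[idx[b], ]
      s1 <- c(gi[seq_len(n_plus)], gj[(n_plus + 1L):n])
      s2 <- c(gj[seq_len(n_plus)], gi[(n_plus + 1L):n])
      if (group_sum_idx(group, matrix(s1, ncol = 1L)) != 1L) next
      m1 <- sort(c(keys[idx[a]], keys[idx[b]]))
      m2 <- sort(c(lab_key(group, s1), lab_key(group, s2)))
      if (identical(m1, m2)) next
      out[[length(out) + 1L]] <- qpoly(c(1, -1), list(m1, m2))
    }
  }
  unique(out)
}

# combine a plus-piece key and a minus-piece key into a glued coordinate key
glue_keys <- function(plus_key, minus_key, model) {
  group <- model$group
  pi <- key_to_idx(group, plus_key)
  mi <- key_to_idx(group, minus_key)
  if (mi[1L] != group$neg[pi[length(pi)]])
    stop("cannot glue ", plus_key, " with ", minus_key,
         ": cut-edge labels are not opposite")
  lab_key(group, c(pi[-length(pi)], mi[-1L]))
}

#' Lift a piece polynomial to the glued coordinates
#'
#' A polynomial f in one piece's coordinates, homogeneous in the cut-edge
#' multigrading, lifts by a choice k of one co-factor generator per term
#' slot (slots are the factors of each term sorted by degree then key; the
#' degree sequence is the same in every term).  Applying the gluing
#' monomial map to the lift returns the co-factor monomial times f.
#'
#' @param f a `qpoly` in the coordinates of one piece (plus pieces carry
#'   the cut leaf last; minus pieces first).
#' @param k character vector of co-factor coordinate keys, one per slot,
#'   with degrees matching the slot degrees.
#' @param side `"plus"` if `f` lives on the plus piece.
#' @param model a `gb_model`.
#' @return a `qpoly` in the glued coordinates.
#' @export
lift_polynomial <- function(f, k, side = c("plus", "minus"), model) {
  side <- match.arg(side)
  co_side <- if (side == "plus") "minus" else "plus"
  monos <- qp_monomials(f)
  sorted <- lapply(monos, function(fac) {
    d <- vapply(fac, piece_degree, 0L, side = side, model = model)
    fac[order(d, fac)]
  })
  degseq <- lapply(sorted, function(fac)
    unname(vapply(fac, piece_degree, 0L, side = side, model = model)))
  for (ds in degseq) if (!identical(ds, degseq[[1L]]))
    stop("polynomial is not homogeneous in the cut multigrading")
  if (length(k) != length(degseq[[1L]]))
    stop("lift index must supply one co-factor per term slot")
  kdeg <- vapply(k, piece_degree, 0L, side = co_side, model = model)
  if (!identical(unname(kdeg), unname(degseq[[1L]])))
    stop("co-factor degrees do not match the slot degrees")
  glued <- lapply(sorted, function(fac)
    vapply(seq_along(fac), function(u) {
      if (side == "plus") glue_keys(fac[u], k[u], model)
      else glue_keys(k[u], fac[u], model)
    }, ""))
  qpoly(as.numeric(f), glued)
}

#' All lifts of a piece polynomial
#'
#' Enumerates every co-factor choice with matching degrees and returns the
#' corresponding lifts.
#'
#' @inheritParams lift_polynomial
#' @param n number of leaves of the glued network.
#' @param n_plus number of plus-side leaves.
#' @return list of `qpoly`.
#' @export
lift_all <- function(f, side = c("plus", "minus"), model, n, n_plus) {
  side <- match.arg(side)
  co_side <- if (side == "plus") "minus" else "plus"
  group <- model$group
  n_co <- if (co_side == "plus") n_plus + 1L else n - n_plus + 1L
  co_labs <- consistent_labellings(n_co, group)
  co_keys <- apply(co_labs, 1L, function(r) lab_key(group, r))
  co_degs <- vapply(co_keys, piece_degree, 0L, side = co_side, model = model)
  mono1 <- qp_monomials(f)[[1L]]
  d1 <- vapply(mono1, piece_degree, 0L, side = side, model = model)
  slots <- sort(d1)
  choices <- lapply(slots, function(d) co_keys[co_degs == d])
  grid <- do.call(expand.grid, c(lapply(choices, identity),
                                 stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(grid)), function(i)
    lift_polynomial(f, as.character(unlist(grid[i, ])), side, model))
  unique(out)
}

#' Gluing monomial map, applied symbolically
#'
#' Maps a polynomial in glued coordinates to the mixed piece coordinates:
#' every glued coordinate q_{g1...gn} becomes the product of its plus-piece
#' coordinate (keys prefixed "P:") and minus-piece coordinate ("M:").
#' Quad_B generators map to zero; a lift maps to the co-factor monomial
#' times the original polynomial.
#'
#' @param qp a `qpoly` in glued coordinates.
#' @param n_plus number of plus-side leaves.
#' @param model a `gb_model`.
#' @return a `qpoly` over prefixed mixed keys.
#' @export
phi_B <- function(qp, n_plus, model) {
  group <- model$group
  monos <- qp_monomials(qp)
  mixed <- lapply(monos, function(fac) {
    unlist(lapply(fac, function(key) {
      idx <- key_to_idx(group, key)
      n <- length(idx)
      plus <- idx[seq_len(n_plus)]
      minus <- idx[(n_plus + 1L):n]
      gplus <- group$neg[group_sum_idx(group, matrix(plus, ncol = 1L))]
      gminus <- group$neg[group_sum_idx(group, matrix(minus, ncol = 1L))]
      c(paste0("P:", lab_key(group, c(plus, gplus))),
        paste0("M:", lab_key(group, c(gminus, minus))))
    }))
  })
  qpoly(as.numeric(qp), mixed)
}

# embed a piece polynomial into the mixed coordinates and multiply by a
# co-factor monomial; used to check phi_B(f_k) == (co-factor) * f
embed_with_cofactor <- function(f, k, side, model) {
  pre <- if (side == "plus") "P:" else "M:"
  co_pre <- if (side == "plus") "M:" else "P:"
  monos <- qp_monomials(f)
  mixed <- lapply(monos, function(fac)
    c(paste0(pre, fac), paste0(co_pre, k)))
  qpoly(as.numeric(f), mixed)
}
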