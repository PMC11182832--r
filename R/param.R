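#' Fourier-coordinate parameterization of a group-based network model
#'
#' For each consistent leaf labelling the coordinate is a sum of one
#' monomial per displayed tree: the monomial has one factor a_e^{[xi(e)]}
#' per retained edge, where xi(e) is the sum of the leaf labels on the
#' arrow side of e mapped to its B-orbit representative.  Parameters are
#' indexed by (edge, orbit); there are m(l+1) of them.
#'
#' @param net an `sdnet`.
#' @param model a `gb_model`.
#' @return object of class `gb_param` with the labelling matrix, displayed
#'   trees, and per-tree matrices of parameter indices (`pidx`, one row per
#'   retained edge, one column per coordinate).
#' @export
build_parameterization <- function(net, model) {
  group <- model$group
  l1 <- model$l + 1L
  leaf_order <- net$leaf_order
  n <- length(leaf_order)
  labellings <- consistent_labellings(n, group)
  trees <- displayed_trees(net)
  m <- nrow(net$edges)
  edge_ids <- net$edges$id
  param_names <- as.vector(t(outer(edge_ids, element_label(group, model$reps),
                                   function(e, g) paste0(e, "^", g))))
  pidx <- vector("list", length(trees))
  elab <- vector("list", length(trees))
  for (t in seq_along(trees)) {
    sides <- tree_leafsides(net, trees[[t]])
    eids <- names(sides)
    P <- matrix(0L, length(eids), nrow(labellings))
    E <- matrix(0L, length(eids), nrow(labellings))
    for (r in seq_along(eids)) {
      pos <- match(sides[[r]], leaf_order)
      lab <- if (length(pos) == 0L) rep(1L, nrow(labellings)) else
        group_sum_idx(group, t(labellings[, pos, drop = FALSE]))
      E[r, ] <- lab
      epos <- match(eids[r], edge_ids)
      P[r, ] <- (epos - 1L) * l1 + model$orbit_of[lab]
    }
    rownames(P) <- eids
    rownames(E) <- eids
    pidx[[t]] <- P
    elab[[t]] <- E
  }
  structure(list(net = net, model = model, leaf_order = leaf_order,
                 labellings = labellings, trees = trees,
                 pidx = pidx, elab = elab,
                 m = m, edge_ids = edge_ids,
                 n_params = m * l1, param_names = param_names),
            class = "gb_param")
}

#' @export
print.gb_param <- function(x, ...) {
  cat(sprintf(
    "Fourier parameterization: %d coordinates, %d parameters, %d monomial(s) per coordinate\n",
    nrow(x$labellings), x$n_params, length(x$trees)))
  invisible(x)
}

#' Evaluate the parameterization at a parameter point
#'
#' @param param a `gb_param`.
#' @param point numeric vector of length `param$n_params` (order as in
#'   `param$param_names`), or named by parameter name.
#' @param p optional prime; if given, arithmetic is done in F_p.
#' @return numeric vector of coordinate values, one per consistent leaf
#'   labelling.
#' @export
evaluate_param <- function(param, point, p = NULL) {
  point <- resolve_point(param, point)
  N <- nrow(param$labellings)
  out <- numeric(N)
  for (t in seq_along(param$trees)) {
    v <- rep(1, N)
    P <- param$pidx[[t]]
    for (r in seq_len(nrow(P))) {
      v <- v * point[P[r, ]]
      if (!is.null(p)) v <- v %% p
    }
    out <- out + v
    if (!is.null(p)) out <- out %% p
  }
  out
}

resolve_point <- function(param, point) {
  if (!is.null(names(point))) {
    if (!all(param$param_names %in% names(point)))
      stop("missing parameter values: ",
           paste(setdiff(param$param_names, names(point)), collapse = ", "))
    point <- unname(point[param$param_names])
  }
  if (length(point) != param$n_params)
    stop("point must assign a value to every parameter")
  point
}

#' Jacobian of the parameterization at a point
#'
#' Rows are coordinates, columns parameters.  Entries are exact partial
#' derivatives; with `p` given all arithmetic is in F_p (point values must
#' be nonzero mod p).
#'
#' @inheritParams evaluate_param
#' @return numeric matrix |G|^(n-1) x m(l+1).
#' @export
param_jacobian <- function(param, point, p = NULL) {
  point <- resolve_point(param, point)
  N <- nrow(param$labellings)
  J <- matrix(0, N, param$n_params)
  inv <- if (!is.null(p))
    vapply(point %% p, function(a) mod_inv(a, p), 0) else NULL
  for (t in seq_along(param$trees)) {
    P <- param$pidx[[t]]
    v <- rep(1, N)
    for (r in seq_len(nrow(P))) {
      v <- v * point[P[r, ]]
      if (!is.null(p)) v <- v %% p
    }
    for (r in seq_len(nrow(P))) {
      idx <- cbind(seq_len(N), P[r, ])
      contrib <- if (is.null(p)) v / point[P[r, ]] else
        (v * inv[P[r, ]]) %% p
      J[idx] <- J[idx] + contrib
      if (!is.null(p)) J[idx] <- J[idx] %% p
    }
  }
  J
}

#' Project (edge, group-element) axes onto (edge, orbit) axes
#'
#' The linear surjection that sums, for every edge, the coefficients of the
#' unit vectors within each B-orbit.  Applied to the exponent vector of a
#' general-model monomial it yields the exponent vector of the same
#' monomial in the (G, B) model; its kernel has dimension (|G| - l - 1) m.
#'
#' @param x vector of length m|G| (edge-major, element index fastest), or a
#'   matrix with that many rows.
#' @param model a `gb_model`; the general-model axes refer to the same group
#'   with trivial action.
#' @param m number of edges.
#' @return vector (or matrix) over m(l+1) axes.
#' @export
orbit_project <- function(x, model, m) {
  g <- model$group$order
  l1 <- model$l + 1L
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  if (nrow(xm) != m * g) stop("expected ", m * g, " rows, got ", nrow(xm))
  tgt <- rep((seq_len(m) - 1L) * l1, each = g) + model$orbit_of
  out <- matrix(0, m * l1, ncol(xm))
  for (i in seq_len(m * g)) out[tgt[i], ] <- out[tgt[i], ] + xm[i, ]
  if (is.matrix(x)) out else drop(out)
}

#' Render a parameterization symbolically in the notation of the literature
#'
#' Produces the generic coordinate of the model as plain text, one monomial
#' per displayed tree: `a<i>^{g<j>+...}` factors ordered by edge number,
#' joined by " + ".  Used for golden-file comparisons against printed maps.
#'
#' @param net an `sdnet` whose edge ids have the form `e<number>`.
#' @return single string.
#' @export
render_parameterization <- function(net) {
  trees <- displayed_trees(net)
  leaf_order <- net$leaf_order
  monos <- vapply(trees, function(tree) {
    sides <- tree_leafsides(net, tree)
    num <- as.integer(sub("^e", "", names(sides)))
    ord <- order(num)
    paste(vapply(ord, function(i) {
      pos <- sort(match(sides[[i]], leaf_order))
      lab <- if (length(pos) == 0L) "0" else
        paste0("g", pos, collapse = "+")
      sprintf("a%d^{%s}", num[i], lab)
    }, ""), collapse = "")
  }, "")
  paste(monos, collapse = " + ")
}

# coordinate keys: concatenated element labels in leaf order
labelling_keys <- function(param) {
  group <- param$model$group
  labs <- element_label(group, seq_len(group$order))
  sep <- if (any(nchar(labs) > max(nchar(labs)[1]))) "," else ""
  apply(param$labellings, 1L, function(r) paste(labs[r], collapse = ""))
}
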