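#' Finite abelian groups as products of cyclic groups
#'
#' A group is specified by its invariant factors: the group is the direct
#' product of cyclic groups of the given orders.  Elements are encoded as
#' tuples of residues (rows of the element matrix) and, interchangeably, as
#' 1-based indices into the lexicographic enumeration of those tuples.  The
#' identity is the all-zero tuple and always has index 1.
#'
#' @param invariant_factors integer vector, each entry at least 2.
#' @return An object of class `gb_group` with fields `factors`, `order`,
#'   `elements` (order x length(factors) matrix of residues), `add`
#'   (order x order index addition table) and `neg` (index negation table).
#' @examples
#' G <- make_group(c(2, 2))   # Klein four-group
#' G$order                    # 4
#' @export
make_group <- function(invariant_factors) {
  f <- as.integer(invariant_factors)
  if (length(f) == 0 || any(is.na(f)) || any(f < 2))
    stop("invalid group: every invariant factor must be an integer >= 2")
  ord <- prod(f)
  # lexicographic enumeration of residue tuples, first coordinate slowest
  grids <- lapply(f, function(k) 0:(k - 1))
  elements <- as.matrix(rev(expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE)))
  dimnames(elements) <- NULL
  storage.mode(elements) <- "integer"
  idx_of <- function(tuples) {
    # tuples: matrix with one row per element
    idx <- rep(0L, nrow(tuples))
    for (j in seq_along(f)) idx <- idx * f[j] + tuples[, j]
    idx + 1L
  }
  add <- matrix(0L, ord, ord)
  for (i in seq_len(ord)) {
    s <- sweep(elements, 2L, elements[i, ], "+") %% rep(f, each = ord)
    add[i, ] <- idx_of(s)
  }
  neg <- idx_of((-elements) %% rep(f, each = ord))
  structure(list(factors = f, order = ord, elements = elements,
                 add = add, neg = neg),
            class = "gb_group")
}

#' @export
print.gb_group <- function(x, ...) {
  cat(sprintf("Abelian group %s of order %d\n",
              paste0("Z/", x$factors, collapse = " x "), x$order))
  invisible(x)
}

element_label <- function(group, idx) {
  apply(group$elements[idx, , drop = FALSE], 1L,
        function(r) paste(r, collapse = if (any(group$factors > 10)) "," else ""))
}

# Fold group addition over the rows of an index matrix: returns, for each
# column, the index of the sum of the column's elements.  An empty matrix
# sums to the identity.
group_sum_idx <- function(group, idx_matrix) {
  n <- ncol(idx_matrix)
  acc <- rep(1L, n)
  for (i in seq_len(nrow(idx_matrix)))
    acc <- group$add[cbind(acc, idx_matrix[i, ])]
  acc
}

#' Automorphism subgroup acting on a finite abelian group
#'
#' The action is supplied as permutations of the element indices
#' (1..`group$order`).  Each generator must fix the identity and commute with
#' group addition; validity is checked by exhaustion.  The stored set is the
#' full subgroup generated by the generators (closure under composition).
#'
#' @param group a `gb_group`.
#' @param generators list of integer permutations of `1:group$order`
#'   (possibly empty for the trivial action).
#' @return Object of class `gb_action` with fields `generators` and `perms`
#'   (matrix, one row per subgroup element, first row the identity).
#' @export
automorphism_action <- function(group, generators = list()) {
  ord <- group$order
  id <- seq_len(ord)
  for (p in generators) {
    p <- as.integer(p)
    if (length(p) != ord || !setequal(p, id))
      stop("invalid action: generator is not a permutation of the element set")
    if (p[1L] != 1L)
      stop("invalid action: automorphisms must fix the identity")
    # sigma(a + b) == sigma(a) + sigma(b) for all a, b
    lhs <- matrix(p[group$add], ord, ord)
    rhs <- group$add[p, p]
    if (!identical(lhs, rhs))
      stop("invalid action: permutation is not a group automorphism")
  }
  perms <- matrix(id, nrow = 1L)
  keys <- paste(id, collapse = ".")
  queue <- list(id)
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (p in generators) {
      nxt <- as.integer(p)[cur]
      k <- paste(nxt, collapse = ".")
      if (!(k %in% keys)) {
        keys <- c(keys, k)
        perms <- rbind(perms, nxt)
        queue <- c(queue, list(nxt))
      }
    }
  }
  dimnames(perms) <- NULL
  structure(list(generators = generators, perms = perms), class = "gb_action")
}

#' Orbits of an automorphism action
#'
#' Partitions the element set into B-orbits and picks the lexicographically
#' smallest tuple of each orbit as its canonical representative, so parameter
#' names are deterministic across runs.  Under the lexicographic element
#' enumeration this is the smallest element index.
#'
#' @param group a `gb_group`.
#' @param action a `gb_action` on `group`.
#' @return list with `orbit_of` (orbit id per element index, orbit 1 is the
#'   identity's singleton orbit), `reps` (element index of each orbit's
#'   representative) and `n_orbits`.
#' @export
compute_orbits <- function(group, action) {
  ord <- group$order
  orbit_of <- integer(ord)
  reps <- integer(0)
  for (i in seq_len(ord)) {
    if (orbit_of[i] != 0L) next
    members <- sort(unique(action$perms[, i]))
    reps <- c(reps, min(members))
    orbit_of[members] <- length(reps)
  }
  list(orbit_of = orbit_of, reps = reps, n_orbits = length(reps))
}

#' Group-based model specification
#'
#' Bundles a finite abelian group G with a subgroup B of Aut(G) and the
#' derived B-orbit structure.  The model has l + 1 = number of B-orbits
#' parameter classes per edge.
#'
#' @param group a `gb_group`.
#' @param action a `gb_action`; defaults to the trivial action, which gives
#'   the general group-based model for G.
#' @param name optional display name.
#' @return Object of class `gb_model` with fields `group`, `action`,
#'   `orbit_of`, `reps`, `l` and `name`.
#' @export
gb_model <- function(group, action = automorphism_action(group), name = NULL) {
  orb <- compute_orbits(group, action)
  if (orb$orbit_of[1L] != 1L || sum(orb$orbit_of == 1L) != 1L)
    stop("internal error: identity orbit is not the singleton {0}")
  structure(list(group = group, action = action,
                 orbit_of = orb$orbit_of, reps = orb$reps,
                 l = orb$n_orbits - 1L,
                 name = if (is.null(name)) "generic" else name),
            class = "gb_model")
}

#' @export
print.gb_model <- function(x, ...) {
  cat(sprintf("Group-based model %s: |G| = %d, %d B-orbits (l = %d)\n",
              x$name, x$group$order, x$l + 1L, x$l))
  invisible(x)
}

#' Named biological models and generic group-based models
#'
#' CFN is the general group-based model for Z/2; K3P the general model for
#' the Klein four-group; JC and K2P are the Klein four-group with the full
#' symmetric group S3 on the nonzero elements, respectively an S2 swapping
#' two nonzero elements.
#'
#' @param name one of "CFN", "JC", "K2P", "K3P", "generic".
#' @param group for `name = "generic"`, the `gb_group` to use with the
#'   trivial action.
#' @return a `gb_model`.
#' @examples
#' named_model("JC")$l    # 1
#' @export
named_model <- function(name, group = NULL) {
  name <- toupper(name)
  klein <- function() make_group(c(2L, 2L))
  # element order of Klein-4: (0,0) (0,1) (1,0) (1,1) -> indices 1..4
  switch(name,
    CFN = gb_model(make_group(2L), name = "CFN"),
    K3P = gb_model(klein(), name = "K3P"),
    JC = {
      g <- klein()
      a <- automorphism_action(g, list(c(1L, 3L, 2L, 4L), c(1L, 2L, 4L, 3L)))
      gb_model(g, a, name = "JC")
    },
    K2P = {
      g <- klein()
      a <- automorphism_action(g, list(c(1L, 3L, 2L, 4L)))
      gb_model(g, a, name = "K2P")
    },
    GENERIC = {
      if (is.null(group)) stop("generic model requires a group")
      gb_model(group, name = "generic")
    },
    stop(sprintf(
      "unknown model '%s'; valid names: CFN, JC, K2P, K3P, generic", name))
  )
}

#' Build a model from a configuration list
#'
#' Accepts either `list(model = "CFN")` (a named model) or
#' `list(group = c(n1, n2, ...), action_generators = list(...))` where each
#' generator is a permutation of the element indices.
#'
#' @param config a list as parsed from JSON/YAML.
#' @return a `gb_model`.
#' @export
model_from_config <- function(config) {
  if (!is.null(config$model)) return(named_model(config$model))
  if (is.null(config$group)) stop("config needs either 'model' or 'group'")
  g <- make_group(unlist(config$group))
  gens <- lapply(config$action_generators %||% list(), as.integer)
  gb_model(g, automorphism_action(g, gens))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
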