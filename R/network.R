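#' Semi-directed level-1 phylogenetic networks
#'
#' A semi-directed network is stored as a mixed graph: tree edges carry an
#' auxiliary orientation (tail -> head) used only to read off edge labels
#' (reversing it negates the label and leaves the model unchanged), while
#' reticulation edges are genuinely directed into their reticulation vertex.
#' Leaves are degree-1 vertices carrying labels.
#'
#' @param vertices character vector of vertex ids.
#' @param edges data.frame with columns `id`, `tail`, `head`, `type`
#'   (`"tree"` or `"ret"`).
#' @param leaves named character vector mapping leaf labels to vertex ids.
#' @param contracted logical; TRUE if the network is in contracted form
#'   (the pendant edge below each reticulation vertex has been contracted).
#' @param leaf_order optional character vector giving the order in which
#'   leaf labels index coordinates; defaults to numeric-aware sorting.
#' @param validate check level-1 validity (default TRUE).
#' @return object of class `sdnet`.
#' @export
sdnet <- function(vertices, edges, leaves, contracted = FALSE,
                  leaf_order = NULL, validate = TRUE) {
  edges <- data.frame(id = as.character(edges$id),
                      tail = as.character(edges$tail),
                      head = as.character(edges$head),
                      type = as.character(edges$type),
                      stringsAsFactors = FALSE)
  net <- structure(list(vertices = as.character(vertices), edges = edges,
                        leaves = leaves, contracted = contracted,
                        leaf_order = leaf_order %||% order_labels(names(leaves))),
                   class = "sdnet")
  if (validate) validate_sdnet(net)
  net
}

order_labels <- function(labels) {
  suppressWarnings(num <- as.numeric(labels))
  labels[order(is.na(num), num, labels)]
}

#' @export
print.sdnet <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf(
    "Level-1 semi-directed network%s: %d leaves, %d edges, %d cycle(s)\n",
    if (x$contracted) " (contracted)" else "", s$n, s$m, s$c))
  invisible(x)
}

ret_vertices <- function(net) {
  sort(unique(net$edges$head[net$edges$type == "ret"]))
}

vertex_degrees <- function(net) {
  tab <- table(c(net$edges$tail, net$edges$head))
  deg <- stats::setNames(integer(length(net$vertices)), net$vertices)
  deg[names(tab)] <- as.integer(tab)
  deg
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("tail", "head")], directed = FALSE,
    vertices = data.frame(name = net$vertices))
}

#' Validate a level-1 semi-directed network
#'
#' Checks connectivity, absence of parallel edges, reticulation in-degrees,
#' the level-1 condition (every cycle of the underlying undirected graph
#' contains exactly one reticulation vertex) and degree constraints.
#'
#' @param net an `sdnet`.
#' @return invisibly TRUE; errors otherwise.
#' @export
validate_sdnet <- function(net) {
  e <- net$edges
  if (anyDuplicated(e$id)) stop("duplicate edge ids")
  key <- apply(cbind(pmin(e$tail, e$head), pmax(e$tail, e$head)), 1, paste,
               collapse = "~")
  if (anyDuplicated(key)) stop("parallel edges are not allowed")
  g <- as_igraph(net)
  if (!igraph::is_connected(g)) stop("network is not connected")
  deg <- vertex_degrees(net)
  rv <- ret_vertices(net)
  leaf_v <- unname(net$leaves)
  # in contracted form a leaf-adjacent reticulation becomes a labelled
  # reticulation vertex of degree 2 (its two incoming reticulation edges)
  bad <- deg[leaf_v] != 1L &
    !(net$contracted & leaf_v %in% rv & deg[leaf_v] == 2L)
  if (any(bad)) stop("leaf vertices must have degree 1")
  unlabelled <- setdiff(names(deg)[deg == 1L], leaf_v)
  if (length(unlabelled)) stop("degree-1 vertex without leaf label: ",
                               paste(unlabelled, collapse = ", "))
  rv <- ret_vertices(net)
  for (v in rv) {
    if (sum(e$type == "ret" & e$head == v) != 2L)
      stop("reticulation vertex ", v,
           " must have exactly 2 incoming reticulation edges")
  }
  if (any(e$type == "ret" & !(e$head %in% rv)))
    stop("reticulation edge pointing at a non-reticulation vertex")
  # level-1: every nontrivial biconnected component is a cycle with exactly
  # one reticulation vertex
  bc <- igraph::biconnected_components(g)
  for (comp in bc$components) {
    vs <- igraph::V(g)$name[as.integer(comp)]
    if (length(vs) < 3L) next
    sub <- igraph::induced_subgraph(g, vs)
    if (igraph::ecount(sub) != length(vs))
      stop("biconnected component is not a simple cycle (level > 1)")
    n_ret <- sum(vs %in% rv)
    if (n_ret != 1L)
      stop(sprintf(
        "cycle through {%s} contains %d reticulation vertices, expected 1",
        paste(vs, collapse = ","), n_ret))
    r <- vs[vs %in% rv]
    in_ret <- e$id[e$type == "ret" & e$head == r]
    on_cycle <- e$tail %in% vs & e$head %in% vs
    if (!all(in_ret %in% e$id[on_cycle]))
      stop("reticulation edges of ", r, " do not both lie on its cycle")
  }
  inner <- setdiff(names(deg)[deg > 1L], rv)
  if (!net$contracted && any(deg[inner] != 3L))
    stop("non-leaf, non-reticulation vertices must have degree 3 ",
         "in the uncontracted form")
  invisible(TRUE)
}

#' Basic counts for a network
#'
#' @param net an `sdnet`.
#' @return list with leaf count `n`, edge count `m`, cycle counts `c`, `c3`,
#'   `c4`, `c_ge5`, reticulation count `k`, the cycle lengths, and whether
#'   the network is contracted.  For an uncontracted binary level-1 network,
#'   m = 2n - 3 + 3c.
#' @export
network_stats <- function(net) {
  g <- as_igraph(net)
  bc <- igraph::biconnected_components(g)
  lens <- integer(0)
  for (comp in bc$components) {
    if (length(comp) >= 3L) lens <- c(lens, length(comp))
  }
  list(n = length(net$leaves), m = nrow(net$edges), c = length(lens),
       c3 = sum(lens == 3L), c4 = sum(lens == 4L), c_ge5 = sum(lens >= 5L),
       k = length(ret_vertices(net)), cycle_lengths = lens,
       contracted = net$contracted)
}

#' Sunlet networks
#'
#' An n-sunlet is the level-1 network with a single cycle of length n, one
#' pendant leaf per cycle vertex, and leaf 1 at the reticulation vertex.
#' Edges are numbered e1..en for the leaf edges and e(n+1)..e(2n) around the
#' cycle, with e(n+1) and e(2n) the reticulation edges.  With
#' `contracted = TRUE` the pendant edge at the reticulation is contracted so
#' leaf 1 sits on the cycle; edges are then e1 and e(n+1) for the
#' reticulation edges, e2..en for the remaining leaf edges and
#' e(n+2)..e(2n-1) for the other cycle edges.
#'
#' @param n number of leaves, at least 3.
#' @param contracted build the contracted form directly.
#' @return an `sdnet`.
#' @examples
#' network_stats(make_sunlet(4))$m   # 8
#' @export
make_sunlet <- function(n, contracted = FALSE) {
  if (n < 3) stop("a sunlet needs at least 3 leaves")
  n <- as.integer(n)
  if (!contracted) {
    vs <- c(paste0("v", 1:n), paste0("x", 1:n))
    ed <- data.frame(
      id = paste0("e", 1:(2L * n)),
      tail = c(paste0("v", 1:n),            # leaf edges
               "v2",                         # e(n+1): ret edge v2 -> v1
               if (n > 3) paste0("v", 3:(n - 1)) else character(0),
               if (n > 3) paste0("v", n - 1) else "v2",
               paste0("v", n)),              # e(2n): ret edge vn -> v1
      head = c(paste0("x", 1:n),
               "v1",
               if (n > 3) paste0("v", 2:(n - 2)) else character(0),
               paste0("v", n),
               "v1"),
      type = c(rep("tree", n), "ret", rep("tree", n - 2L), "ret"),
      stringsAsFactors = FALSE)
    # middle cycle edges e(n+2)..e(2n-2) point towards the reticulation side
    # (head v_{j+1}); the last cycle edge e(2n-1) points towards vn, matching
    # the orientation used to read off printed edge labellings
    if (n == 3) {
      ed <- ed[ed$id != "e0", ]
      ed$tail[ed$id == "e5"] <- "v2"; ed$head[ed$id == "e5"] <- "v3"
    }
    leaves <- stats::setNames(paste0("x", 1:n), as.character(1:n))
    sdnet(vs, ed, leaves)
  } else {
    # leaf 1 is the reticulation vertex u1 on the cycle
    vs <- c(paste0("u", 1:n), paste0("x", 2:n))
    ids <- paste0("e", 1:(2L * n - 1L))
    tails <- character(2L * n - 1L); heads <- character(2L * n - 1L)
    types <- rep("tree", 2L * n - 1L)
    tails[1] <- "u2"; heads[1] <- "u1"; types[1] <- "ret"
    for (i in 2:n) { tails[i] <- paste0("u", i); heads[i] <- paste0("x", i) }
    tails[n + 1L] <- paste0("u", n); heads[n + 1L] <- "u1"
    types[n + 1L] <- "ret"
    if (n > 3) {
      for (j in 1:(n - 3L)) {
        tails[n + 1L + j] <- paste0("u", j + 2L)
        heads[n + 1L + j] <- paste0("u", j + 1L)
      }
    }
    tails[2L * n - 1L] <- paste0("u", n - 1L); heads[2L * n - 1L] <- paste0("u", n)
    if (n == 3) { tails[5] <- "u2"; heads[5] <- "u3" }
    ed <- data.frame(id = ids, tail = tails, head = heads, type = types,
                     stringsAsFactors = FALSE)
    leaves <- stats::setNames(c("u1", paste0("x", 2:n)), as.character(1:n))
    sdnet(vs, ed, leaves, contracted = TRUE)
  }
}

#' Contract a level-1 network
#'
#' Contracts the non-reticulation (outgoing) edge of each reticulation
#' vertex.  Edge count drops by the number of cycles; distinct reticulation
#' vertices are never merged; the operation is idempotent and leaves the
#' model variety unchanged.
#'
#' @param net an `sdnet`.
#' @return a contracted `sdnet`.
#' @export
contract <- function(net) {
  e <- net$edges
  rv <- ret_vertices(net)
  for (v in rv) {
    out <- which(e$type != "ret" & (e$tail == v | e$head == v))
    if (length(out) == 0L) next  # already contracted at this vertex
    if (length(out) != 1L)
      stop("reticulation vertex ", v, " has ", length(out),
           " non-reticulation edges; cannot contract")
    other <- if (e$tail[out] == v) e$head[out] else e$tail[out]
    e <- e[-out, , drop = FALSE]
    e$tail[e$tail == v] <- other
    e$head[e$head == v] <- other
    net$vertices <- setdiff(net$vertices, v)
    net$leaves[net$leaves == v] <- other
  }
  sdnet(net$vertices, e, net$leaves, contracted = TRUE,
        leaf_order = net$leaf_order)
}

#' Displayed trees of a level-1 network
#'
#' Removing one reticulation edge per reticulation vertex yields a tree; the
#' choice is encoded by a binary vector sigma with one bit per reticulation
#' vertex (vertices sorted by id).  Bit 0 keeps the first-listed reticulation
#' edge of that vertex.  Trees are returned in lexicographic sigma order, so
#' the first displayed tree keeps the lower-numbered reticulation edges.
#'
#' @param net an `sdnet`.
#' @return list of `displayed_tree` objects, each with fields `sigma`,
#'   `edges` (retained edge ids) and `removed`.
#' @export
displayed_trees <- function(net) {
  rv <- ret_vertices(net)
  k <- length(rv)
  ret_pairs <- lapply(rv, function(v)
    net$edges$id[net$edges$type == "ret" & net$edges$head == v])
  sigmas <- if (k == 0L) matrix(integer(0), nrow = 1L) else
    as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  # expand.grid varies the first factor fastest; reversing columns gives
  # lexicographic order in (sigma_1, ..., sigma_k)
  sigmas <- sigmas[order(apply(sigmas, 1L, paste, collapse = "")), ,
                   drop = FALSE]
  out <- vector("list", nrow(sigmas))
  for (s in seq_len(nrow(sigmas))) {
    sigma <- as.integer(sigmas[s, ])
    removed <- character(0)
    for (i in seq_len(k))
      removed <- c(removed, ret_pairs[[i]][2L - (sigma[i] == 1L)])
    # sigma_i = 0 removes the second-listed edge (keeps the first-listed)
    keep <- setdiff(net$edges$id, removed)
    out[[s]] <- structure(list(sigma = sigma, edges = keep, removed = removed),
                          class = "displayed_tree")
  }
  out
}

# adjacency of a displayed tree as list vertex -> data.frame(edge, other)
tree_adjacency <- function(net, tree) {
  e <- net$edges[net$edges$id %in% tree$edges, ]
  adj <- list()
  for (i in seq_len(nrow(e))) {
    adj[[e$tail[i]]] <- rbind(adj[[e$tail[i]]],
                              data.frame(edge = e$id[i], other = e$head[i]))
    adj[[e$head[i]]] <- rbind(adj[[e$head[i]]],
                              data.frame(edge = e$id[i], other = e$tail[i]))
  }
  adj
}

# for each retained edge, the leaf labels on the head (arrow) side
tree_leafsides <- function(net, tree) {
  e <- net$edges[match(tree$edges, net$edges$id), ]
  adj <- tree_adjacency(net, tree)
  leaf_of_vertex <- stats::setNames(names(net$leaves), unname(net$leaves))
  sides <- vector("list", nrow(e))
  names(sides) <- e$id
  for (i in seq_len(nrow(e))) {
    # BFS from head without crossing the edge itself
    seen <- e$head[i]; queue <- e$head[i]
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]]
      if (is.null(nb)) next
      nb <- nb[nb$edge != e$id[i], , drop = FALSE]
      new <- setdiff(nb$other, seen)
      seen <- c(seen, new); queue <- c(queue, new)
    }
    lv <- seen[seen %in% unname(net$leaves)]
    sides[[i]] <- unname(leaf_of_vertex[lv])
  }
  sides
}

#' Consistent leaf labellings
#'
#' Enumerates all assignments of group elements to n leaves whose sum is the
#' identity.  There are exactly |G|^(n-1) of them; the first n - 1 leaves
#' range lexicographically and the last is determined.
#'
#' @param n number of leaves.
#' @param group a `gb_group`.
#' @return integer matrix with |G|^(n-1) rows and n columns of element
#'   indices (1-based; index 1 is the identity).
#' @export
consistent_labellings <- function(n, group) {
  ord <- group$order
  if (n == 1L) return(matrix(1L, 1L, 1L))
  free <- as.matrix(rev(expand.grid(rev(rep(list(seq_len(ord)), n - 1L)),
                                    KEEP.OUT.ATTRS = FALSE)))
  dimnames(free) <- NULL
  last <- group$neg[group_sum_idx(group, t(free))]
  cbind(free, last)
}

#' Edge labelling induced by a leaf labelling
#'
#' For each edge of a displayed tree, the label is the sum of the leaf
#' labels on the arrow (head) side of the edge.
#'
#' @param net an `sdnet`.
#' @param tree a `displayed_tree` of `net`.
#' @param leaf_labels named integer vector of element indices, one per leaf
#'   label of the network.
#' @param group the `gb_group` the labels live in.
#' @return named integer vector of element indices, one per retained edge.
#' @export
induced_edge_labelling <- function(net, tree, leaf_labels, group) {
  if (group_sum_idx(group, matrix(leaf_labels, ncol = 1L)) != 1L)
    stop("leaf labelling is not consistent (labels do not sum to identity)")
  sides <- tree_leafsides(net, tree)
  out <- stats::setNames(integer(length(sides)), names(sides))
  for (eid in names(sides)) {
    s <- sides[[eid]]
    out[eid] <- if (length(s) == 0L) 1L else
      group_sum_idx(group, matrix(leaf_labels[s], ncol = 1L))
  }
  out
}

#' Flip the auxiliary orientation of a tree edge
#'
#' Swaps tail and head of a non-reticulation edge.  By the reorientation
#' invariance of the model this changes only the pairing g <-> -g of that
#' edge's parameters and leaves the variety (and generic Jacobian rank)
#' unchanged.
#'
#' @param net an `sdnet`.
#' @param edge_id edge to flip.
#' @return the modified `sdnet`.
#' @export
flip_edge <- function(net, edge_id) {
  i <- match(edge_id, net$edges$id)
  if (is.na(i)) stop("unknown edge ", edge_id)
  if (net$edges$type[i] == "ret")
    stop("cannot reorient a reticulation edge")
  tmp <- net$edges$tail[i]
  net$edges$tail[i] <- net$edges$head[i]
  net$edges$head[i] <- tmp
  net
}

#' Cut a network at a cut edge
#'
#' Cutting at a non-reticulation cut edge e yields two smaller level-1
#' networks N+ and N-.  Each piece gains a new leaf named `ne` attached by a
#' copy of e; N+ is the side the stored orientation of e points into.  Edge
#' counts satisfy m = m+ + m- - 1 and cycle counts add.
#'
#' @param net an `sdnet`.
#' @param edge_id the cut edge.
#' @return list with `plus`, `minus` (both `sdnet`), and `cut_leaf = "ne"`.
#'   In `plus` the cut leaf is ordered last; in `minus`, first.
#' @export
cut_at <- function(net, edge_id) {
  i <- match(edge_id, net$edges$id)
  if (is.na(i)) stop("unknown edge ", edge_id)
  if (net$edges$type[i] == "ret") stop("cannot cut at a reticulation edge")
  rest <- net$edges[-i, ]
  g <- igraph::graph_from_data_frame(rest[, c("tail", "head")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$vertices))
  comp <- igraph::components(g)
  if (comp$no != 2L) stop("edge ", edge_id, " is not a cut edge")
  memb <- stats::setNames(comp$membership, igraph::V(g)$name)
  side_of <- function(v) memb[[v]]
  plus_side <- side_of(net$edges$head[i])
  piece <- function(side, cut_first) {
    vs <- names(memb)[memb == side]
    ed <- rest[rest$tail %in% vs & rest$head %in% vs, ]
    lv <- net$leaves[net$leaves %in% vs]
    nl <- "ne_v"
    if (side == plus_side) {
      ed <- rbind(ed, data.frame(id = edge_id, tail = nl,
                                 head = net$edges$head[i], type = "tree"))
    } else {
      ed <- rbind(ed, data.frame(id = edge_id, tail = net$edges$tail[i],
                                 head = nl, type = "tree"))
    }
    lv <- c(lv, stats::setNames(nl, "ne"))
    ord <- order_labels(setdiff(names(lv), "ne"))
    lo <- if (cut_first) c("ne", ord) else c(ord, "ne")
    sdnet(c(vs, nl), ed, lv, contracted = net$contracted, leaf_order = lo)
  }
  list(plus = piece(plus_side, cut_first = FALSE),
       minus = piece(setdiff(1:2, plus_side), cut_first = TRUE),
       cut_leaf = "ne", edge = edge_id)
}

#' Restrict a network to a subset of its leaves
#'
#' Deletes the leaves outside the set together with their pendant edges,
#' removes any reticulation vertex left with no leaf below it together with
#' both reticulation edges, and suppresses degree-2 vertices (merging a
#' reticulation edge with a tree edge keeps the reticulation direction).
#'
#' @param net an `sdnet`.
#' @param leafset character (or numeric) vector of leaf labels to keep.
#' @return an `sdnet` on the restricted leaf set.
#' @export
restrict_net <- function(net, leafset) {
  leafset <- as.character(leafset)
  if (length(leafset) == 0L) stop("leafset must be nonempty")
  if (!all(leafset %in% names(net$leaves)))
    stop("unknown leaf labels: ",
         paste(setdiff(leafset, names(net$leaves)), collapse = ", "))
  e <- net$edges
  vs <- net$vertices
  lv <- net$leaves[names(net$leaves) %in% leafset]
  fresh <- 0L
  repeat {
    deg <- table(c(e$tail, e$head))
    degree <- function(v) if (v %in% names(deg)) as.integer(deg[[v]]) else 0L
    changed <- FALSE
    # prune unlabelled pendant vertices
    pend <- vs[vapply(vs, degree, 1L) <= 1L & !(vs %in% unname(lv))]
    if (length(pend)) {
      e <- e[!(e$tail %in% pend | e$head %in% pend), ]
      vs <- setdiff(vs, pend)
      changed <- TRUE
    }
    # reticulation vertex with no leaf below it: only its two ret in-edges
    # remain; delete vertex and both edges
    rvs <- unique(e$head[e$type == "ret"])
    for (v in rvs) {
      inc <- which(e$tail == v | e$head == v)
      if (length(inc) == 2L && all(e$type[inc] == "ret") &&
          all(e$head[inc] == v) && !(v %in% unname(lv))) {
        e <- e[-inc, ]
        vs <- setdiff(vs, v)
        changed <- TRUE
      }
    }
    # suppress degree-2 vertices (never a live reticulation vertex: those
    # keep indegree 2 plus a live subtree, or were deleted above)
    deg <- table(c(e$tail, e$head))
    two <- vs[vapply(vs, function(v)
      (if (v %in% names(deg)) as.integer(deg[[v]]) else 0L) == 2L, TRUE) &
      !(vs %in% unname(lv))]
    two <- setdiff(two, unique(e$head[e$type == "ret"]))
    for (v in two) {
      inc <- which(e$tail == v | e$head == v)
      if (length(inc) != 2L) next
      e1 <- e[inc[1L], ]; e2 <- e[inc[2L], ]
      fresh <- fresh + 1L
      is_ret <- c(e1$type, e2$type) == "ret"
      if (all(is_ret)) next  # both in-edges of a ret vertex: handled above
      if (any(is_ret)) {
        r <- if (is_ret[1L]) e1 else e2
        o <- if (is_ret[1L]) e2 else e1
        other <- if (o$tail == v) o$head else o$tail
        new <- data.frame(id = paste0("r", fresh), tail = other,
                          head = r$head, type = "ret")
      } else {
        a <- if (e1$tail == v) e1$head else e1$tail
        b <- if (e2$tail == v) e2$head else e2$tail
        # orient along the path if the stored orientations agree
        if (e1$head == v && e2$tail == v)
          new <- data.frame(id = paste0("r", fresh), tail = a, head = b,
                            type = "tree")
        else if (e2$head == v && e1$tail == v)
          new <- data.frame(id = paste0("r", fresh), tail = b, head = a,
                            type = "tree")
        else
          new <- data.frame(id = paste0("r", fresh), tail = a, head = b,
                            type = "tree")
      }
      e <- rbind(e[-inc, ], new)
      vs <- setdiff(vs, v)
      changed <- TRUE
      break  # degrees changed; recompute
    }
    if (!changed) break
  }
  sdnet(vs, e, lv, contracted = net$contracted)
}

#' Splits (leaf bipartitions) of a network's internal tree edges
#'
#' Used to compare unrooted tree topologies: two binary trees on the same
#' leaf set are equal iff their split sets are equal.
#'
#' @param net an `sdnet` (typically a tree).
#' @return character vector of canonical split strings.
#' @export
tree_splits <- function(net) {
  trees <- displayed_trees(net)
  tree <- trees[[1L]]
  sides <- tree_leafsides(net, tree)
  all_lv <- names(net$leaves)
  out <- character(0)
  for (eid in names(sides)) {
    s <- sides[[eid]]
    if (length(s) <= 1L || length(s) >= length(all_lv) - 1L) next
    a <- sort(s); b <- sort(setdiff(all_lv, s))
    canon <- if (paste(a, collapse = ",") < paste(b, collapse = ","))
      a else b
    out <- c(out, paste(canon, collapse = ","))
  }
  sort(unique(out))
}

#' Random level-1 network generator
#'
#' Builds a random unrooted binary tree on n leaves by sequential leaf
#' insertion, then blows up c disjoint paths of internal edges into cycles
#' of length at least `min_cycle_len`, choosing a random cycle vertex as the
#' reticulation.  The result is a valid uncontracted level-1 network with
#' 2n - 3 + 3c edges; identical seeds give identical networks.
#'
#' @param n number of leaves (>= 3).
#' @param c number of cycles (>= 0).
#' @param min_cycle_len minimum cycle length (>= 3).
#' @param seed integer seed.
#' @return an `sdnet`.
#' @export
random_level1 <- function(n, c = 0L, min_cycle_len = 4L, seed = 1L) {
  if (n < 3) stop("need n >= 3")
  if (min_cycle_len < 3) stop("min_cycle_len must be >= 3")
  last_err <- NULL
  for (attempt in 0:49) {
    net <- tryCatch(random_level1_once(n, c, min_cycle_len,
                                       seed + 7919L * attempt),
                    error = function(e) { last_err <<- e; NULL })
    if (!is.null(net)) return(net)
  }
  stop("parameters do not admit a level-1 network (last error: ",
       conditionMessage(last_err), ")")
}

random_level1_once <- function(n, c, min_cycle_len, seed) {
  set.seed(seed)
  # random binary tree via edge subdivision
  eid <- 0L
  new_edge <- function(tail, head) {
    eid <<- eid + 1L
    data.frame(id = paste0("e", eid), tail = tail, head = head, type = "tree")
  }
  e <- rbind(new_edge("i1", "L1"), new_edge("i1", "L2"), new_edge("i1", "L3"))
  vs <- c("i1", "L1", "L2", "L3")
  n_int <- 1L
  for (k in seq_len(n - 3L)) {
    pick <- sample.int(nrow(e), 1L)
    n_int <- n_int + 1L
    v <- paste0("i", n_int)
    leaf <- paste0("L", 3L + k)
    old <- e[pick, ]
    e <- rbind(e[-pick, ], new_edge(old$tail, v), new_edge(v, old$head),
               new_edge(v, leaf))
    vs <- c(vs, v, leaf)
  }
  used <- character(0)
  cyc <- 0L
  for (ci in seq_len(c)) {
    L <- min_cycle_len
    placed <- FALSE
    for (attempt in 1:200) {
      internal <- function(v) !startsWith(v, "L")
      cand <- vs[vapply(vs, internal, TRUE) & !(vs %in% used)]
      if (length(cand) == 0L) break
      path <- sample(cand, 1L)
      ok <- TRUE
      while (length(path) < L - 2L) {
        v <- path[length(path)]
        nb <- unique(c(e$head[e$tail == v], e$tail[e$head == v]))
        nb <- nb[vapply(nb, internal, TRUE) & !(nb %in% used) &
                   !(nb %in% path)]
        if (length(nb) == 0L) { ok <- FALSE; break }
        path <- c(path, sample(nb, 1L))
      }
      if (!ok) next
      # contract the path into one vertex, then blow up into an L-cycle
      w <- path[1L]
      if (length(path) > 1L) {
        drop <- (e$tail %in% path & e$head %in% path)
        e <- e[!drop, ]
        e$tail[e$tail %in% path] <- w
        e$head[e$head %in% path] <- w
        vs <- setdiff(vs, path[-1L])
      }
      inc <- which(e$tail == w | e$head == w)
      if (length(inc) != L) next
      cyc <- cyc + 1L
      cvs <- paste0("c", cyc, "_", seq_len(L))
      ord <- sample(inc)      # which hanging edge attaches where
      for (j in seq_len(L)) {
        i <- ord[j]
        if (e$tail[i] == w) e$tail[i] <- cvs[j] else e$head[i] <- cvs[j]
      }
      r <- sample.int(L, 1L)   # reticulation position
      for (j in seq_len(L)) {
        a <- cvs[j]; b <- cvs[if (j == L) 1L else j + 1L]
        is_ret <- (j == r || (if (j == L) 1L else j + 1L) == r)
        ret_head <- cvs[r]
        if (is_ret) {
          tl <- if (a == ret_head) b else a
          e <- rbind(e, data.frame(id = paste0("e", eid <- eid + 1L),
                                   tail = tl, head = ret_head, type = "ret"))
        } else {
          e <- rbind(e, data.frame(id = paste0("e", eid <- eid + 1L),
                                   tail = a, head = b, type = "tree"))
        }
      }
      vs <- c(setdiff(vs, w), cvs)
      used <- c(used, cvs)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place cycle ", ci,
           ": parameters do not admit a level-1 network")
  }
  leaves <- stats::setNames(paste0("L", 1:n), as.character(1:n))
  net <- sdnet(vs, e, leaves, validate = FALSE)
  net <- orient_from_leaf1(net)
  validate_sdnet(net)
  net
}

# orient every tree edge away from leaf 1 (BFS); reticulation edges keep
# their stored direction
orient_from_leaf1 <- function(net) {
  start <- unname(net$leaves[[net$leaf_order[1L]]])
  e <- net$edges
  seen <- start; queue <- start
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    inc <- which(e$tail == v | e$head == v)
    for (i in inc) {
      other <- if (e$tail[i] == v) e$head[i] else e$tail[i]
      if (other %in% seen) next
      if (e$type[i] == "tree" && e$head[i] != other) {
        e$head[i] <- other; e$tail[i] <- v
      }
      seen <- c(seen, other); queue <- c(queue, other)
    }
  }
  net$edges <- e
  net
}
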