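test_that("sunlet construction matches the stated counts", {
  s4 <- make_sunlet(4)
  st <- network_stats(s4)
  expect_equal(st$m, 8L)
  expect_equal(st$c, 1L)
  expect_equal(st$c4, 1L)
  s5 <- network_stats(make_sunlet(5))
  expect_equal(s5$m, 10L)
  expect_equal(s5$c_ge5, 1L)
  expect_equal(network_stats(contract(s4))$m, 7L)
  expect_error(make_sunlet(2), "at least 3")
  # contracted n-sunlet has 2n - 1 edges directly
  expect_equal(network_stats(make_sunlet(6, contracted = TRUE))$m, 11L)
})

test_that("contract removes one edge per cycle, never merges reticulations,
           and is idempotent", {
  for (n in 3:5) {
    s <- make_sunlet(n)
    cs <- contract(s)
    expect_equal(nrow(cs$edges), nrow(s$edges) - 1L)
    expect_equal(length(ret_vertices <- unique(
      cs$edges$head[cs$edges$type == "ret"])), 1L)
    expect_identical(contract(cs)$edges, cs$edges)
  }
  net <- random_level1(6, 2, 4, seed = 2)
  expect_equal(nrow(contract(net)$edges), nrow(net$edges) - 2L)
  # a tree is unchanged
  tr <- random_level1(5, 0, 4, seed = 3)
  expect_equal(nrow(contract(tr)$edges), nrow(tr$edges))
})

test_that("edge counts obey m = 2n - 3 + 3c on random fixtures", {
  cases <- list(c(6, 1, 4), c(6, 2, 4), c(5, 0, 4), c(7, 1, 5), c(5, 1, 3))
  for (cs in cases) {
    net <- random_level1(cs[1], cs[2], cs[3], seed = sum(cs))
    st <- network_stats(net)
    expect_equal(st$m, 2L * cs[1] - 3L + 3L * cs[2])
    expect_equal(st$c, cs[2])
    expect_true(all(st$cycle_lengths >= cs[3]))
    expect_equal(network_stats(contract(net))$m, st$m - st$c)
  }
  expect_identical(random_level1(7, 1, 5, seed = 11),
                   random_level1(7, 1, 5, seed = 11))
})

test_that("level-1 validation rejects a cycle with two reticulations", {
  # square v1-v2-v3-v4 with two reticulation vertices on one cycle
  ed <- data.frame(
    id = paste0("e", 1:8),
    tail = c("v1", "v2", "v3", "v4", "v2", "v2", "v4", "v4"),
    head = c("x1", "x2", "x3", "x4", "v1", "v3", "v3", "v1"),
    type = c(rep("tree", 4), "ret", "ret", "ret", "ret"))
  expect_error(
    sdnet(c(paste0("v", 1:4), paste0("x", 1:4)), ed,
          stats::setNames(paste0("x", 1:4), 1:4)),
    "reticulation vertices")
})

test_that("displayed trees are spanning trees, 2^k of them, ordered by sigma", {
  s4 <- make_sunlet(4)
  tr <- displayed_trees(s4)
  expect_length(tr, 2L)
  # sigma = 0 keeps the lower-numbered reticulation edge e5 (removes e8)
  expect_equal(tr[[1]]$removed, "e8")
  expect_equal(tr[[2]]$removed, "e5")
  net <- random_level1(6, 2, 4, seed = 5)
  trs <- displayed_trees(net)
  expect_length(trs, 4L)
  nv <- length(net$vertices)
  g_all <- igraph::graph_from_data_frame(
    net$edges[, c("tail", "head")], directed = FALSE)
  for (t in trs) {
    expect_length(t$edges, nv - 1L)
    sub <- igraph::subgraph_from_edges(
      g_all, which(net$edges$id %in% t$edges), delete.vertices = FALSE)
    expect_true(igraph::is_connected(sub))
  }
})

test_that("consistent labellings have size |G|^(n-1) and sum to identity", {
  z2 <- make_group(2)
  expect_equal(nrow(consistent_labellings(4, z2)), 8L)
  expect_equal(nrow(consistent_labellings(3, z2)), 4L)
  z3 <- make_group(3)
  labs <- consistent_labellings(4, z3)
  expect_equal(nrow(labs), 27L)
  sums <- netvardim:::group_sum_idx(z3, t(labs))
  expect_true(all(sums == 1L))
  expect_equal(anyDuplicated(labs), 0L)
})

test_that("induced edge labels sum the leaf labels on the arrow side", {
  z5 <- make_group(5)
  s4 <- make_sunlet(4)
  trees <- displayed_trees(s4)
  # leaf labels g1..g4 as element indices; g4 makes the sum vanish
  g <- c(2L, 3L, 4L, 1L)
  g[4] <- z5$neg[netvardim:::group_sum_idx(z5, matrix(g[1:3], ncol = 1))]
  lv <- stats::setNames(g, as.character(1:4))
  lab1 <- induced_edge_labelling(s4, trees[[1]], lv, z5)
  expect_equal(unname(lab1["e6"]), z5$add[g[1], g[2]])  # g1 + g2
  expect_equal(unname(lab1["e7"]), g[4])                # g4
  lab2 <- induced_edge_labelling(s4, trees[[2]], lv, z5)
  expect_equal(unname(lab2["e6"]), g[2])                # g2
  expect_equal(unname(lab2["e7"]), z5$add[g[1], g[4]])  # g1 + g4
  # all-identity labelling labels every edge with the identity
  lv0 <- stats::setNames(rep(1L, 4), as.character(1:4))
  expect_true(all(induced_edge_labelling(s4, trees[[1]], lv0, z5) == 1L))
  # inconsistent labelling errors
  expect_error(
    induced_edge_labelling(s4, trees[[1]],
                           stats::setNames(c(2L, 1L, 1L, 1L), 1:4), z5),
    "not consistent")
})

test_that("cutting at a cut edge splits leaves, edges and cycles", {
  fig3 <- fig3_network()
  cut <- cut_at(fig3, "e")
  sp <- network_stats(cut$plus); sm <- network_stats(cut$minus)
  expect_equal(sp$n, 4L); expect_equal(sp$m, 8L); expect_equal(sp$c, 1L)
  expect_equal(sm$n, 4L); expect_equal(sm$m, 5L); expect_equal(sm$c, 0L)
  expect_equal(sp$m + sm$m - 1L, network_stats(fig3)$m)
  expect_equal(sp$c + sm$c, network_stats(fig3)$c)
  expect_setequal(c(setdiff(names(cut$plus$leaves), "ne"),
                    setdiff(names(cut$minus$leaves), "ne")),
                  names(fig3$leaves))
  expect_error(cut_at(fig3, "e6"), "not a cut edge")
  expect_error(cut_at(fig3, "e5"), "reticulation")
})

test_that("restriction follows the delete-then-simplify semantics", {
  for (n in 4:6) {
    sun <- make_sunlet(n)
    # away from the reticulation leaf: caterpillar tree on n-1 leaves
    cat_tree <- restrict_net(sun, as.character(2:n))
    st <- network_stats(cat_tree)
    expect_equal(st$c, 0L)
    expect_equal(st$m, 2L * (n - 1L) - 3L)
    # away from a non-reticulation leaf: (n-1)-sunlet
    small <- restrict_net(sun, as.character(c(1, 3:n)))
    st2 <- network_stats(small)
    expect_equal(st2$c, 1L)
    expect_equal(st2$m, 2L * (n - 1L))
  }
  s5 <- make_sunlet(5)
  full <- restrict_net(s5, as.character(1:5))
  expect_equal(network_stats(full)$m, 10L)
  # restrict then restrict equals restrict to the intersection
  tr <- random_level1(7, 0, 4, seed = 8)
  a <- restrict_net(restrict_net(tr, as.character(1:6)), as.character(1:5))
  b <- restrict_net(tr, as.character(1:5))
  expect_identical(tree_splits(a), tree_splits(b))
  expect_equal(network_stats(a)$m, network_stats(b)$m)
  expect_error(restrict_net(s5, character(0)), "nonempty")
})
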