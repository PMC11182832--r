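test_that("the 4-sunlet parameterization reproduces the printed map", {
  expect_identical(
    render_parameterization(fig1_sunlet()),
    paste0("a1^{g1}a2^{g2}a3^{g3}a4^{g4}a5^{g1}a6^{g1+g2}a7^{g4}",
           " + ",
           "a1^{g1}a2^{g2}a3^{g3}a4^{g4}a6^{g2}a7^{g1+g4}a8^{g1}"))
})

test_that("coordinate, monomial and degree counts match the closed forms", {
  cases <- list(list(make_sunlet(4), models$z3),
                list(make_sunlet(5), models$cfn),
                list(random_level1(6, 2, 4, seed = 5), models$cfn),
                list(random_level1(5, 0, 4, seed = 5), models$k2p))
  for (cs in cases) {
    net <- cs[[1]]; model <- cs[[2]]
    st <- network_stats(net)
    p <- build_parameterization(net, model)
    expect_equal(nrow(p$labellings), model$group$order^(st$n - 1L))
    expect_length(p$trees, 2L^st$k)
    expect_equal(p$n_params, st$m * (model$l + 1L))
    # per-monomial degree = edge count of the displayed tree
    for (t in seq_along(p$trees))
      expect_equal(nrow(p$pidx[[t]]), length(p$trees[[t]]$edges))
  }
})

test_that("the contracted sunlet map has the stated structure", {
  # independent oracle: the closed-form exponents of the two monomials
  n <- 5
  z5 <- make_group(5)
  model <- gb_model(z5)
  net <- make_sunlet(n, contracted = TRUE)
  p <- build_parameterization(net, model)
  labs <- p$labellings  # columns ordered by leaf 1..n
  add <- function(a, b) z5$add[cbind(a, b)]
  for (j in sample(nrow(labs), 10)) {
    g <- labs[j, ]
    # tree 1 (keeps e1): a1^{g1}, a_i^{g_i}, a_{n+j+1}^{g1+...+g_{j+1}},
    # a_{2n-1}^{g_n}
    exp1 <- stats::setNames(integer(0), character(0))
    exp1[paste0("e1^", g[1])] <- 1L
    for (i in 2:n) exp1[paste0("e", i, "^", g[i])] <- 1L
    run <- g[1]
    for (jj in 1:(n - 3)) {
      run <- add(run, g[jj + 1])
      exp1[paste0("e", n + 1 + jj, "^", run)] <- 1L
    }
    exp1[paste0("e", 2 * n - 1, "^", g[n])] <- 1L
    got1 <- table(paste0(p$edge_ids[(p$pidx[[1]][, j] - 1) %/%
                                      (model$l + 1) + 1], "^",
                         (p$pidx[[1]][, j] - 1) %% (model$l + 1) + 1))
    oracle1 <- table(names(exp1))
    expect_identical(sort(names(got1)), sort(names(oracle1)))
    # tree 2 (keeps e_{n+1}): a_{n+1}^{g1}, a_i^{g_i}, a_{n+2}^{g2}, ...,
    # a_{2n-1}^{g1+g_n}
    exp2 <- character(0)
    exp2 <- c(exp2, paste0("e", n + 1, "^", g[1]))
    for (i in 2:n) exp2 <- c(exp2, paste0("e", i, "^", g[i]))
    run <- 1L
    for (jj in 1:(n - 3)) {
      run <- add(run, g[jj + 1])
      exp2 <- c(exp2, paste0("e", n + 1 + jj, "^", run))
    }
    exp2 <- c(exp2, paste0("e", 2 * n - 1, "^", add(g[1], g[n])))
    got2 <- paste0(p$edge_ids[(p$pidx[[2]][, j] - 1) %/% (model$l + 1) + 1],
                   "^", (p$pidx[[2]][, j] - 1) %% (model$l + 1) + 1)
    expect_setequal(got2, exp2)
  }
})

test_that("evaluation: all-ones gives 2^k; missing parameters error", {
  for (net in list(make_sunlet(4), random_level1(6, 2, 4, seed = 1),
                   random_level1(5, 0, 4, seed = 1))) {
    p <- build_parameterization(net, models$cfn)
    k <- network_stats(net)$k
    expect_equal(unique(evaluate_param(p, rep(1, p$n_params))), 2^k)
  }
  p <- build_parameterization(make_sunlet(3), models$cfn)
  expect_error(evaluate_param(p, rep(1, 3)), "every parameter")
})

test_that("contracting a sunlet is a reparameterization", {
  n <- 4
  model <- models$z3
  net <- make_sunlet(n)
  cnet <- contract(net)   # keeps edge ids e2..e8
  p <- build_parameterization(net, model)
  pc <- build_parameterization(cnet, model)
  set.seed(42)
  w <- stats::setNames(sample(2:50, p$n_params, replace = TRUE),
                       p$param_names)
  u <- w[pc$param_names]
  # fold the contracted pendant-edge parameters into both reticulation edges
  for (g in seq_len(model$l + 1)) {
    lab <- netvardim:::element_label(model$group, model$reps[g])
    u[paste0("e", n + 1, "^", lab)] <-
      w[paste0("e1^", lab)] * w[paste0("e", n + 1, "^", lab)]
    u[paste0("e", 2 * n, "^", lab)] <-
      w[paste0("e1^", lab)] * w[paste0("e", 2 * n, "^", lab)]
  }
  expect_equal(evaluate_param(p, w), evaluate_param(pc, u))
})

test_that("killing one tree's private reticulation edge leaves the other
           monomial", {
  p <- build_parameterization(make_sunlet(4), models$cfn)
  set.seed(1)
  w <- stats::setNames(sample(2:9, p$n_params, replace = TRUE),
                       p$param_names)
  w[grepl("^e8\\^", names(w))] <- 0    # removes the sigma = 1 monomial
  v <- evaluate_param(p, w)
  only1 <- rep(1, nrow(p$labellings))
  for (r in seq_len(nrow(p$pidx[[1]])))
    only1 <- only1 * unname(w)[p$pidx[[1]][r, ]]
  expect_equal(v, only1)
})

test_that("Jacobian ranks match known tree and sunlet dimensions", {
  # 3-claw tree: dim = 3l + 1
  claw <- sdnet(c("c", "x1", "x2", "x3"),
                data.frame(id = paste0("e", 1:3), tail = "c",
                           head = paste0("x", 1:3), type = "tree"),
                stats::setNames(paste0("x", 1:3), 1:3))
  expect_equal(jdim(claw, models$cfn), 4L)
  expect_equal(jdim(claw, models$k3p), 10L)
  expect_equal(jdim(make_sunlet(4), models$cfn, trials = 3), 7L)
})

test_that("reorientation flips the g <-> -g pairing and keeps the rank", {
  net <- make_sunlet(4)
  model <- models$z3
  p1 <- build_parameterization(net, model)
  p2 <- build_parameterization(flip_edge(net, "e6"), model)
  row1 <- match("e6", rownames(p1$elab[[1]]))
  expect_equal(p2$elab[[1]][row1, ],
               model$group$neg[p1$elab[[1]][row1, ]])
  expect_equal(jacobian_dimension(p2, 2, 3)$computed_dim,
               jacobian_dimension(p1, 2, 3)$computed_dim)
  expect_error(flip_edge(net, "e5"), "reticulation")
})

test_that("generic rank is invariant under contraction", {
  for (model in list(models$cfn, models$z3)) {
    for (n in 3:5) {
      expect_equal(jdim(make_sunlet(n), model, seed = n),
                   jdim(contract(make_sunlet(n)), model, seed = n))
    }
  }
})

test_that("orbit projection sums orbit coefficients and halves nothing else", {
  # trivial B: identity map
  x <- stats::setNames(1:8, NULL)
  expect_equal(orbit_project(x, models$k3p, 2), x)
  # JC on one edge: (c0, c1, c2, c3) -> (c0, c1 + c2 + c3)
  expect_equal(orbit_project(c(5, 1, 2, 3), models$jc, 1), c(5, 6))
  # kernel dimension (|G| - l - 1) m via the rank of the projection matrix
  m <- 3
  P <- vapply(seq_len(4 * m), function(i) {
    e <- numeric(4 * m); e[i] <- 1; orbit_project(e, models$jc, m)
  }, numeric(2 * m))
  expect_equal(qr(P)$rank, 2 * m)
  # p maps general-model exponent vectors to (G,B) exponent vectors
  net <- make_sunlet(4, contracted = TRUE)
  gen <- build_parameterization(net, models$klein)   # trivial B on Klein-4
  gb <- build_parameterization(net, models$jc)
  m4 <- network_stats(net)$m
  for (j in c(1, 7, 30)) {
    for (t in 1:2) {
      alpha <- numeric(m4 * 4)
      idx <- gen$pidx[[t]][, j]
      alpha[idx] <- alpha[idx] + 1
      alpha_p <- numeric(m4 * 2)
      idx2 <- gb$pidx[[t]][, j]
      alpha_p[idx2] <- alpha_p[idx2] + 1
      expect_equal(orbit_project(alpha, models$jc, m4), alpha_p)
    }
  }
})
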