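test_that("closed-form dimensions and bounds", {
  s4 <- network_stats(make_sunlet(4))
  expect_equal(expected_dimension(s4, models$k3p), 22L)
  expect_equal(cfn_dimension(s4), 7L)
  expect_equal(cfn_dimension(network_stats(make_sunlet(3))), 4L)
  expect_equal(cfn_dimension(network_stats(make_sunlet(5))), 10L)
  expect_equal(parameter_upper_bound(network_stats(contract(make_sunlet(4))),
                                     models$cfn), 8L)
  # stats of contracted and uncontracted forms agree after conversion
  expect_equal(expected_dimension(network_stats(
    make_sunlet(5, contracted = TRUE)), models$z3), 2L * 9L + 1L)
  # trees: lm + 1
  tr <- network_stats(random_level1(5, 0, 4, seed = 2))
  expect_equal(expected_dimension(tr, models$jc), tr$m + 1L)
  expect_equal(parameter_upper_bound(tr, models$jc), tr$m + 1L)
})

test_that("generic Jacobian rank reproduces the known sunlet dimensions", {
  expect_equal(jdim(make_sunlet(4), models$cfn, trials = 3), 7L)
  expect_equal(jdim(make_sunlet(3), models$cfn, trials = 3), 4L)
  r <- deficiency(make_sunlet(3, contracted = TRUE), models$z3,
                  trials = 3, seed = 2)
  expect_equal(r$computed_dim, 9L)   # fills the ambient space C^9
  expect_equal(r$deficiency, 2L)
})

test_that("rank is stable across random points (genericity smoke test)", {
  p <- build_parameterization(make_sunlet(5, contracted = TRUE), models$z3)
  ranks <- vapply(1:3, function(s)
    jacobian_dimension(p, trials = 1, seed = s)$computed_dim, 0L)
  expect_equal(length(unique(ranks)), 1L)
})

test_that("sandwich: tropical lower <= jacobian <= parameter upper bound", {
  set.seed(99)
  fixtures <- list(
    list(make_sunlet(4, contracted = TRUE), models$cfn),
    list(make_sunlet(4, contracted = TRUE), models$z3),
    list(make_sunlet(5, contracted = TRUE), models$jc),
    list(random_level1(5, 1, 4, seed = 12), models$k2p))
  for (fx in fixtures) {
    p <- build_parameterization(fx[[1]], fx[[2]])
    jd <- jacobian_dimension(p, trials = 2, seed = 4)
    best <- 0L
    for (i in 1:20) {
      lam <- sample(-1e6:1e6, p$n_params, replace = TRUE)
      cert <- tropical_lower_bound(p, lam)
      if (length(cert$ties) == 0L) { best <- cert$rank; break }
    }
    expect_lte(best, jd$computed_dim)
    expect_lte(jd$computed_dim, jd$upper_bound)
  }
})

test_that("expected-dimension theorem holds on random triangle-free
           level-1 networks", {
  grid <- list(c(6, 1), c(6, 2), c(5, 1), c(4, 1), c(6, 0))
  mods <- list(models$z3, models$klein, models$z4)
  for (i in seq_along(grid)) {
    net <- random_level1(grid[[i]][1], grid[[i]][2], 4, seed = 20 + i)
    st <- network_stats(net)
    model <- mods[[(i %% 3) + 1]]
    expect_equal(jdim(net, model, seed = i),
                 model$l * (st$m - st$c) + 1L)
  }
})

test_that("binary-state dimension formula holds including small cycles", {
  cases <- list(c(5, 1, 3), c(5, 1, 4), c(6, 1, 5), c(6, 2, 3), c(7, 1, 4))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    net <- random_level1(cs[1], cs[2], cs[3], seed = 30 + i)
    st <- network_stats(net)
    expect_equal(jdim(net, models$cfn, seed = i), cfn_dimension(st))
  }
})

test_that("witness weight vectors have the stated entries and domain", {
  lam <- sunlet_witness_lambda(6, models$z3)
  expect_equal(unname(lam["e8^0"]), -2)     # cycle edge n+2, identity orbit
  expect_true(all(lam[paste0("e7^", 0:2)] == 1))
  expect_equal(sum(lam != 0), 4L)
  lam5 <- sunlet_witness_lambda(5, models$cfn)
  expect_equal(unname(lam5[c("e6^0", "e6^1")]), c(1, 1))
  expect_equal(unname(lam5["e8^0"]), 2)
  expect_error(sunlet_witness_lambda(3, models$z3), "n = 3")
})

test_that("tropical certificates: ties for lambda = 0, witness ranks", {
  p4 <- build_parameterization(make_sunlet(4, contracted = TRUE), models$cfn)
  cert0 <- tropical_lower_bound(p4, numeric(p4$n_params))
  expect_equal(length(cert0$ties), nrow(p4$labellings))
  lam4 <- sunlet_witness_lambda(4, models$cfn)
  cert4 <- tropical_lower_bound(p4, lam4)
  expect_length(cert4$ties, 0L)
  expect_equal(submatrix_B_rank(p4, lam4), 3L)
  p5 <- build_parameterization(make_sunlet(5, contracted = TRUE), models$cfn)
  lam5 <- sunlet_witness_lambda(5, models$cfn)
  expect_equal(tropical_lower_bound(p5, lam5)$rank, 10L)
  expect_gte(submatrix_B_rank(p5, lam5), 4L)
  # |G| > 2 witness certifies the full expected dimension
  pz <- build_parameterization(make_sunlet(4, contracted = TRUE), models$z3)
  lamz <- sunlet_witness_lambda(4, models$z3)
  expect_equal(tropical_lower_bound(pz, lamz)$rank, 2L * 7L + 1L)
  expect_gte(submatrix_B_rank(pz, lamz), 8L)  # 4l with l = 2
})

test_that("orbit projection is compatible with orbit-constant weights", {
  # a weight vector constant on B-orbits selects the same monomials in the
  # general model and in the (G,B) model; projecting the selected columns
  # gives the (G,B) certificate matrix
  net <- make_sunlet(4, contracted = TRUE)
  m <- network_stats(net)$m
  gen <- build_parameterization(net, models$klein)
  gb <- build_parameterization(net, models$jc)
  lam_gb <- sunlet_witness_lambda(4, models$jc)
  # lift to the general axes: same value on every element of each orbit
  lam_gen <- numeric(m * 4L)
  for (e in seq_len(m)) for (g in 1:4) {
    orb <- models$jc$orbit_of[g]
    lam_gen[(e - 1L) * 4L + g] <- lam_gb[(e - 1L) * 2L + orb]
  }
  cg <- tropical_lower_bound(gen, lam_gen)
  cb <- tropical_lower_bound(gb, unname(lam_gb))
  expect_length(cg$ties, 0L)
  projected <- orbit_project(cg$A_matrix, models$jc, m)
  expect_equal(projected, cb$A_matrix + 0)
  expect_gte(cb$rank, models$jc$l * m + 1L)
})

test_that("toric-fiber-product combination matches glued Jacobian ranks", {
  fig3 <- fig3_network()
  cut <- cut_at(fig3, "e")
  for (model in list(models$cfn, models$z3)) {
    dp <- jdim(cut$plus, model, seed = 1)
    dm <- jdim(cut$minus, model, seed = 2)
    dg <- jdim(fig3, model, seed = 3)
    expect_equal(tfp_combine(dp, dm, model), dg)
  }
  # gluing two trees reproduces the tree dimension (cut a random tree)
  tr <- random_level1(6, 0, 4, seed = 40)
  internal <- tr$edges$id[!(tr$edges$tail %in% unname(tr$leaves) |
                              tr$edges$head %in% unname(tr$leaves))]
  cutt <- cut_at(tr, internal[1])
  l <- models$z3$l
  st <- network_stats(tr)
  expect_equal(tfp_combine(jdim(cutt$plus, models$z3, seed = 4),
                           jdim(cutt$minus, models$z3, seed = 5), models$z3),
               l * st$m + 1L)
  expect_equal(tfp_dimension_formula(1, 1, 1), 1)
})

test_that("small deficiency sweep matches the published values", {
  tab <- table1_sweep(4, c("Z2", "Z3", "JC", "Z4"), seed = 3, trials = 2)
  expect_equal(tab$Z2, c(2L, 1L))
  expect_equal(tab$Z3, c(2L, 0L))
  expect_equal(tab$JC, c(1L, 0L))
  expect_equal(tab$Z4, c(0L, 0L))
  # deterministic across seeds (ranks are generically stable)
  tab2 <- table1_sweep(4, c("Z2", "Z3", "JC", "Z4"), seed = 77, trials = 2)
  expect_identical(tab, tab2)
})
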