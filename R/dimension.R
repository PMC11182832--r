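#' Expected dimension of a level-1 network variety
#'
#' The expected (affine cone) dimension is l(m - c) + 1, where m is the
#' edge count of the uncontracted binary network and c the cycle count.
#' Stats from a contracted network are converted back (m_uncontracted =
#' m + c).
#'
#' @param stats output of [network_stats()].
#' @param model a `gb_model`.
#' @return integer.
#' @export
expected_dimension <- function(stats, model) {
  m <- stats$m + if (isTRUE(stats$contracted)) stats$c else 0L
  model$l * (m - stats$c) + 1L
}

#' Closed-form dimension under the binary-state (CFN) model
#'
#' For G = Z/2 the variety of a level-1 network with m edges and c3, c4,
#' c_ge5 cycles of each length has dimension m - (c_ge5 + 2 c4 + 3 c3) + 1
#' (uncontracted edge count).
#'
#' @param stats output of [network_stats()].
#' @return integer.
#' @export
cfn_dimension <- function(stats) {
  m <- stats$m + if (isTRUE(stats$contracted)) stats$c else 0L
  m - (stats$c_ge5 + 2L * stats$c4 + 3L * stats$c3) + 1L
}

#' Parameter-count upper bound on the dimension
#'
#' dim V <= l m' + 1 where m' is the edge count of the contracted network.
#'
#' @param stats output of [network_stats()] (of either form; converted).
#' @param model a `gb_model`.
#' @return integer.
#' @export
parameter_upper_bound <- function(stats, model) {
  m_contr <- stats$m - if (isTRUE(stats$contracted)) 0L else stats$c
  model$l * m_contr + 1L
}

new_dimension_report <- function(computed, expected, upper, tropical = NA,
                                 trials, seed, field) {
  structure(list(computed_dim = computed, expected_dim = expected,
                 upper_bound = upper, tropical_lower = tropical,
                 deficiency = expected - computed,
                 trials = trials, seed = seed, field = field),
            class = "dimension_report")
}

#' @export
print.dimension_report <- function(x, ...) {
  cat(sprintf(
    "dim = %d (expected %d, upper bound %d, deficiency %d)\n  %d trial(s), seed %d, field: %s\n",
    x$computed_dim, x$expected_dim, x$upper_bound, x$deficiency,
    x$trials, x$seed, x$field))
  if (!is.na(x$tropical_lower))
    cat(sprintf("  tropical lower bound: %d\n", x$tropical_lower))
  invisible(x)
}

#' Variety dimension by generic Jacobian rank
#'
#' Evaluates the Jacobian of the Fourier parameterization at `trials`
#' independently drawn random integer points (entries uniform in [2, 997])
#' and returns the maximum exact rank.  Ranks are computed over two
#' independent prime fields (p just below sqrt(2^53)) and the maximum is
#' taken: a rank over F_p never exceeds, and generically equals, the rank
#' over Q.
#'
#' @param param a `gb_param`.
#' @param trials number of random points (default 3).
#' @param seed integer seed.
#' @return a `dimension_report`.
#' @export
jacobian_dimension <- function(param, trials = 3L, seed = 1L) {
  if (trials < 1L) stop("trials must be >= 1")
  set.seed(seed)
  best <- 0L
  for (t in seq_len(trials)) {
    point <- sample(2:997, param$n_params, replace = TRUE)
    r <- max(vapply(MOD_PRIMES, function(p)
      rank_modp(param_jacobian(param, point, p = p), p), 0L))
    best <- max(best, r)
  }
  stats <- network_stats(param$net)
  new_dimension_report(
    computed = best,
    expected = expected_dimension(stats, param$model),
    upper = parameter_upper_bound(stats, param$model),
    trials = trials, seed = seed,
    field = sprintf("Fp (p = %s)", paste(MOD_PRIMES, collapse = ", ")))
}

#' Deficiency report for a network and model
#'
#' Deficiency = expected dimension minus the computed (generic Jacobian
#' rank) dimension; nonnegative on every case covered by the theory.
#'
#' @param net an `sdnet`.
#' @param model a `gb_model`.
#' @param trials,seed passed to [jacobian_dimension()].
#' @return a `dimension_report`.
#' @export
deficiency <- function(net, model, trials = 3L, seed = 1L) {
  jacobian_dimension(build_parameterization(net, model),
                     trials = trials, seed = seed)
}

#' Toric-fiber-product dimension combination
#'
#' Gluing two networks along a cut edge adds their variety dimensions and
#' subtracts the number of B-orbits, l + 1.
#'
#' @param dim_plus,dim_minus affine dimensions of the two pieces.
#' @param model a `gb_model`.
#' @return integer.
#' @export
tfp_combine <- function(dim_plus, dim_minus, model) {
  tfp_dimension_formula(dim_plus, dim_minus, model$l + 1L)
}

#' Dimension formula for a codimension-zero toric fiber product
#'
#' For prime ideals with full-support independent sets the toric fiber
#' product over a linearly independent degree set of size r has dimension
#' dim I + dim J - r.
#'
#' @param dim_I,dim_J dimensions of the factors.
#' @param r size of the degree set.
#' @return integer.
#' @export
tfp_dimension_formula <- function(dim_I, dim_J, r) dim_I + dim_J - r

#' Sunlet deficiency table
#'
#' Recomputes the deficiency of the n-sunlet for n = 3..nmax under a panel
#' of models, using contracted sunlets for speed.  The binary-state column
#' is cross-checked against the closed-form CFN dimension.
#'
#' @param nmax largest sunlet size (>= 3).
#' @param models character vector of model codes among
#'   `c("Z2","Z3","JC","K2P","K3P","Z4","Z5","Z6","Z7")`, or a named list
#'   of `gb_model`s.
#' @param seed integer seed.
#' @param trials random points per rank computation.
#' @param verbose print progress.
#' @return data.frame with column `n` and one deficiency column per model.
#' @export
table1_sweep <- function(nmax = 6L,
                         models = c("Z2", "Z3", "JC", "K2P", "K3P",
                                    "Z4", "Z5", "Z6", "Z7"),
                         seed = 1L, trials = 3L, verbose = FALSE) {
  if (nmax < 3L) stop("nmax must be >= 3")
  if (is.character(models))
    models <- stats::setNames(lapply(models, model_by_code), models)
  out <- data.frame(n = 3:nmax)
  for (code in names(models)) out[[code]] <- NA_integer_
  for (n in 3:nmax) {
    net <- make_sunlet(n, contracted = TRUE)
    stats <- network_stats(net)
    for (code in names(models)) {
      model <- models[[code]]
      rep <- deficiency(net, model, trials = trials,
                        seed = seed + 1000L * n)
      if (model$group$order == 2L &&
          rep$computed_dim != cfn_dimension(stats))
        warning(sprintf(
          "CFN cross-check failed at n = %d: rank %d vs closed form %d",
          n, rep$computed_dim, cfn_dimension(stats)))
      out[out$n == n, code] <- rep$deficiency
      if (verbose)
        message(sprintf("n = %d, %s: dim %d, deficiency %d",
                        n, code, rep$computed_dim, rep$deficiency))
    }
  }
  out
}

#' Resolve a short model code to a model
#'
#' @param code one of "Z2" (CFN), "Z3", "Z4".."Z9", "JC", "K2P", "K3P".
#' @return a `gb_model`.
#' @export
model_by_code <- function(code) {
  if (code %in% c("CFN", "JC", "K2P", "K3P")) return(named_model(code))
  if (code == "Z2") return(named_model("CFN"))
  if (grepl("^Z[0-9]+$", code)) {
    k <- as.integer(sub("^Z", "", code))
    m <- gb_model(make_group(k), name = paste0("Z/", k))
    return(m)
  }
  stop("unknown model code: ", code)
}
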