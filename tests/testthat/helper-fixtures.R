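# shared fixtures for the test suite

models <- list(
  cfn = named_model("CFN"),
  jc = named_model("JC"),
  k2p = named_model("K2P"),
  k3p = named_model("K3P"),
  z3 = model_by_code("Z3"),
  z4 = model_by_code("Z4"),
  z5 = model_by_code("Z5"),
  klein = gb_model(make_group(c(2, 2)), name = "Klein4")
)

# permute the leaf labels of a network (perm: named map old -> new)
relabel_leaves <- function(net, perm) {
  nm <- unname(perm[names(net$leaves)])
  names(net$leaves) <- nm
  net$leaf_order <- nm[order(as.numeric(nm))]
  net
}

# dimension shortcut
jdim <- function(net, model, trials = 2, seed = 1)
  jacobian_dimension(build_parameterization(net, model),
                     trials = trials, seed = seed)$computed_dim

# the worked-example quadric of the 4-sunlet (binary-state model) and the
# two verified quartet-tree generators of the 4-leaf piece
example_F <- function() qpoly(c(1, -1, 1, -1),
                              list(c("0000", "1111"), c("1100", "0011"),
                                   c("1010", "0101"), c("0110", "1001")))
example_g3 <- function() qpoly(c(1, -1), list(c("0011", "1100"),
                                              c("0000", "1111")))
example_g4 <- function() qpoly(c(1, -1), list(c("0110", "1001"),
                                              c("0101", "1010")))
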