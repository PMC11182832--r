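# netvardim

Dimensions of group-based Markov models on level-1 phylogenetic networks.

## The problem

Phylogenetic networks extend trees to evolutionary histories with
hybridization: a *level-1* (galled-tree) semi-directed network is a mixed
graph whose cycles are vertex-disjoint, each carrying one *reticulation
vertex* with two directed incoming edges.  A *group-based model* `(G, B)` —
a finite abelian group `G` (states) and a subgroup `B ⊆ Aut(G)` identifying
parameters — places a Markov process on the network.  The classical named
models are CFN `(Z/2, id)`, JC `((Z/2)², S₃)`, K2P `((Z/2)², S₂)` and K3P
`((Z/2)², id)`.

In Fourier coordinates the model of a tree is monomial,

    q_{g1…gn} = ∏_{e ∈ E(T)} a_e^{[ξ(e)]},   ξ(e) = Σ_{v on the arrow side} g_v,

and the model of a network with k reticulations is the sum of these maps
over its `2^k` displayed trees.  The Zariski closure of the image is an
algebraic variety `V_N^{(G,B)}`; its (affine cone) dimension is the basic
geometric invariant behind identifiability arguments.  With `l + 1` the
number of `B`-orbits in `G`, `m` edges and `c` cycles, the *expected
dimension* is `l(m − c) + 1`; the *deficiency* is expected minus actual.

`netvardim` builds these parameterizations for any `(G, B)` on any level-1
network, computes dimensions as exact generic Jacobian ranks (prime-field
arithmetic, never floating point), certifies lower bounds by tropical
geometry (the rank of the argmin exponent matrix `A_λ` of a weight vector
`λ`), combines dimensions across cut edges by the toric-fiber-product
formula `dim = dim₊ + dim₋ − (l+1)`, reproduces the published sunlet
deficiency table, and runs dimension-based distinguishability tests.

## Worked example

```r
library(netvardim)
net   <- make_sunlet(4)          # 4-leaf cycle network, reticulation at leaf 1
model <- named_model("CFN")      # G = Z/2, trivial B, l = 1
deficiency(net, model, trials = 3, seed = 1)
#> dim = 7 (expected 8, upper bound 8, deficiency 1)
#>   3 trial(s), seed 1, field: Fp (p = 94906249, 94906219)
```

The 4-sunlet under the binary-state model is the famous deficient case: the
generic Jacobian rank is 7, one below the expected `l(2n−1)+1 = 8`.  The
symbolic map itself:

```r
cat(render_parameterization(net))
#> a1^{g1}a2^{g2}a3^{g3}a4^{g4}a5^{g1}a6^{g1+g2}a7^{g4} + a1^{g1}a2^{g2}a3^{g3}a4^{g4}a6^{g2}a7^{g1+g4}a8^{g1}
```

one monomial per displayed tree (the first removes reticulation edge e8,
the second removes e5).  Deficiencies of small sunlets across models:

```r
table1_sweep(4, c("Z2", "Z3", "JC", "K2P", "K3P"), seed = 1)
#>   n Z2 Z3 JC K2P K3P
#> 1 3  2  2  1   1   1
#> 2 4  1  0  0   0   0
```

Row `n = 3` says: the 3-sunlet is deficient by 2 under Z/2 and Z/3 and by 1
under JC/K2P/K3P; for n ≥ 4 only the binary-state model stays deficient
(and only at n = 4).  All other entries vanish — dimension is determined by
leaf and cycle counts.

## Command line

```sh
exec/netvardim dim --network net.enewick --model K3P --seed 1
exec/netvardim table1 --nmax 6 --models Z2,Z3,JC,K2P,K3P,Z4,Z5,Z6,Z7 --out table.csv
exec/netvardim distinguish --a a.enewick --b b.enewick --model JC --seed 1
```

Networks are read from extended Newick (`#H` hybrid tags) or a small JSON
edge-list dialect (see `inst/extdata/fig3.json`).

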