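---
title: "Dimensions of group-based models on level-1 networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimensions of group-based models on level-1 networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netvardim)
```

## The model

A group-based model is a pair `(G, B)`: a finite abelian group `G` whose
elements are the character states, and a subgroup `B` of `Aut(G)` that
identifies transition parameters.  After the discrete Fourier transform the
transition structure of an edge `e` collapses to one free parameter
`a_e^{[g]}` per `B`-orbit `[g]`; with `l + 1` orbits and `m` edges the
parameter space is `C^{m(l+1)}`.  In this package a group is a product of
cyclic groups (`make_group(c(2, 2))`), an action is a set of permutations of
the element set validated as automorphisms by exhaustion, and orbits take
the lexicographically smallest element as representative so parameter names
are reproducible.  `named_model()` provides CFN, JC, K2P and K3P.

On an `n`-leaf tree the model in Fourier coordinates is monomial: a
coordinate is indexed by a *consistent leaf labelling* (group elements
summing to zero; there are `|G|^(n-1)` of them) and equals the product over
edges of `a_e^{[ξ(e)]}`, where the edge label `ξ(e)` sums the leaf labels on
the arrow side of the edge's auxiliary orientation.  On a level-1
semi-directed network with `k` reticulation vertices, deleting one
reticulation edge per reticulation gives a displayed tree, and the model is
the coordinate-wise **sum** of the `2^k` displayed-tree monomials.  The
variety `V_N^{(G,B)}` is the closure of the image; everything here concerns
its affine cone dimension.

Three structural facts make the computation modular, and each is exercised
as a test rather than assumed: reorienting a tree edge only swaps the
`g ↔ -g` parameter pairing (`flip_edge`), contracting the pendant edge
below each reticulation is a reparameterization (`contract`), and cutting
the network at a cut edge `e` factors the coordinate ring as a toric fiber
product graded by the `B`-orbit of `ξ(e)` (`cut_at`, `multidegree`).

## Dimension computations

Four routes are implemented and cross-checked:

* **Generic Jacobian rank** (`jacobian_dimension`).  The Jacobian of the
  parameterization at a generic point has rank equal to the dimension.
  Points are drawn uniformly from integers in `[2, 997]`, three independent
  trials by default, and the maximum rank is reported.
* **Closed forms** (`expected_dimension`, `cfn_dimension`).  The expected
  dimension `l(m - c) + 1` is attained by every triangle-free level-1
  network when `|G| ≥ 3`; for the binary-state model the dimension is
  `m - (c_{≥5} + 2c_4 + 3c_3) + 1`.  Both use the uncontracted edge count.
* **Tropical certificates** (`tropical_lower_bound`).  For a weight vector
  `λ`, each coordinate selects the exponent vector of its `⟨λ, α⟩`-minimal
  monomial; the rank of the resulting integer matrix `A_λ` bounds the
  dimension from below.  Coordinates where the minimum ties disqualify `λ`
  (the certificate is only valid where the tropicalized map is linear);
  ties are reported, never silently broken.  `sunlet_witness_lambda`
  reproduces the two published witness vectors for contracted sunlets, and
  `submatrix_B_rank` performs the associated row/column reduction to the
  small block whose rank carries the argument.
* **Toric fiber products** (`tfp_combine`).  Across a cut edge,
  `dim = dim₊ + dim₋ − (l + 1)`.  This is how dimension results propagate
  from sunlets and trees to arbitrary level-1 networks, and the test suite
  verifies it against directly computed glued ranks.

### Exact arithmetic

Ranks are never decided in floating point.  Small integer matrices
(tropical certificates, reduced blocks) go through Bareiss fraction-free
elimination, which is exact over the rationals as long as intermediate
minors stay below 2^49 — guarded explicitly.  Jacobians are evaluated and
eliminated over prime fields `F_p` with the two largest primes below
`sqrt(2^53)` (94906249 and 94906219), so every product of residues is an
exact double.  A rank over `F_p` never exceeds the rank over `Q` and the
maximum over both primes and all random points is reported, together with
the field, in the `DimensionReport`.  The choice of moduli is a deliberate
departure from "rationals by default with p > 10^9": R has no arbitrary
precision rationals in the supported stack, and a 31-bit modulus would
overflow double multiplication.  Two independent ~2^26.5 moduli at three
points make an undershoot practically impossible, and in every case covered
by the closed forms the result is confirmed by the matching upper bound
`l·m_contracted + 1` (`parameter_upper_bound`).

### Conventions and degenerate inputs

Dimensions are affine (cone) dimensions.  Expected dimension always means
`l(m − c) + 1` on the uncontracted network, so the binary-state 3- and
4-cycle cases have positive deficiency by definition.  Coordinates are
indexed by full `G`-labellings even for nontrivial `B`: the `B`-action
identifies some coordinates but does not change the image dimension, and
the orbit projection `orbit_project` maps general-model exponent vectors to
`(G, B)`-model exponent vectors, which is the published route from the
general to the symmetric case (tested as the compatibility
`p ∘ A_λ = A_{λ'}` for orbit-constant weights).  The witness construction
is refused for `n = 3` sunlets, where it degenerates; whether the 3-sunlet
reaches the expected dimension for `|G| > 4` is exposed as a computation,
not assumed.

## Networks, I/O, and the random generator

Networks are stored uncontracted and binary as the normal form; contraction
is explicit.  Validation (via igraph's biconnected components) enforces
connectivity, simple edges, two incoming reticulation edges per
reticulation vertex, and exactly one reticulation per cycle.  Sunlets are
built with the published edge numbering — leaf edges first, then the cycle,
reticulation edges at positions `n+1` and `2n` (uncontracted) or `1` and
`n+1` (contracted) — and with the figure orientations, so the rendered
parameterization reproduces the printed map character for character.

`random_level1(n, c, min_cycle_len, seed)` grows a random binary tree by
leaf insertion, then blows up `c` disjoint internal paths into cycles of the
requested length, picking a random cycle vertex as the reticulation.  It
emulates topology only: every generated network is a valid uncontracted
level-1 network with `2n − 3 + 3c` edges and deterministic per seed.  It
does not emulate branch lengths, base composition, or data — a green
property test certifies a statement about generic ranks of the stated
topology class, nothing about inference from finite sequences.  Where the
literature prescribes no sizes we test `n ≤ 7`, `c ≤ 2`, cycle lengths 3–5:
the smallest sizes at which every qualitatively distinct case (triangles,
4-cycles, long cycles, multiple cycles, trees) occurs.

Extended Newick input maps `#H` hybrid nodes to reticulation vertices and
suppresses the root; the writer searches for a rooting compatible with the
stored reticulation directions.  A JSON edge-list dialect exists because
eNewick cannot mark semi-directedness natively.

## Identifiability

`distinguishable_by_dimension` implements the dimension route to
distinguishability: with equal full dimensions (checked first), a leaf
subset `A` whose restrictions have a dimension gap — different cycle
counts, or tree against network — or distinct restricted tree topologies
certified by a quartet invariant, witnesses that neither variety contains
the other.  Restriction deletes leaves, removes reticulations left with no
leaf below, and suppresses degree-2 vertices.  Subsets of size `n − 1` are
searched before quartets because the published arguments only ever need
those.  The quartet invariant for orbits `[g] ≠ [h]` vanishes identically
on the `12|34` tree (verified symbolically, by cancellation in the
composed monomial map) and is certified nonzero on the other two topologies
by exact evaluation — a nonzero residue mod `p` is an exact certificate,
while "vanishes" is probabilistic with the trial count logged.  For the
binary-state model the cycle-count rule is only applied when all restricted
cycles have length at least 5, since the closed form for `|G| = 2` penalizes
short cycles and the general argument is stated for `|G| > 2`.
"not-decided" is an honest outcome; the package never claims
indistinguishability (the adjacent-leaf-swap sunlet pair is the canonical
undecided case and is tested as such).

## Known limitations

* Vanishing ideals are never computed: no Gröbner bases, no primality or
  irreducibility checks.  The toric-fiber-product content is exercised
  through multigradings, Quad_B generators, lifts, and exact vanishing
  checks of the lifted generators on the glued parameterization.
* For nontrivial `B`, pairs of equal multidegree whose swap would be
  inconsistent are skipped in `Quad_B` (the swap consistency that is
  automatic for trivial `B` can fail when degrees are orbits); the worked
  examples in the tests are binary-state, where the issue does not arise.
* Prime-field ranks are lower bounds for rational ranks; the report records
  the field so a doubting reader knows what was computed.  Deficiency
  claims (where no matching upper bound exists) rest on two moduli and
  three points each.
* The published generator list for the 4-leaf-tree piece of the worked
  gluing example is partly inconsistent as printed (four of its six
  binomials fail exponent matching on any quartet tree); the golden tests
  reproduce the printed lifts symbolically from the printed inputs, and the
  vanishing tests use the two generators that verify.
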