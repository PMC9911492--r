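---
title: "Flattening ranks, tree cuts, and certified verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flattening ranks, tree cuts, and certified verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flatrank)
```

## The model and the quantity of interest

A phylogeny here is an acyclic connected graph whose degree-1 vertices
carry taxon labels; internal vertices are addressable too (by Newick label
or by integer id), because the subsets entering the theory are subsets of
*vertices*, not only of leaves.  The general Markov model attaches to a
root `ρ` a distribution `π_ρ` over `r` states and to every edge directed
away from the root a row-stochastic `r × r` matrix `P_uv`; a full
assignment `F` of states to vertices has probability
`π_ρ(F(ρ)) · ∏ P_uv(F(u), F(v))`, and anything observable is a marginal of
this product.  This subsumes the standard iid-site substitution models; no
branch lengths or rate matrices appear, only the matrices themselves.

For disjoint vertex subsets `A`, `B` the flattening `flat_{A|B}` is the
`r^|A| × r^|B|` matrix of joint marginals.  Its rank is governed by the
combinatorics of the tree: `rank(flat_{A|B}) = r^{ν_T(A|B)}`, with
`ν_T(A|B)` the minimum vertex cut separating `A` from `B`, provided the
parameters satisfy

* **(C1)** every `P_uv` nonsingular,
* **(C2)** `π_ρ(i) > 0` for every state,
* **(C3)** `P_uv(i,j) > 0` on internal edges.

The package's job is to make every term in that sentence computable and
independently checkable.

## Combinatorial side: `ℓ`, `ν`, and certificates

The parsimony length `ℓ_T(f)` of a partial character is computed by
unit-cost Sankoff dynamic programming with the domain vertices clamped;
clamping (rather than Fitch's set rule) is what makes internal-vertex
constraints and arbitrary `r` work.  For a bipartition `A|B`, `ℓ_T(A|B)`
is the parsimony length of the two-state indicator and simultaneously the
maximum number of edge-disjoint `A`–`B` paths; `ν_T(A|B)` is its
vertex-disjoint analogue.  Both are computed by unit-capacity max-flow
(`igraph::max_flow`): `ℓ` on the tree with unit edge capacities, `ν`
through the standard vertex-splitting reduction in which *every* vertex —
terminals included — gets a capacity-1 internal arc, so the minimum cut
may contain members of `A ∪ B`, as the theory requires (the star tree
with alternating leaf sets is the canonical example: `ν = 1` at the
centre while `ℓ` equals the number of leaf pairs).  Each result carries a
Menger certificate — a disjoint path system and a separating cut of equal
cardinality — and `validate_cut_result()` re-checks both independently of
the flow computation.  Tie-breaking among minimum cuts follows the
residual graph of the max flow (the cut saturated from the source side);
uniqueness is not promised.  Trees are tiny throughout, so no attempt is
made at asymptotically optimal flow algorithms.

The general multistate `ν_T(f)` (domains with more than two blocks) is
deliberately exposed only through the exhaustive oracle
`brute_force_nu()`: the two-block case is all the rank theory needs, and
no efficient algorithm for the general case is attempted here.

## Algebraic side: tensors, flattenings, and exact rank

Marginals and flattenings are computed by variable elimination along the
tree: one post-order sweep with messages indexed by the states of the
retained vertices.  The index convention is fixed everywhere: the row
index of an assignment `f_A` is `Σ_k f_A(a_k) · r^(|A|−1−k)` — the last
listed vertex varies fastest — matching the conventional enumeration
`p_RRRR, p_RRRY, p_RRYR, …` of pattern vectors, and tested positionally
against brute-force enumeration of the product formula.

Rank is discontinuous, so a floating-point SVD alone cannot *certify* it.
Two complementary modes are provided:

* **Numerical**: singular values with tolerance `σ_max · 1e−9`
  (configurable).  True flattening ranks are powers of `r`, and for
  generic parameters on trees of the sizes used here the spectrum shows a
  gap of many orders of magnitude; the largest relative gap is reported as
  a diagnostic against borderline cases.
* **Exact**: when parameters are rational (the generator's
  `rational = TRUE` mode stores every row as an integer composition of a
  common denominator), the whole elimination is carried out in a prime
  field GF(p) and the rank obtained by Gaussian elimination mod `p`.  The
  two built-in primes sit just below `2^25` so that products of residues
  and their short sums stay exactly representable in doubles.  Reduction
  mod `p` can only lower rank, so each prime yields a certified lower
  bound, equal to the rational rank for all primes outside a finite bad
  set; the package reports the maximum over two independent primes plus
  the inter-prime agreement flag, and the test suite additionally compares
  against the SVD rank.  In every harness the certified rank is the
  arbiter.

Two factorization witnesses from the theory are implemented as checkable
objects rather than left as proof devices: `cut_factorization()` exhibits
`flat_{A|B} = R·S` across a computed minimum vertex cut (conditional
independence given the cut, valid even when the cut intersects `A ∪ B`),
and `marginalization_matrix()` builds the 0–1 matrices `U_A`, `U_B` with
`flat_{A'|B'} = U_A · flat_{A|B} · U_Bᵀ` for nested subsets, which gives
rank monotonicity under marginalization.  The Kronecker-product induction
decomposition used in the full proof is not exported; it is exercised
indirectly through these witnesses.

## Tree space: SPR, TBR, and split distances

`spr_neighbors()` and `tbr_neighbors()` enumerate all topologies one
rearrangement away from a binary tree, suppressing the degree-2 vertices
the surgery creates; topologies are identified by their canonical split
sets (two binary leaf-labelled trees are isomorphic iff their split sets
coincide), encoded as leaf bitmasks for speed.  `split_distance()` reports
`ν_T(A|B) − 1` as the distance from `T` to the nearest tree containing the
split under either move type, and can certify the value by breadth-first
search; certification refuses trees with more than 7 leaves (the
neighbourhood growth is explosive) and falls back to the formula with a
warning.  The BFS identifies a split found at depth `d` with the split
sets of the layer-`d` topologies, and memoises neighbourhoods across
queries, so certifying all 25 non-trivial splits of a 6-leaf tree costs
two graph explorations, not fifty.  General tree-to-tree SPR/TBR distance
is NP-hard and out of scope; only distance-to-nearest-tree-containing-a-
split is computed, which is what the rank connection needs.

## Necessity of the conditions

`degeneracy_demo()` zeroes a chosen root entry or internal-edge entry —
renormalizing the affected row, which keeps the object a probability
distribution while preserving the structural zero that drives the rank
drop — and ranks the non-split flattening.  On a quartet rooted on the
internal edge `(u, v)`, gathering terms gives `flat_{13|24} = U D V` with
`D` diagonal, `D_{ij,ij} = π_ρ(i)·P_uv(i,j)`, and `U`, `V` nonsingular
under (C1); the demo therefore also reports the predicted rank (the count
of nonzero diagonal entries) and the harness checks prediction and
certified rank coincide: rank 4 generically, 2 after zeroing a root entry
(`r = 2`), 3 after zeroing one internal-edge entry.

## Synthetic data: what the generators emulate

`random_binary_tree()` grows unrooted binary trees by uniform sequential
leaf attachment; `random_tree()` contracts each internal edge with
probability 0.25 (default) to produce multifurcations — enough to exercise
the non-binary side of the rank formula, not a model of any biological
tree-shape distribution.  `random_generic_params()` draws rows from the
flat Dirichlet with an entry floor of `1e−3` and a determinant floor of
`1e−6`, resampling violators (budget 1000): the floors realise
"genericity" concretely, keeping the numerical ranks unambiguous on trees
up to a dozen leaves; the generator keeps *all* entries positive (slightly
stronger than (C3), which constrains only internal edges — user-supplied
parameters may have pendant-edge zeros).  In rational mode each row is an
integer composition of 1000 by largest-remainder rounding of the same
Dirichlet draw.  `simulate_alignment()` draws iid sites root-to-leaf.
None of this emulates real data: no rate heterogeneity, no alignment
error, no lineage sorting, no model misspecification.  Passing tests show
the algebra–combinatorics identity holds as stated for the model's exact
distributions and that the empirical machinery concentrates as sampling
theory predicts — not that split scores resolve trees on hard biological
alignments.

## Numerical and design choices

* States are 0-based integers `0..r−1` internally; presentation alphabets
  (R/Y for two states, nucleotides for four) apply only at FASTA
  boundaries.
* `parse_newick()` reads branch lengths and discards them (the model
  carries matrices); an unlabeled degree-2 Newick root is suppressed by
  default so that `((1,2),(3,4));` is the 6-vertex unrooted quartet, while
  `rooted = TRUE` (or a labelled root) preserves it.  Degree-2 vertices
  are representable in general; `suppress_degree2()` removes them where
  rearrangements require it.
* Unrooted trees store a recorded reference orientation; everything that
  needs a root calls `reroot()`/`reroot_params()` explicitly.  Moving the
  model root Bayes-reverses the flipped edges and provably preserves the
  leaf pattern distribution; this is implemented in floating point only
  (checked to `1e−12`), since the reversal's divisions take exact
  denominators beyond double-integer range, and no certification step
  needs a rerooted rational parameter set.
* Flattenings are dense with a `2^24`-entry cap — this is a desk-scale
  verification tool, not a genome-scale inference engine.
* Split scores generalize to parameter `k` (score of rank `≤ r^k`);
  `k = 1` is the standard definition and the default.  For empirical
  flattenings no hard rank is ever reported — only the spectrum and the
  score — because no principled tolerance exists for estimated
  probabilities.
* Exit codes of the CLI: 0 success, 1 usage error, 2 theorem
  disagreement, so the `suite` subcommand can drive CI.

## Study sizes

The shipped harnesses (also what `scripts/acceptance.R` reruns) use: 50
instances for the rank formula (trees of 4–10 leaves, binary and
multifurcating, `r ∈ {2,3}`, vertex subsets of size ≤ 3 including
internal vertices); 200 instances each for cut equality and for the three
oracle equivalences (trees of 4–7 leaves, `r ≤ 4`, enumeration bounded to
a few thousand extensions); all bipartitions of a quartet and a 6-leaf
tree for the split-rank dichotomy; 10 six-leaf trees × 25 non-trivial
splits for the SPR/TBR certification; and the fixed two-state quartet for
the degeneracy study.  These sizes make every enumeration exhaustive and
keep the full suite under a minute on one core while exercising every
code path the theory distinguishes.

## Known limitations

Exact rank certification requires generator-produced (or otherwise
rational) parameters; for arbitrary floating-point parameters only the
numerical rank and gap diagnostic are available.  The prime-field
certificate is one-sided per prime (a lower bound that is almost surely
tight); a symbolic determinant over the rationals would close even that
gap but needs arbitrary-precision arithmetic.  BFS certification of split
distances is limited to 7 leaves.  Multistate `ν_T(f)` beyond two blocks
is oracle-only, as discussed above.
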