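# flatrank

Flattening matrices of site-pattern distributions on phylogenetic trees,
and exact verification of the identity between their rank and the
combinatorics of the tree.

## The problem

Under the general Markov model of sequence evolution, a rooted tree `T`
with root distribution `π_ρ` and one row-stochastic `r × r` transition
matrix per edge determines a joint distribution over the `r^n` possible
site patterns at the `n` leaves.  For disjoint vertex subsets `A` and `B`,
the *flattening* `flat_{A|B}` arranges the joint probabilities
`π(X_A = f_A, X_B = f_B)` into an `r^|A| × r^|B|` matrix — an unfolding of
the pattern probability tensor.  Flattening ranks underlie phylogenetic
invariants and split-score methods of tree inference (SVDQuartets and
relatives): a split that belongs to the tree gives a flattening of rank
`r`, so its split score — the sum of singular values beyond the largest
`r`, over the total — vanishes.

The precise statement verified by this package: if every edge matrix is
nonsingular (C1), the root distribution is strictly positive (C2), and
internal-edge matrices are strictly positive (C3), then

    rank(flat_{A|B}) = r^{ν_T(A|B)},

where `ν_T(A|B)` is the minimum number of vertices whose removal leaves no
component meeting both `A` and `B` (equivalently, by Menger's theorem, the
maximum number of vertex-disjoint `A`–`B` paths).  On a binary tree with
`A, B` leaf subsets, `ν` coincides with the parsimony length `ℓ_T(A|B)` of
the two-state indicator character of `A|B`.  A further consequence ties
algebra to tree space: for a leaf bipartition `A|B` of a binary tree, the
SPR and TBR distances from `T` to the nearest tree containing the split
both equal `ν_T(A|B) − 1`.  Each of (C1)–(C3) is necessary: zeroing a root
entry or an internal-edge entry drops the rank of a non-split flattening
below `r²`.

`flatrank` implements all the moving parts as first-class, testable
operations: Newick trees with addressable internal vertices, Sankoff
parsimony with clamped internal vertices, max-flow/min-cut computations of
`ℓ` and `ν` with Menger certificates (disjoint path systems and separating
cuts), exact pattern tensors and flattenings by variable elimination,
SVD-based numerical rank and split scores, certified exact rank over prime
fields for rationally specified parameters, SPR/TBR neighbourhood
enumeration with breadth-first certification, and seeded generators for
trees, generic parameters and simulated alignments.

## Worked example

```r
library(flatrank)
tr <- parse_newick("((1,2)u,(3,4)v);")       # quartet, internal vertices u, v
params <- random_generic_params(tr, r = 2, seed = 1, rational = TRUE)

fl <- build_flattening(tr, params, c("1","2"), c("3","4"))
round(fl$matrix, 4)
#>        [,1]   [,2]   [,3]   [,4]
#> [1,] 0.0541 0.0888 0.0291 0.0462
#> [2,] 0.0774 0.1282 0.0390 0.0633
#> [3,] 0.0469 0.0774 0.0243 0.0391
#> [4,] 0.0721 0.1195 0.0360 0.0586
flattening_rank(fl)
#> rank 2 (numerical, tol 2.76e-10, gap 2.26e+14)
split_score(fl)
#> [1] 4.661331e-17
```

The rows enumerate the four state assignments to taxa 1, 2 (last taxon
fastest) and columns those to 3, 4, so entry (1, 2) is the pattern
probability `p_RRRY`.  Because `{1,2}|{3,4}` is the split of the internal
edge, `ν = 1` and the flattening has rank `r = 2` — 14 orders of magnitude
separate the second and third singular values — and the split score is
numerically zero.  The interleaved bipartition is not a split of this
tree:

```r
verify_rank_theorem(tr, params, c("1","3"), c("2","4"))
#> nu = 2, predicted rank 2^2 = 4; rank = 4 (exact); AGREE
split_distance(tr, c("1","3"), c("2","4"), certify = TRUE)
#> split 1,3 | 2,4: nu = 2, SPR/TBR distance = 1 (BFS: spr 1, tbr 1)
```

Here `ν = 2` (both internal vertices must be removed), the certified rank
is `2² = 4`, and one SPR move reaches a quartet containing the split —
exactly `ν − 1`.

A command-line front end with the same operations is installed as
`exec/flatrank` inside the package directory, e.g.

```sh
flatrank nu --tree t.nwk --A 1,2 --B 3,4
flatrank verify --tree t.nwk --A 1,3 --B 2,4 --r 2 --seed 5
flatrank suite --seed 1
```

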