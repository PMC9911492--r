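# Seeded verification harnesses.  Each runs one study at a configurable
# scale and returns machine-readable counts; the test suite, run_suite()
# and the acceptance script all call these.

#' Exhaustive-enumeration marginal probability (test oracle)
#'
#' Sums the joint product formula over every extension of `f`; the
#' independent check for the message-passing marginals.
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params`.
#' @param f a `character_map`.
#' @return a probability.
#' @export
brute_force_marginal <- function(tree, params, f) {
  r <- params$r
  free <- setdiff(seq_len(tree$nv), f$dom)
  if (r^length(free) > 2^16) stop("too many extensions for brute force")
  w <- model_wiring(tree, params)
  Fv <- integer(tree$nv)
  Fv[f$dom] <- f$states
  total <- 0
  for (i in seq_len(r^length(free)) - 1L) {
    x <- i
    for (j in seq_along(free)) { Fv[free[j]] <- x %% r; x <- x %/% r }
    pr <- w$root_dist[Fv[w$root] + 1L]
    for (v in w$ord[-1L])
      pr <- pr * w$mats[[v]][Fv[w$parent[v]] + 1L, Fv[v] + 1L]
    total <- total + pr
  }
  total
}

# disjoint random vertex subsets, sizes bounded so flattenings stay small
random_disjoint_subsets <- function(tree, max_size = 3L, leaf_only = FALSE) {
  pool <- if (leaf_only) leaves(tree) else seq_len(tree$nv)
  sa <- sample.int(max_size, 1L)
  sb <- sample.int(max_size, 1L)
  while (sa + sb > length(pool)) {
    if (sb > 1L) sb <- sb - 1L else sa <- sa - 1L
  }
  picked <- sample(pool, sa + sb)
  list(A = picked[seq_len(sa)], B = picked[sa + seq_len(sb)])
}

#' Rank-formula harness
#'
#' Seeded random instances: trees of 4 to `max_leaves` leaves (binary and
#' multifurcating), r drawn from `r_choices`, random disjoint vertex subsets
#' (internal vertices allowed), rational generic parameters.  For each
#' instance the certified prime-field rank of the flattening is compared
#' with `r^nu`.
#' @param n_instances number of instances.
#' @param seed integer seed.
#' @param r_choices candidate state counts.
#' @param max_leaves largest tree size.
#' @return list: `n`, `agreements`, `all_agree`, `details` (data frame).
#' @export
harness_rank_formula <- function(n_instances = 50L, seed = 1L,
                                 r_choices = c(2L, 3L), max_leaves = 10L) {
  set.seed(seed)
  details <- vector("list", n_instances)
  for (i in seq_len(n_instances)) {
    n <- sample(4:max_leaves, 1L)
    binary <- i %% 2L == 0L
    tr <- if (binary) random_binary_tree(n) else random_tree(n)
    r <- sample(r_choices, 1L)
    params <- random_generic_params(tr, r, rational = TRUE)
    ss <- random_disjoint_subsets(tr)
    nu_size <- nu(tr, ss$A, ss$B)$size
    er <- exact_flattening_rank(tr, params, ss$A, ss$B)
    details[[i]] <- data.frame(
      instance = i, leaves = n, binary = binary, r = r,
      size_A = length(ss$A), size_B = length(ss$B),
      nu = nu_size, predicted = r^nu_size, rank = er$rank,
      primes_agree = er$agree,
      agree = er$agree && er$rank == r^nu_size)
  }
  details <- do.call(rbind, details)
  list(n = n_instances, agreements = sum(details$agree),
       all_agree = all(details$agree), details = details)
}

#' Edge-cut/vertex-cut equality harness
#'
#' On seeded random binary trees with random disjoint leaf subsets,
#' ell_T(A|B) must equal nu_T(A|B); on every instance (and on the star-tree
#' family, where the two differ) nu <= ell must hold.
#' @param n_trees number of random binary trees.
#' @param seed integer seed.
#' @param max_leaves largest tree size.
#' @return list with counts, including the star-tree family check
#'   (nu = 1 < ell = k for a star with k leaf pairs).
#' @export
harness_cut_equality <- function(n_trees = 200L, seed = 1L, max_leaves = 10L) {
  set.seed(seed)
  equal <- logical(n_trees)
  le <- logical(n_trees)
  for (i in seq_len(n_trees)) {
    n <- sample(4:max_leaves, 1L)
    tr <- random_binary_tree(n)
    ss <- random_disjoint_subsets(tr, leaf_only = TRUE)
    e <- ell(tr, ss$A, ss$B)$size
    v <- nu(tr, ss$A, ss$B)$size
    equal[i] <- e == v
    le[i] <- v <= e
  }
  # star trees: center c with 2k leaves, A and B alternating; every A-B path
  # passes through the center, so nu = 1 while ell = k
  star <- vapply(2:4, function(k) {
    n <- 2L * k
    edge <- cbind(rep(n + 1L, n), seq_len(n))
    st <- phylo_graph(edge, c(paste0("x", seq_len(n)), NA), root = n + 1L)
    A <- seq(1L, n, by = 2L); B <- seq(2L, n, by = 2L)
    nu(st, A, B)$size == 1L && ell(st, A, B)$size == k && 1L <= k
  }, logical(1))
  list(n = n_trees, equal = sum(equal), nu_le_ell = sum(le),
       all_equal = all(equal), all_nu_le_ell = all(le),
       star_family_ok = all(star))
}

#' Oracle-equivalence harness
#'
#' Compares the production algorithms with exhaustive oracles on seeded
#' small instances: Sankoff parsimony vs enumeration over all extensions,
#' flow-based nu vs enumeration over vertex subsets (with certificate
#' re-validation), and message-passing marginals vs summing the product
#' formula.
#' @param n_instances instances per comparison.
#' @param seed integer seed.
#' @return list of counts and the maximum marginal discrepancy.
#' @export
harness_oracles <- function(n_instances = 200L, seed = 1L) {
  set.seed(seed)
  ell_ok <- nu_ok <- logical(n_instances)
  marg_err <- numeric(n_instances)
  for (i in seq_len(n_instances)) {
    n <- sample(4:7, 1L)
    tr <- if (i %% 3L == 0L) random_tree(n) else random_binary_tree(n)
    r <- sample(2:4, 1L)
    # parsimony: domain = all leaves plus a random sprinkle of internals
    lv <- leaves(tr)
    extra <- setdiff(seq_len(tr$nv), lv)
    extra <- extra[stats::runif(length(extra)) < 0.3]
    dom <- c(lv, extra)
    f <- character_map(tr, dom, sample(0:(r - 1L), length(dom), replace = TRUE), r = r)
    ell_ok[i] <- parsimony_length(tr, f) == brute_force_ell(tr, f)
    # vertex cut, internal vertices allowed in A and B
    ss <- random_disjoint_subsets(tr)
    res <- nu(tr, ss$A, ss$B)
    validate_cut_result(tr, ss$A, ss$B, res)
    nu_ok[i] <- res$size == brute_force_nu(tr, ss$A, ss$B)
    # marginals (float parameters; a small tree keeps the enumeration cheap)
    r2 <- sample(2:3, 1L)
    tr2 <- random_binary_tree(sample(4:5, 1L))
    params <- random_generic_params(tr2, r2)
    nd <- sample.int(3L, 1L)
    dom2 <- sample(tr2$nv, nd)
    f2 <- character_map(tr2, dom2, sample(0:(r2 - 1L), nd, replace = TRUE), r = r2)
    marg_err[i] <- abs(marginal_prob(tr2, params, f2) -
                         brute_force_marginal(tr2, params, f2))
  }
  list(n = n_instances,
       ell_agree = sum(ell_ok), nu_agree = sum(nu_ok),
       max_marginal_error = max(marg_err),
       all_agree = all(ell_ok) && all(nu_ok) && max(marg_err) <= 1e-12)
}

#' Split-rank dichotomy harness
#'
#' On a seeded quartet and 6-leaf binary tree with rational generic
#' parameters: every edge-induced split must have certified rank exactly r,
#' and every leaf bipartition that is not a split of the tree must have
#' rank at least r^2.
#' @param seed integer seed.
#' @param r state count.
#' @return list of counts over both trees.
#' @export
harness_split_dichotomy <- function(seed = 1L, r = 2L) {
  set.seed(seed)
  trees <- list(random_binary_tree(4L), random_binary_tree(6L))
  split_ok <- 0L; split_n <- 0L
  nonsplit_ok <- 0L; nonsplit_n <- 0L
  for (tr in trees) {
    params <- random_generic_params(tr, r, rational = TRUE)
    labs <- leaf_labels(tr)
    in_tree <- vapply(tree_splits(tr),
                      function(s) paste(sort(s$A), collapse = ","), character(1))
    # enumerate all non-trivial leaf bipartitions via the side holding labs[1]
    others <- setdiff(labs, labs[1L])
    for (mask in 0:(2^length(others) - 1L)) {
      side <- c(labs[1L], others[bitwAnd(mask, 2^(seq_along(others) - 1L)) > 0])
      rest <- setdiff(labs, side)
      if (!length(rest)) next
      rk <- exact_flattening_rank(tr, params, side, rest)$rank
      if (paste(sort(side), collapse = ",") %in% in_tree ||
          paste(sort(rest), collapse = ",") %in% in_tree) {
        split_n <- split_n + 1L
        if (rk == r) split_ok <- split_ok + 1L
      } else {
        nonsplit_n <- nonsplit_n + 1L
        if (rk >= r^2L) nonsplit_ok <- nonsplit_ok + 1L
      }
    }
  }
  list(split_ok = split_ok, split_n = split_n,
       nonsplit_ok = nonsplit_ok, nonsplit_n = nonsplit_n,
       all_ok = split_ok == split_n && nonsplit_ok == nonsplit_n)
}

#' Tree-distance harness
#'
#' For every non-trivial split of each seeded 6-leaf binary tree, certifies
#' by exhaustive BFS over both the SPR and the TBR rearrangement graphs that
#' the distance to the nearest tree containing the split equals nu - 1, and
#' checks SPR(T) is a subset of TBR(T) for every expanded topology.
#' @param n_trees number of seeded 6-leaf trees.
#' @param seed integer seed.
#' @param n_leaves leaves per tree.
#' @return list of counts.
#' @export
harness_tree_distance <- function(n_trees = 10L, seed = 1L, n_leaves = 6L) {
  set.seed(seed)
  cache <- new.env(parent = emptyenv())
  certified <- 0L; total <- 0L
  spr_subset_tbr <- TRUE
  for (t in seq_len(n_trees)) {
    tr <- random_binary_tree(n_leaves)
    labs <- sort(leaf_labels(tr))
    bit <- 2^(seq_along(labs) - 1L); names(bit) <- labs
    sprk <- vapply(spr_neighbors(tr), topology_key, character(1))
    tbrk <- vapply(tbr_neighbors(tr), topology_key, character(1))
    if (!all(sprk %in% tbrk)) spr_subset_tbr <- FALSE
    # non-trivial splits, each written from the side holding the first taxon
    others <- labs[-1L]
    sides <- list()
    for (mask in 1:(2^length(others) - 1L)) {
      side <- c(labs[1L], others[bitwAnd(mask, 2^(seq_along(others) - 1L)) > 0])
      if (length(side) >= 2L && length(side) <= n_leaves - 2L)
        sides[[length(sides) + 1L]] <- side
    }
    nus <- vapply(sides, function(s)
      nu(tr, s, setdiff(labs, s))$size, integer(1))
    max_depth <- max(nus) - 1L
    # one BFS per move type; a split at BFS distance d shows up as a split
    # mask of some topology in layer d and in no earlier layer
    dist_for <- function(move) {
      layers <- bfs_layers(tr, move, max_depth, cache = cache)
      lmask <- lapply(layers, function(ts)
        unique(unlist(lapply(ts, function(x) {
          em <- edge_child_masks(x)
          ifelse(em$child_mask %% 2 == 1, em$child_mask, em$total - em$child_mask)
        }))))
      vapply(sides, function(s) {
        m <- sum(bit[s])                       # contains the anchor bit
        for (d in seq_along(lmask)) if (m %in% lmask[[d]]) return(d - 1L)
        NA_integer_
      }, integer(1))
    }
    d_spr <- dist_for("spr")
    d_tbr <- dist_for("tbr")
    total <- total + length(sides)
    certified <- certified +
      sum(!is.na(d_spr) & d_spr == nus - 1L & !is.na(d_tbr) & d_tbr == nus - 1L)
  }
  list(n_trees = n_trees, total_splits = total, certified = certified,
       all_certified = certified == total, spr_subset_tbr = spr_subset_tbr)
}

# quartet fixture rooted on the internal edge: ((1,2),(3,4)) with internal
# vertices u (root) and v
quartet_fixture <- function(labels = c("1", "2", "3", "4")) {
  edge <- rbind(c(5L, 1L), c(5L, 2L), c(5L, 6L), c(6L, 3L), c(6L, 4L))
  phylo_graph(edge, c(labels, "u", "v"), root = 5L, rooted = TRUE)
}

#' Condition-necessity harness
#'
#' On the two-state quartet with rational generic parameters: the generic
#' non-split flattening has certified rank 4; zeroing one root entry drops
#' it to 2; zeroing one internal-edge entry drops it to 3 — so neither (C2)
#' nor (C3) can be dropped from the rank formula's hypotheses.
#' @param seed integer seed.
#' @return list with the three certified ranks and the diagonal predictions.
#' @export
harness_degeneracy <- function(seed = 1L) {
  tr <- quartet_fixture()
  params <- random_generic_params(tr, 2L, seed = seed, rational = TRUE)
  control <- degeneracy_demo(tr, params)
  root0 <- degeneracy_demo(tr, params, zero = list(kind = "root", i = 0L))
  edge0 <- degeneracy_demo(tr, params,
                           zero = list(kind = "edge", u = "u", v = "v",
                                       i = 0L, j = 0L))
  list(generic_rank = control$rank, root_zero_rank = root0$rank,
       edge_zero_rank = edge0$rank,
       predictions = c(control$predicted_rank, root0$predicted_rank,
                       edge0$predicted_rank),
       ok = control$rank == 4L && root0$rank == 2L && edge0$rank == 3L &&
         root0$rank == root0$predicted_rank &&
         edge0$rank == edge0$predicted_rank)
}

#' Model-plumbing harness
#'
#' Basic distributional sanity on a seeded quartet and a seeded 7-leaf
#' tree: the full pattern tensor sums to 1; rerooting preserves the leaf
#' pattern tensor; the split score of a true split on exact probabilities
#' is 0.
#' @param seed integer seed.
#' @return list of the measured discrepancies.
#' @export
harness_model_plumbing <- function(seed = 1L) {
  set.seed(seed)
  trees <- list(quartet_fixture(), random_binary_tree(7L))
  sum_err <- reroot_err <- score <- 0
  for (tr in trees) {
    r <- 2L + (tr$nv > 6L)
    params <- random_generic_params(tr, r)
    tens <- pattern_tensor(tr, params)
    sum_err <- max(sum_err, abs(sum(tens) - 1))
    nr <- sample(setdiff(seq_len(tr$nv), c(params$root, leaves(tr))), 1L)
    params2 <- reroot_params(tr, params, nr)
    reroot_err <- max(reroot_err, max(abs(pattern_tensor(tr, params2) - tens)))
    ie <- internal_edges(tr)
    sp <- induced_split(tr, ie[sample.int(nrow(ie), 1L), ])
    fl <- build_flattening(tr, params, sp$A, sp$B)
    score <- max(score, split_score(fl, k = 1L))
  }
  list(tensor_sum_error = sum_err, reroot_error = reroot_err,
       true_split_score = score,
       ok = sum_err <= 1e-10 && reroot_err <= 1e-12 && score <= 1e-9)
}
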