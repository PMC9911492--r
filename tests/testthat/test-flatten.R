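# independent oracle for flattening entries: sum the joint product formula
# over all extensions of the row/column assignment
enum_flat_entry <- function(tree, params, verts, states) {
  free <- setdiff(seq_len(tree$nv), verts)
  total <- 0
  r <- params$r
  Fv <- integer(tree$nv)
  Fv[verts] <- states
  for (i in seq_len(r^length(free)) - 1L) {
    x <- i
    for (j in seq_along(free)) { Fv[free[j]] <- x %% r; x <- x %/% r }
    total <- total + joint_probability(tree, params, Fv)
  }
  total
}

test_that("the flattening layout enumerates assignments last-vertex-fastest", {
  q <- make_rooted_quartet()
  params <- random_generic_params(q, 2, seed = 1)
  lv <- resolve_vertices(q, c("1", "2", "3", "4"))
  fl <- build_flattening(q, params, c("1", "2"), c("3", "4"))
  expect_equal(dim(fl$matrix), c(4L, 4L))
  asg <- flatrank:::state_assignments(2, 2)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(fl$matrix[i, j],
                 enum_flat_entry(q, params, lv, c(asg[i, ], asg[j, ])),
                 tolerance = 1e-12)
  }
  # the (RR, RY) entry is the pattern probability p_RRRY
  expect_equal(fl$matrix[1, 2],
               enum_flat_entry(q, params, lv, c(0L, 0L, 0L, 1L)),
               tolerance = 1e-14)

  # one-versus-rest flattening is 2 x 8 with the same convention
  fl1 <- build_flattening(q, params, "1", c("2", "3", "4"))
  expect_equal(dim(fl1$matrix), c(2L, 8L))
  asg3 <- flatrank:::state_assignments(3, 2)
  for (j in 1:8)
    expect_equal(fl1$matrix[2, j],
                 enum_flat_entry(q, params, lv, c(1L, asg3[j, ])),
                 tolerance = 1e-12)
  expect_error(build_flattening(q, params, c("1", "2"), c("2", "3")), "disjoint")
})

test_that("deterministic identity-edge models give the degenerate flattening", {
  q <- make_rooted_quartet()
  mats <- random_generic_params(q, 2, seed = 1)$mats
  p_id <- gmm_params(q, 5L, c(0.5, 0.5), lapply(mats, function(m) diag(2)))
  fl <- build_flattening(q, p_id, c("1", "2"), c("3", "4"))
  expect_equal(sum(fl$matrix > 0), 2L)
  expect_equal(sort(unique(as.vector(fl$matrix))), c(0, 0.5))
  expect_equal(flattening_rank(fl)$numerical_rank, 2L)
})

test_that("generic quartet flattenings have rank r for splits, r^2 across", {
  q <- make_quartet()
  for (r in 2:3) {
    params <- random_generic_params(q, r, seed = 40 + r, rational = TRUE)
    fl_split <- build_flattening(q, params, c("1", "2"), c("3", "4"))
    fl_cross <- build_flattening(q, params, c("1", "3"), c("2", "4"))
    expect_equal(flattening_rank(fl_split)$numerical_rank, r)
    expect_equal(flattening_rank(fl_cross)$numerical_rank, r^2L)
    expect_equal(exact_flattening_rank(q, params, c("1", "2"), c("3", "4"))$rank, r)
    expect_equal(exact_flattening_rank(q, params, c("1", "3"), c("2", "4"))$rank, r^2L)
    # exact flattening entries sum to 1 and are strictly positive
    expect_equal(sum(fl_cross$matrix), 1, tolerance = 1e-12)
    expect_true(all(fl_cross$matrix > 0))
  }
})

test_that("split scores vanish exactly on splits of the tree", {
  q <- make_quartet()
  params <- random_generic_params(q, 2, seed = 11)
  fl_split <- build_flattening(q, params, c("1", "2"), c("3", "4"))
  expect_lt(split_score(fl_split, k = 1), 1e-9)
  fl_cross <- build_flattening(q, params, c("1", "3"), c("2", "4"))
  expect_gt(split_score(fl_cross, k = 1), 1e-3)
  expect_equal(split_score(fl_cross, k = 2), 0, tolerance = 1e-12)
  expect_error(split_score(fl_cross, k = 3), "dimension")
})

test_that("numerical rank is invariant under reordering within each side", {
  tr <- random_binary_tree(6, seed = 9)
  params <- random_generic_params(tr, 2, seed = 9)
  A <- leaf_labels(tr)[c(1, 3, 5)]; B <- leaf_labels(tr)[c(2, 6)]
  r1 <- flattening_rank(build_flattening(tr, params, A, B))$numerical_rank
  r2 <- flattening_rank(build_flattening(tr, params, rev(A), B))$numerical_rank
  r3 <- flattening_rank(build_flattening(tr, params, A[c(2, 1, 3)], rev(B)))$numerical_rank
  expect_equal(r1, r2)
  expect_equal(r1, r3)
})

test_that("empirical flattenings aggregate pattern frequencies", {
  q <- make_quartet()
  lv <- leaf_labels(q)
  one <- matrix(0L, 4, 1, dimnames = list(lv, NULL))
  fl <- empirical_flattening(one, lv[1:2], lv[3:4], r = 2)
  expect_equal(fl$matrix[1, 1], 1)
  expect_equal(sum(fl$matrix), 1)

  # one column per pattern: the uniform rank-1 flattening
  pats <- t(flatrank:::state_assignments(4, 2))
  rownames(pats) <- lv
  flu <- empirical_flattening(pats, lv[1:2], lv[3:4], r = 2)
  expect_true(all(flu$matrix == 1 / 16))
  expect_equal(flattening_rank(flu)$numerical_rank, 1L)
  expect_equal(split_score(flu, k = 1), 0, tolerance = 1e-12)

  # sampled data: the true split scores low
  params <- random_generic_params(q, 2, seed = 3)
  aln <- simulate_alignment(q, params, 50000, seed = 12)
  fle <- empirical_flattening(aln, lv[1:2], lv[3:4], r = 2)
  expect_lt(split_score(fle, k = 1), 0.05)
  expect_error(empirical_flattening(aln, c("1", "zz"), c("3", "4")), "unknown taxon")
})

test_that("marginalizing a flattening multiplies by 0-1 matrices (rank monotone)", {
  set.seed(77)
  for (i in 1:8) {
    tr <- random_binary_tree(sample(5:7, 1))
    r <- sample(2:3, 1)
    params <- random_generic_params(tr, r)
    ss <- flatrank:::random_disjoint_subsets(tr)
    if (length(ss$A) < 2 && length(ss$B) < 2) next
    A <- ss$A; B <- ss$B
    Ap <- A[sample.int(length(A), max(1, length(A) - 1))]
    Bp <- B[sample.int(length(B), max(1, length(B) - 1))]
    big <- build_flattening(tr, params, A, B)
    small <- build_flattening(tr, params, Ap, Bp)
    UA <- marginalization_matrix(Ap, A, r)
    UB <- marginalization_matrix(Bp, B, r)
    expect_tensor_equal(small$matrix, UA %*% big$matrix %*% t(UB))
    expect_lte(flattening_rank(small)$numerical_rank,
               flattening_rank(big)$numerical_rank)
  }
})

test_that("the flattening factorizes across a minimum vertex cut", {
  set.seed(55)
  for (i in 1:8) {
    tr <- if (i %% 2) random_binary_tree(sample(5:7, 1)) else
      random_tree(sample(5:7, 1))
    params <- random_generic_params(tr, 2)
    ss <- flatrank:::random_disjoint_subsets(tr)
    cf <- cut_factorization(tr, params, ss$A, ss$B)
    expect_tensor_equal(cf$product, cf$flat)
  }
  # star tree: the cut is the centre, shared by all paths
  st <- make_star(4)
  params <- random_generic_params(st, 2, seed = 5)
  cf <- cut_factorization(st, params, c("x1", "x2"), c("x3", "x4"))
  expect_equal(cf$C, resolve_vertices(st, "ctr"))
  expect_tensor_equal(cf$product, cf$flat)
})
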