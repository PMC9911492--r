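test_that("the joint probability is the product over root and edges", {
  two <- phylo_graph(cbind(1L, 2L), c("a", "b"), root = 1L)
  p <- gmm_params(two, 1L, c(0.5, 0.5), list("1>2" = diag(2)))
  expect_equal(joint_probability(two, p, c(0L, 0L)), 0.5)
  expect_equal(joint_probability(two, p, c(0L, 1L)), 0)   # annihilated entry

  q <- make_rooted_quartet()
  params <- random_generic_params(q, 2, seed = 21)
  total <- 0
  for (i in 0:(2^6 - 1)) {
    F <- as.integer(intToBits(i))[1:6]
    total <- total + joint_probability(q, params, F)
  }
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("message-passing marginals agree with exhaustive enumeration", {
  q <- make_rooted_quartet()
  params <- random_generic_params(q, 3, seed = 5)
  # full domain reduces to the joint probability
  F <- c(2L, 0L, 1L, 2L, 0L, 1L)
  f_full <- character_map(q, 1:6, F, r = 3)
  expect_equal(marginal_prob(q, params, f_full), joint_probability(q, params, F))
  # single-vertex marginals are strictly positive under (C1)-(C3)
  for (v in 1:6) for (s in 0:2) {
    f <- character_map(q, v, s, r = 3)
    m <- marginal_prob(q, params, f)
    expect_gt(m, 0)
    expect_equal(m, brute_force_marginal(q, params, f), tolerance = 1e-12)
  }
  # pairwise joint matrices are nonsingular (including non-adjacent pairs)
  set.seed(8)
  for (k in 1:5) {
    uv <- sample(1:6, 2)
    M <- matrix(as.numeric(joint_tensor(q, params, uv)), 3, byrow = TRUE)
    expect_gt(abs(det(M)), 1e-12)
  }
})

test_that("the pattern tensor is a distribution and rerooting preserves it", {
  trees <- list(make_rooted_quartet(), random_binary_tree(6, seed = 3))
  for (tr in trees) {
    params <- random_generic_params(tr, 2, seed = 13)
    tens <- pattern_tensor(tr, params)
    expect_equal(sum(tens), 1, tolerance = 1e-10)
    expect_true(all(tens > 0))
    expect_identical(reroot_params(tr, params, params$root), params)
    for (nr in setdiff(seq_len(tr$nv), params$root)[1:3]) {
      p2 <- reroot_params(tr, params, nr)
      expect_true(check_conditions(tr, p2)$all_pass)
      expect_tensor_equal(pattern_tensor(tr, p2), tens)
      back <- reroot_params(tr, p2, params$root)
      expect_tensor_equal(pattern_tensor(tr, back), tens)
    }
  }
})

test_that("condition checking reports violations with witnesses", {
  two <- phylo_graph(cbind(1L, 2L), c("a", "b"), root = 1L)
  p_badroot <- gmm_params(two, 1L, c(0, 1), list("1>2" = diag(2)))
  cc <- check_conditions(two, p_badroot)
  expect_false(cc$C2$pass)
  expect_match(cc$C2$witness, "state 0")

  q <- make_rooted_quartet()
  params <- random_generic_params(q, 2, seed = 2)
  # identity matrix on a pendant edge: C1 fine, C3 not applicable
  params$mats[["5>1"]] <- diag(2)
  cc <- check_conditions(q, params)
  expect_true(cc$C1$pass)
  expect_true(cc$C3$pass)
  # equal rows on any edge break C1
  params$mats[["5>1"]] <- matrix(0.5, 2, 2)
  cc <- check_conditions(q, params)
  expect_false(cc$C1$pass)
  expect_match(cc$C1$witness, "5>1")
  # a zero on the internal edge breaks C3
  params2 <- random_generic_params(q, 2, seed = 2)
  params2$mats[["5>6"]][1, 1] <- 0
  params2$mats[["5>6"]][1, 2] <- 1
  expect_false(check_conditions(q, params2)$C3$pass)
})

test_that("the parameter generator is deterministic and generic", {
  q <- make_quartet()
  a <- random_generic_params(q, 3, seed = 99)
  b <- random_generic_params(q, 3, seed = 99)
  expect_identical(a, b)
  for (seed in 1:25) {
    p <- random_generic_params(q, 2, seed = seed, rational = seed %% 2 == 0)
    expect_true(check_conditions(q, p)$all_pass)
    if (!is.null(p$rational)) {
      # the rational representation reproduces the numeric matrices exactly
      for (k in names(p$mats))
        expect_equal(p$rational$mats[[k]]$num / p$rational$mats[[k]]$den,
                     p$mats[[k]])
      expect_equal(p$rational$root_num / p$rational$root_den, p$root_dist)
    }
  }
})

test_that("alignment simulation is seeded and matches the model", {
  q <- make_rooted_quartet()
  params <- random_generic_params(q, 2, seed = 4)
  expect_equal(ncol(simulate_alignment(q, params, 0, seed = 1)), 0L)
  a1 <- simulate_alignment(q, params, 100, seed = 7)
  a2 <- simulate_alignment(q, params, 100, seed = 7)
  expect_identical(a1, a2)
  expect_equal(rownames(a1), leaf_labels(q))

  # identity transitions propagate the root state unchanged down the tree
  id_mats <- lapply(params$mats, function(m) diag(2))
  p_id <- gmm_params(q, params$root, c(0.5, 0.5), id_mats)
  aln <- simulate_alignment(q, p_id, 50, seed = 1)
  expect_true(all(apply(aln, 2, function(col) length(unique(col)) == 1L)))

  # binomial concentration of empirical pattern frequencies
  n <- 50000
  aln <- simulate_alignment(q, params, n, seed = 31)
  tens <- as.numeric(pattern_tensor(q, params))
  lv <- leaf_labels(q)
  idx <- rep(0, n)
  for (k in seq_along(lv)) idx <- idx * 2 + aln[lv[k], ]
  emp <- tabulate(idx + 1, nbins = 16) / n
  within <- abs(emp - tens) <= 3 * sqrt(tens * (1 - tens) / n)
  expect_gte(sum(within), 15L)
})

test_that("parameters and alignments round-trip through YAML and FASTA", {
  tr <- make_quartet()
  params <- random_generic_params(tr, 2, seed = 6)
  yml <- tempfile(fileext = ".yaml")
  write_params_yaml(tr, params, yml)
  back <- read_params_yaml(tr, yml)
  expect_equal(back$root_dist, params$root_dist, tolerance = 1e-12)
  for (k in names(params$mats))
    expect_equal(back$mats[[k]], params$mats[[k]], tolerance = 1e-12)

  aln <- simulate_alignment(tr, params, 20, seed = 2)
  fa <- tempfile(fileext = ".fasta")
  write_alignment_fasta(aln, fa, r = 2)
  back_aln <- read_alignment_fasta(fa, r = 2)
  expect_equal(back_aln[rownames(aln), ], aln)
})
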