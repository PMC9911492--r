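test_that("the rank formula verifies on quartets and random instances", {
  q <- make_quartet()
  params <- random_generic_params(q, 2, seed = 10, rational = TRUE)
  rep_split <- verify_rank_theorem(q, params, c("1", "2"), c("3", "4"))
  expect_equal(rep_split$nu, 1L)
  expect_equal(rep_split$exact_rank, 2L)
  expect_true(rep_split$agree)
  expect_true(rep_split$ell_equals_nu)

  rep_cross <- verify_rank_theorem(q, params, c("1", "3"), c("2", "4"))
  expect_equal(rep_cross$nu, 2L)
  expect_equal(rep_cross$exact_rank, 4L)
  expect_true(rep_cross$agree)

  # internal vertices in A and B
  rep_int <- verify_rank_theorem(q, params, c("1", "v"), c("u", "4"))
  expect_true(rep_int$agree)

  set.seed(123)
  for (i in 1:6) {
    tr <- random_binary_tree(8)
    p3 <- random_generic_params(tr, 3, rational = TRUE)
    ss <- flatrank:::random_disjoint_subsets(tr, leaf_only = TRUE)
    rep <- verify_rank_theorem(tr, p3, ss$A, ss$B)
    expect_true(rep$agree)
    expect_true(rep$exact_primes_agree)
    expect_true(rep$ell_equals_nu)
  }
})

test_that("verification refuses parameters violating the conditions", {
  q <- make_quartet()
  params <- random_generic_params(q, 2, seed = 1)
  bad <- flatrank:::zero_param_entry(params, list(kind = "root", i = 0L))
  expect_error(verify_rank_theorem(q, bad, c("1", "3"), c("2", "4")),
               "degeneracy_demo")
})

test_that("quartet rearrangement neighbourhoods cover the other topologies", {
  q <- make_quartet()
  nb <- spr_neighbors(q)
  expect_length(nb, 2L)
  keys <- vapply(nb, flatrank:::topology_key, character(1))
  expect_length(unique(keys), 2L)
  expect_false(flatrank:::topology_key(q) %in% keys)
  # both alternative quartets appear
  alt1 <- parse_newick("((1,3),(2,4));")
  alt2 <- parse_newick("((1,4),(2,3));")
  expect_setequal(keys, vapply(list(alt1, alt2), flatrank:::topology_key,
                               character(1)))
  expect_error(spr_neighbors(parse_newick("(a,b,c,d);")), "binary")
})

test_that("SPR neighbourhoods are contained in TBR neighbourhoods and reverse", {
  set.seed(31)
  for (i in 1:10) {
    tr <- random_binary_tree(6)
    sprk <- vapply(spr_neighbors(tr), flatrank:::topology_key, character(1))
    tbrk <- vapply(tbr_neighbors(tr), flatrank:::topology_key, character(1))
    expect_true(all(sprk %in% tbrk))
  }
  # moves are reversible: the origin is in each neighbour's neighbourhood
  tr <- random_binary_tree(5, seed = 2)
  k0 <- flatrank:::topology_key(tr)
  for (nb in spr_neighbors(tr)[1:3]) {
    back <- vapply(spr_neighbors(nb), flatrank:::topology_key, character(1))
    expect_true(k0 %in% back)
  }
})

test_that("split distance equals the vertex cut size minus one", {
  q <- make_quartet()
  d0 <- split_distance(q, c("1", "2"), c("3", "4"), certify = TRUE)
  expect_equal(d0$nu, 1L)
  expect_equal(d0$spr_distance, 0L)
  expect_equal(d0$bfs_spr_distance, 0L)

  d1 <- split_distance(q, c("1", "3"), c("2", "4"), certify = TRUE)
  expect_equal(d1$spr_distance, 1L)
  expect_equal(d1$bfs_spr_distance, 1L)
  expect_equal(d1$bfs_tbr_distance, 1L)
  expect_true(has_split(d1$witness, split_spec(c("1", "3"), c("2", "4"))))

  cat6 <- make_caterpillar6()
  cache <- new.env(parent = emptyenv())
  for (side in list(c("1", "4"), c("1", "5", "6"), c("2", "5"))) {
    rest <- setdiff(leaf_labels(cat6), side)
    d <- split_distance(cat6, side, rest, certify = TRUE, cache = cache)
    expect_equal(d$bfs_spr_distance, d$nu - 1L)
    expect_equal(d$bfs_tbr_distance, d$nu - 1L)
  }
  expect_error(split_distance(q, c("1", "2"), c("3")), "bipartition")
})

test_that("zeroed root or internal-edge entries drop the non-split rank", {
  tr <- make_rooted_quartet()
  params <- random_generic_params(tr, 2, seed = 77, rational = TRUE)
  control <- degeneracy_demo(tr, params)
  expect_equal(control$rank, 4L)
  expect_false(control$dropped)
  expect_equal(control$predicted_rank, 4L)

  root0 <- degeneracy_demo(tr, params, zero = list(kind = "root", i = 1L))
  expect_equal(root0$rank, 2L)
  expect_equal(root0$numerical_rank, 2L)
  expect_equal(root0$predicted_rank, 2L)
  expect_true(root0$dropped)

  edge0 <- degeneracy_demo(tr, params,
                           zero = list(kind = "edge", u = "u", v = "v",
                                       i = 1L, j = 0L))
  expect_equal(edge0$rank, 3L)
  expect_equal(edge0$predicted_rank, 3L)
  expect_true(edge0$dropped)
})
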