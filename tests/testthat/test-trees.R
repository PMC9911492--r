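test_that("Newick parsing recovers the expected structure", {
  tr <- parse_newick("((1,2),(3,4));")
  expect_equal(tr$nv, 6L)
  expect_length(leaves(tr), 4L)
  expect_setequal(leaf_labels(tr), c("1", "2", "3", "4"))
  expect_equal(nrow(tr$edge), 5L)

  star <- parse_newick("(a,b,c,d)x;")
  deg <- flatrank:::vertex_degrees(star)
  expect_equal(max(deg), 4L)
  expect_equal(star$labels[which.max(deg)], "x")

  expect_error(parse_newick("((a,b),(c,d);"), "parenthes")
  expect_error(parse_newick("((a,b),(a,d));"), "duplicate")
  expect_error(parse_newick(""), "empty")
})

test_that("Newick writing round-trips internal labels and topology", {
  tr <- parse_newick("((a,b)u,(c,(d,e)w)v)root;")
  expect_true(all(c("u", "v", "w", "root") %in% tr$labels))
  back <- parse_newick(write_newick(tr))
  expect_true(same_topology(tr, back))
  expect_setequal(back$labels[!is.na(back$labels)],
                  tr$labels[!is.na(tr$labels)])
})

test_that("random trees round-trip and satisfy tree counting identities", {
  for (seed in 1:50) {
    n <- 4L + (seed %% 9L)
    tr <- random_binary_tree(n, seed = seed)
    expect_equal(nrow(tr$edge), tr$nv - 1L)
    back <- parse_newick(write_newick(tr))
    expect_true(same_topology(tr, back))
    # a binary n-leaf unrooted tree has 2n-3 edges, all with distinct splits
    keys <- vapply(tree_splits(tr), function(s)
      paste(sort(s$A), collapse = ","), character(1))
    expect_equal(length(unique(keys)), 2L * n - 3L)
    mt <- random_tree(n, seed = seed, contract_prob = 0.4)
    expect_equal(nrow(mt$edge), mt$nv - 1L)
    expect_setequal(leaf_labels(mt), leaf_labels(tr))
  }
})

test_that("binarity is judged by degree (unrooted) or out-degree (rooted)", {
  expect_true(is_binary_tree(make_quartet()))
  expect_false(is_binary_tree(parse_newick("(a,b,c,d);")))
  expect_true(is_binary_tree(parse_newick("((a,b),(c,d));", rooted = TRUE)))
  expect_false(is_binary_tree(random_tree(8, seed = 4, contract_prob = 1)))
})

test_that("edge deletion induces the expected leaf bipartitions", {
  q <- make_quartet()
  sp <- induced_split(q, c("u", "v"))
  expect_setequal(sp$A, c("1", "2"))
  expect_setequal(sp$B, c("3", "4"))
  pend <- induced_split(q, c("1", "u"))
  expect_equal(sort(c(pend$A, pend$B))[1], "1")
  expect_true(setequal(pend$A, "1") || setequal(pend$B, "1"))

  cat6 <- make_caterpillar6()
  mid <- induced_split(cat6, c("b", "d"))
  expect_setequal(mid$A, c("1", "2", "3"))
  expect_setequal(mid$B, c("4", "5", "6"))
  expect_error(induced_split(q, c("1", "2")), "unknown edge")
})

test_that("rerooting reorients every edge away from the new root", {
  tr <- random_binary_tree(7, seed = 2)
  v <- setdiff(seq_len(tr$nv), leaves(tr))[2]
  rr <- reroot(tr, v)
  expect_equal(rr$root, v)
  expect_setequal(apply(tr$edge, 1, function(e) paste(sort(e), collapse = "-")),
                  apply(rr$edge, 1, function(e) paste(sort(e), collapse = "-")))
  # parent is always one BFS level closer to the root
  depth <- integer(tr$nv)
  ord <- flatrank:::bfs_order(rr, v)
  for (i in seq_len(nrow(rr$edge)))
    depth[rr$edge[i, 2]] <- NA
  depth <- rep(NA_integer_, tr$nv); depth[v] <- 0L
  par <- integer(tr$nv); par[rr$edge[, 2]] <- rr$edge[, 1]
  for (w in ord[-1]) depth[w] <- depth[par[w]] + 1L
  expect_true(all(depth[rr$edge[, 1]] == depth[rr$edge[, 2]] - 1L))
  # involution
  back <- reroot(rr, tr$root)
  expect_equal(back$edge, tr$edge)
})

test_that("degree-2 suppression removes relic vertices only", {
  tr <- parse_newick("((a,b)u,(c,d)v);")
  # manually subdivide an edge, then suppress it away again
  sd <- flatrank:::subdivide_row(tr$edge, tr$labels, 1L, resolve_vertices(tr, "u"))
  with_relic <- phylo_graph(rbind(sd$edge), sd$labels, root = resolve_vertices(tr, "u"))
  expect_equal(with_relic$nv, tr$nv + 1L)
  clean <- suppress_degree2(with_relic)
  expect_true(same_topology(clean, tr))
})
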