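# Shared fixtures, built in code.

# unrooted quartet 12|34 with addressable internal vertices u, v
make_quartet <- function() parse_newick("((1,2)u,(3,4)v);")

# rooted quartet with the root on the internal edge (u = root)
make_rooted_quartet <- function() flatrank:::quartet_fixture()

# six-leaf caterpillar (((1,2),3),(4,(5,6)))
make_caterpillar6 <- function() parse_newick("(((1,2)a,3)b,(4,(5,6)c)d);")

# star tree: one center, n labeled leaves
make_star <- function(n, center_label = "ctr") {
  phylo_graph(cbind(rep(n + 1L, n), seq_len(n)),
              c(paste0("x", seq_len(n)), center_label),
              root = n + 1L)
}

expect_tensor_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(as.numeric(a) - as.numeric(b))), tol)
}
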