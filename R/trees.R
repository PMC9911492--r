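# Tree container and Newick I/O.
#
# Vertices are integer ids 1..nv.  Leaves (degree-1 vertices) carry unique
# taxon labels; internal vertices may carry optional labels so that vertex
# subsets A and B given to cut and flattening routines can include them.
# Every tree stores a reference orientation (edges directed away from `root`);
# the `rooted` flag says whether that root is semantic or merely a recorded
# reference, since none of the combinatorial quantities depend on it.

#' Construct a phylogeny from an edge list
#'
#' @param edge two-column integer matrix, one row per edge, oriented
#'   parent -> child away from `root`.
#' @param labels character vector, one entry per vertex (`NA` for unlabeled
#'   internal vertices).  All degree-1 vertices must be labeled, uniquely.
#' @param root integer id of the (reference) root vertex.
#' @param rooted logical; `TRUE` if the root is semantically meaningful.
#' @return an object of class `phylo_graph`.
#' @export
phylo_graph <- function(edge, labels, root = NULL, rooted = FALSE) {
  edge <- matrix(as.integer(edge), ncol = 2L)
  nv <- length(labels)
  if (nv < 2L) stop("a phylogeny needs at least two vertices")
  if (nrow(edge) != nv - 1L)
    stop("edge count must equal vertex count minus one (tree)")
  if (any(edge < 1L | edge > nv)) stop("edge refers to unknown vertex")
  if (is.null(root)) root <- edge[1L, 1L]
  obj <- structure(
    list(nv = nv, edge = edge, labels = as.character(labels),
         root = as.integer(root), rooted = isTRUE(rooted)),
    class = "phylo_graph")
  # connectivity check (counts alone don't rule out a cycle + isolated vertex)
  if (length(bfs_order(obj, root)) != nv) stop("graph is not connected")
  deg <- vertex_degrees(obj)
  lv <- which(deg == 1L)
  ll <- obj$labels[lv]
  if (anyNA(ll)) stop("every leaf must carry a taxon label")
  if (anyDuplicated(ll)) stop("duplicate taxon label: ", ll[duplicated(ll)][1L])
  obj <- reorient(obj, obj$root)
  obj
}

vertex_degrees <- function(tree) {
  tabulate(c(tree$edge[, 1L], tree$edge[, 2L]), nbins = tree$nv)
}

#' Leaf vertex ids of a tree
#' @param tree a `phylo_graph`.
#' @return integer vector of degree-1 vertex ids.
#' @export
leaves <- function(tree) which(vertex_degrees(tree) == 1L)

#' Taxon labels of a tree, in leaf-id order
#' @param tree a `phylo_graph`.
#' @return character vector of leaf labels.
#' @export
leaf_labels <- function(tree) tree$labels[leaves(tree)]

# adjacency list: integer neighbor vector per vertex
adjacency <- function(tree) {
  adj <- vector("list", tree$nv)
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

# breadth-first vertex order from a start vertex
bfs_order <- function(tree, start) {
  adj <- adjacency(tree)
  seen <- logical(tree$nv)
  seen[start] <- TRUE
  ord <- integer(0)
  queue <- start
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  ord
}

# reorient the stored edge matrix away from `root` (pure reference change)
reorient <- function(tree, root) {
  adj <- adjacency(tree)
  parent <- integer(tree$nv)
  ord <- bfs_order(tree, root)
  seen <- logical(tree$nv); seen[root] <- TRUE
  for (v in ord) for (w in adj[[v]]) if (!seen[w]) { parent[w] <- v; seen[w] <- TRUE }
  kids <- ord[-1L]
  tree$edge <- cbind(parent[kids], kids)
  tree$root <- as.integer(root)
  tree
}

#' Resolve vertex identifiers
#'
#' Accepts integer ids or label strings (taxon or internal labels) anywhere a
#' vertex is expected and returns integer ids.
#' @param tree a `phylo_graph`.
#' @param x integer ids, label strings, or a mix.
#' @return integer vertex ids.
#' @export
resolve_vertices <- function(tree, x) {
  if (is.numeric(x)) {
    ids <- as.integer(x)
    if (any(ids < 1L | ids > tree$nv)) stop("unknown vertex id: ",
                                            x[ids < 1L | ids > tree$nv][1L])
    return(ids)
  }
  ids <- match(as.character(x), tree$labels)
  if (anyNA(ids)) stop("unknown vertex label: ", x[is.na(ids)][1L])
  ids
}

#' Parse a Newick string
#'
#' Wraps [ape::read.tree()]; branch lengths are parsed and discarded (the
#' Markov model here carries transition matrices, not lengths).  Internal node
#' labels are preserved; unlabeled internal vertices remain addressable by
#' their deterministic integer id.
#'
#' @param text a Newick string (must end in `;`).
#' @param rooted treat the Newick root as semantic.  The default (`FALSE`)
#'   reads the tree as unrooted and suppresses an unlabeled degree-2
#'   top-level node, so `((1,2),(3,4));` yields the 6-vertex unrooted
#'   quartet; labeled degree-2 roots are kept so they stay addressable.
#' @return a `phylo_graph`.
#' @export
parse_newick <- function(text, rooted = FALSE) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("empty Newick input")
  s <- trimws(text)
  op <- lengths(regmatches(s, gregexpr("(", s, fixed = TRUE)))
  cl <- lengths(regmatches(s, gregexpr(")", s, fixed = TRUE)))
  if (op != cl) stop("malformed Newick: unbalanced parentheses in ", text)
  phy <- tryCatch(ape::read.tree(text = s),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick: ", text)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate taxon label: ", phy$tip.label[duplicated(phy$tip.label)][1L])
  ntip <- length(phy$tip.label)
  nv <- ntip + phy$Nnode
  labels <- rep(NA_character_, nv)
  labels[seq_len(ntip)] <- phy$tip.label
  if (!is.null(phy$node.label)) {
    nl <- phy$node.label
    nl[!nzchar(nl)] <- NA_character_
    labels[ntip + seq_len(phy$Nnode)] <- nl
  }
  if (anyDuplicated(stats::na.omit(labels)))
    stop("duplicate label: ",
         stats::na.omit(labels)[duplicated(stats::na.omit(labels))][1L])
  root <- ntip + 1L
  out <- phylo_graph(phy$edge, labels, root = root, rooted = isTRUE(rooted))
  if (!isTRUE(rooted) && is.na(out$labels[out$root]) &&
      vertex_degrees(out)[out$root] == 2L)
    out <- suppress_degree2(out, vertices = out$root)
  out
}

#' Write a tree as a Newick string
#'
#' Inverse of [parse_newick()] up to whitespace and child order: the result
#' re-parses to an isomorphic labeled tree.
#' @param tree a `phylo_graph`.
#' @return a single Newick string.
#' @export
write_newick <- function(tree) {
  phy <- as_ape_phylo(tree)
  ape::write.tree(phy)
}

# convert to ape's phylo (renumbering: tips first, then internals, root first)
as_ape_phylo <- function(tree) {
  deg <- vertex_degrees(tree)
  lv <- which(deg == 1L)
  iv <- which(deg > 1L)
  # root must be first internal node for a valid phylo
  iv <- c(tree$root, setdiff(iv, tree$root))
  if (deg[tree$root] == 1L)
    stop("cannot serialize a tree whose reference root is a leaf; reroot first")
  newid <- integer(tree$nv)
  newid[lv] <- seq_along(lv)
  newid[iv] <- length(lv) + seq_along(iv)
  edge <- cbind(newid[tree$edge[, 1L]], newid[tree$edge[, 2L]])
  node.label <- tree$labels[iv]
  node.label[is.na(node.label)] <- ""
  phy <- list(edge = edge, tip.label = tree$labels[lv],
              Nnode = length(iv), node.label = node.label)
  class(phy) <- "phylo"
  phy
}

#' Test whether a phylogeny is binary (fully resolved)
#'
#' Unrooted: every internal vertex has degree 3.  Rooted: the root has
#' out-degree 2 and every other internal vertex out-degree 2 (degree 3).
#' @param tree a `phylo_graph`.
#' @return logical.
#' @export
is_binary_tree <- function(tree) {
  deg <- vertex_degrees(tree)
  internal <- which(deg > 1L)
  if (!tree$rooted) return(all(deg[internal] == 3L))
  outdeg <- tabulate(tree$edge[, 1L], nbins = tree$nv)
  all(outdeg[internal] == 2L)
}

#' Leaf bipartition induced by deleting an edge
#'
#' @param tree a `phylo_graph`.
#' @param edge length-2 vector (vertex ids or labels) naming an existing edge.
#' @return a `split_spec` over taxon labels; the part whose sorted label
#'   vector is lexicographically smaller comes first.
#' @export
induced_split <- function(tree, edge) {
  uv <- resolve_vertices(tree, edge)
  hit <- which((tree$edge[, 1L] == uv[1L] & tree$edge[, 2L] == uv[2L]) |
               (tree$edge[, 1L] == uv[2L] & tree$edge[, 2L] == uv[1L]))
  if (!length(hit)) stop("unknown edge: ", paste(edge, collapse = "-"))
  comp <- components_after_deletion(tree, edges_removed = hit)
  lv <- leaves(tree)
  a <- sort(tree$labels[lv[comp[lv] == comp[uv[1L]]]])
  b <- sort(tree$labels[lv[comp[lv] == comp[uv[2L]]]])
  if (paste(b, collapse = "\r") < paste(a, collapse = "\r")) { tmp <- a; a <- b; b <- tmp }
  split_spec(a, b)
}

# component index per vertex after deleting edge rows and/or vertices
components_after_deletion <- function(tree, edges_removed = integer(0),
                                      vertices_removed = integer(0)) {
  keep <- setdiff(seq_len(nrow(tree$edge)), edges_removed)
  e <- tree$edge[keep, , drop = FALSE]
  if (length(vertices_removed))
    e <- e[!(e[, 1L] %in% vertices_removed) & !(e[, 2L] %in% vertices_removed),
           , drop = FALSE]
  comp <- seq_len(tree$nv)        # union-find, path-halving
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (i in seq_len(nrow(e))) {
    a <- find(e[i, 1L]); b <- find(e[i, 2L])
    if (a != b) comp[a] <- b
  }
  out <- vapply(seq_len(tree$nv), find, integer(1))
  out[vertices_removed] <- NA_integer_
  out
}

#' All splits of a tree
#'
#' One `split_spec` per edge, via [induced_split()].
#' @param tree a `phylo_graph`.
#' @return list of `split_spec`.
#' @export
tree_splits <- function(tree) {
  lapply(seq_len(nrow(tree$edge)),
         function(i) induced_split(tree, tree$edge[i, ]))
}

#' Reroot a tree at a given vertex
#'
#' Keeps the undirected edge set and reorients every edge away from the new
#' root.  Model parameters are rerooted separately by [reroot_params()].
#' @param tree a `phylo_graph`.
#' @param new_root vertex id or label.
#' @return a `phylo_graph` rooted at `new_root`.
#' @export
reroot <- function(tree, new_root) {
  v <- resolve_vertices(tree, new_root)
  out <- reorient(tree, v)
  out$rooted <- TRUE
  out
}

#' Suppress degree-2 vertices
#'
#' Repeatedly replaces any unlabeled degree-2 vertex and its two incident
#' edges by a single edge.  SPR/TBR rearrangements create such vertices
#' transiently.
#' @param tree a `phylo_graph`.
#' @param vertices optional restriction: only suppress these vertex ids
#'   (default: every degree-2 vertex).
#' @return a `phylo_graph` without (the selected) degree-2 vertices.
#' @export
suppress_degree2 <- function(tree, vertices = NULL) {
  edge <- tree$edge
  labels <- tree$labels
  allowed_ids <- vertices
  repeat {
    deg <- tabulate(c(edge[, 1L], edge[, 2L]), nbins = length(labels))
    cand <- which(deg == 2L)
    if (!is.null(allowed_ids)) cand <- intersect(cand, allowed_ids)
    if (!length(cand)) break
    v <- cand[1L]
    inc <- which(edge[, 1L] == v | edge[, 2L] == v)
    nb <- setdiff(as.vector(edge[inc, ]), v)
    edge <- edge[-inc, , drop = FALSE]
    edge <- rbind(edge, nb)
    # drop the vertex, compacting ids
    keep <- setdiff(seq_along(labels), v)
    remap <- integer(length(labels)); remap[keep] <- seq_along(keep)
    edge <- matrix(remap[edge], ncol = 2L)
    labels <- labels[keep]
    if (!is.null(allowed_ids)) allowed_ids <- remap[setdiff(allowed_ids, v)]
  }
  deg <- tabulate(c(edge[, 1L], edge[, 2L]), nbins = length(labels))
  phylo_graph(edge, labels, root = which.max(deg), rooted = tree$rooted)
}

#' A split specification
#'
#' Two disjoint, non-empty ordered vertex lists.  The order within each part
#' is meaningful: it fixes the row and column order of a flattening built for
#' the split.
#' @param A,B vectors of vertex ids or labels.
#' @return an object of class `split_spec` with elements `A` and `B`.
#' @export
split_spec <- function(A, B) {
  if (!length(A) || !length(B)) stop("both parts of a split must be non-empty")
  if (length(intersect(as.character(A), as.character(B))))
    stop("split parts must be disjoint")
  structure(list(A = A, B = B), class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(paste(x$A, collapse = ","), "|", paste(x$B, collapse = ","), "\n")
  invisible(x)
}

#' @export
print.phylo_graph <- function(x, ...) {
  deg <- vertex_degrees(x)
  cat("phylo_graph:", x$nv, "vertices,", nrow(x$edge), "edges,",
      sum(deg == 1L), "leaves",
      if (x$rooted) sprintf("(rooted at %d)", x$root) else "(unrooted)", "\n")
  lab <- ifelse(is.na(x$labels), paste0("<", seq_len(x$nv), ">"), x$labels)
  cat("  vertices:", paste(lab, collapse = " "), "\n")
  invisible(x)
}

#' Random binary tree generator
#'
#' Builds an unrooted binary tree by sequential leaf addition: starting from a
#' three-leaf star, each further leaf is attached to a uniformly chosen edge.
#' Deterministic under `seed`.
#' @param n_leaves number of leaves (>= 3).
#' @param seed integer seed.
#' @param labels optional taxon labels (default `t1..tn`).
#' @return a `phylo_graph`.
#' @export
random_binary_tree <- function(n_leaves, seed = NULL, labels = NULL) {
  if (n_leaves < 3L) stop("need at least 3 leaves")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_leaves))
  # vertices: 1..n leaves, then internals as created; center = n+1
  nv <- n_leaves + 1L
  lab <- c(labels, rep(NA_character_, 1L))
  edge <- cbind(rep(n_leaves + 1L, 3L), 1:3)
  for (k in seq(4L, length.out = n_leaves - 3L)) {
    i <- sample.int(nrow(edge), 1L)
    nv <- nv + 1L
    lab <- c(lab, NA_character_)
    u <- edge[i, 1L]; v <- edge[i, 2L]
    edge <- edge[-i, , drop = FALSE]
    edge <- rbind(edge, c(u, nv), c(nv, v), c(nv, k))
  }
  phylo_graph(edge, lab, root = n_leaves + 1L, rooted = FALSE)
}

#' Random (possibly multifurcating) tree generator
#'
#' Draws a random binary tree and contracts each internal edge independently
#' with probability `contract_prob`, yielding multifurcations.
#' @param n_leaves number of leaves (>= 3).
#' @param seed integer seed.
#' @param contract_prob probability of contracting each internal edge.
#' @return a `phylo_graph`.
#' @export
random_tree <- function(n_leaves, seed = NULL, contract_prob = 0.25) {
  tr <- random_binary_tree(n_leaves, seed = seed)
  deg <- vertex_degrees(tr)
  internal_edges <- which(deg[tr$edge[, 1L]] > 1L & deg[tr$edge[, 2L]] > 1L)
  doomed <- internal_edges[stats::runif(length(internal_edges)) < contract_prob]
  if (!length(doomed)) return(tr)
  edge <- tr$edge
  labels <- tr$labels
  comp <- seq_len(tr$nv)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (i in doomed) comp[find(edge[i, 1L])] <- find(edge[i, 2L])
  rep_id <- vapply(seq_len(tr$nv), find, integer(1))
  edge <- edge[-doomed, , drop = FALSE]
  edge <- matrix(rep_id[edge], ncol = 2L)
  keep <- sort(unique(c(rep_id)))
  remap <- integer(tr$nv); remap[keep] <- seq_along(keep)
  phylo_graph(matrix(remap[edge], ncol = 2L), labels[keep],
              root = remap[rep_id[tr$root]], rooted = FALSE)
}

# leaf-set bitmask below each edge's child endpoint (edges are stored
# oriented away from the reference root); masks use one bit per taxon in
# sorted label order, exact in doubles up to 53 taxa
edge_child_masks <- function(tree) {
  labs <- sort(tree$labels[!is.na(tree$labels) &
                             vertex_degrees(tree) == 1L])
  bit <- 2^(seq_along(labs) - 1L)
  names(bit) <- labs
  mask <- numeric(tree$nv)
  lv <- leaves(tree)
  mask[lv] <- bit[tree$labels[lv]]
  parent <- integer(tree$nv)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  for (v in rev(bfs_order(tree, tree$root)))
    if (v != tree$root) mask[parent[v]] <- mask[parent[v]] + mask[v]
  list(child_mask = mask[tree$edge[, 2L]], total = sum(bit), bit = bit)
}

# canonical topology key: sorted set of leaf bipartitions (splits), each
# encoded as the bitmask of the side containing the first taxon
topology_key <- function(tree) {
  em <- edge_child_masks(tree)
  canon <- ifelse(em$child_mask %% 2 == 1, em$child_mask,
                  em$total - em$child_mask)
  paste(sort(unique(canon)), collapse = ",")
}

#' Test whether two trees are isomorphic as leaf-labeled trees
#' @param t1,t2 `phylo_graph` objects.
#' @return logical.
#' @export
same_topology <- function(t1, t2) {
  setequal(leaf_labels(t1), leaf_labels(t2)) &&
    topology_key(t1) == topology_key(t2)
}

#' Test whether a tree contains a given leaf bipartition
#' @param tree a `phylo_graph`.
#' @param split a `split_spec` over taxon labels.
#' @return logical.
#' @export
has_split <- function(tree, split) {
  em <- edge_child_masks(tree)
  a <- as.character(split$A)
  if (!all(a %in% names(em$bit))) return(FALSE)
  target <- sum(em$bit[a])
  any(em$child_mask == target | em$child_mask == em$total - target)
}
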