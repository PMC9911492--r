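# Combinatorial quantities: parsimony length ell_T, minimum vertex cut nu_T,
# and matching disjoint-path systems (Menger certificates).
#
# ell_T(f) is the minimum, over full extensions F of a partial state
# assignment f, of the number of edges whose endpoints disagree; for the
# two-state indicator of A|B it equals the maximum number of edge-disjoint
# A-B paths.  nu_T(A|B) is the minimum number of vertices whose removal
# leaves no component meeting both A and B (the cut may include members of
# A and B themselves) and equals the maximum number of vertex-disjoint A-B
# paths.  On binary trees with A, B leaf subsets the two coincide.

#' A (possibly partial) character on a tree
#'
#' A map from a non-empty vertex subset `dom(f)` to states `0..r-1`.  The
#' domain may include internal vertices.
#' @param tree a `phylo_graph`.
#' @param vertices vertex ids or labels (the domain).
#' @param states integer states in `0..r-1`, one per domain vertex.
#' @param r number of states (>= 2).
#' @return an object of class `character_map` with fields `r`, `dom`
#'   (integer vertex ids) and `states` (0-based).
#' @export
character_map <- function(tree, vertices, states, r = max(states) + 1L) {
  dom <- resolve_vertices(tree, vertices)
  if (!length(dom)) stop("character domain must be non-empty")
  if (anyDuplicated(dom)) stop("duplicate vertex in character domain")
  states <- as.integer(states)
  if (length(states) != length(dom)) stop("one state per domain vertex required")
  if (r < 2L) stop("r must be at least 2")
  if (any(states < 0L | states >= r)) stop("state out of range 0..r-1")
  structure(list(r = as.integer(r), dom = dom, states = states),
            class = "character_map")
}

#' Two-state indicator character of a bipartition A|B
#'
#' State 0 on A, state 1 on B; domain `A` union `B`.
#' @param tree a `phylo_graph`.
#' @param A,B disjoint non-empty vertex sets (ids or labels).
#' @return a `character_map` with `r = 2`.
#' @export
indicator_character <- function(tree, A, B) {
  a <- resolve_vertices(tree, A); b <- resolve_vertices(tree, B)
  if (length(intersect(a, b))) stop("A and B must be disjoint")
  character_map(tree, c(a, b), c(rep(0L, length(a)), rep(1L, length(b))), r = 2L)
}

#' Parsimony length of a character
#'
#' Minimum number of state-changing edges over all full extensions of `f`,
#' by unit-cost Sankoff dynamic programming with the domain vertices clamped.
#' Clamping (rather than Fitch's set rule) is what makes internal-vertex
#' constraints and r > 2 work.
#' @param tree a `phylo_graph`.
#' @param f a `character_map` on `tree`.
#' @return non-negative integer.
#' @export
parsimony_length <- function(tree, f) {
  stopifnot(inherits(f, "character_map"))
  r <- f$r
  nv <- tree$nv
  clamp <- matrix(0, nv, r)
  for (i in seq_along(f$dom))
    clamp[f$dom[i], setdiff(seq_len(r), f$states[i] + 1L)] <- Inf
  ord <- bfs_order(tree, tree$root)
  parent <- integer(nv)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  cost <- clamp
  for (v in rev(ord)) {
    if (v == tree$root) next
    p <- parent[v]
    # min over child state t of cost[v,t] + [t != s]
    m <- min(cost[v, ])
    contrib <- pmin(cost[v, ], m + 1)
    cost[p, ] <- cost[p, ] + contrib
  }
  as.integer(min(cost[tree$root, ]))
}

#' Exhaustive-enumeration parsimony length (test oracle)
#'
#' Minimizes the number of discordant edges over all `r^|V \ dom(f)|` full
#' extensions explicitly.  Guarded to small instances.
#' @param tree a `phylo_graph`.
#' @param f a `character_map`.
#' @return non-negative integer.
#' @export
brute_force_ell <- function(tree, f) {
  r <- f$r
  free <- setdiff(seq_len(tree$nv), f$dom)
  if (length(free) > 15L) stop("too many free vertices for brute force")
  n_ext <- r^length(free)
  if (n_ext > 2^20) stop("too many extensions for brute force")
  Fv <- integer(tree$nv)
  Fv[f$dom] <- f$states
  u <- tree$edge[, 1L]; v <- tree$edge[, 2L]
  best <- Inf
  for (i in seq_len(n_ext) - 1L) {
    x <- i
    for (j in seq_along(free)) { Fv[free[j]] <- x %% r; x <- x %/% r }
    best <- min(best, sum(Fv[u] != Fv[v]))
  }
  as.integer(best)
}

# --- max-flow machinery -------------------------------------------------

# decompose an integral directed flow into `value` unit paths from s to t
decompose_flow <- function(ends, flow, s, t, value) {
  flow <- round(flow)
  paths <- vector("list", value)
  for (k in seq_len(value)) {
    path <- s
    v <- s
    while (v != t) {
      i <- which(ends[, 1L] == v & flow > 0)[1L]
      if (is.na(i)) stop("flow decomposition failed (no outgoing flow)")
      flow[i] <- flow[i] - 1L
      v <- ends[i, 2L]
      path <- c(path, v)
    }
    paths[[k]] <- path
  }
  paths
}

#' Edge cut size ell_T(A|B) with Menger certificates
#'
#' Computes the maximum number of edge-disjoint A-B paths (equivalently the
#' minimum separating edge cut, equivalently the parsimony length of the
#' indicator character of A|B) by unit-edge-capacity max-flow, and returns
#' both certificates.
#' @param tree a `phylo_graph`.
#' @param A,B disjoint non-empty vertex sets (ids or labels).
#' @return an object of class `cut_result`: `size`, `witness_cut` (two-column
#'   matrix of cut edges), `witness_paths` (list of vertex-id sequences).
#' @export
ell <- function(tree, A, B) {
  a <- resolve_vertices(tree, A); b <- resolve_vertices(tree, B)
  if (!length(a) || !length(b)) stop("A and B must be non-empty")
  if (length(intersect(a, b))) stop("A and B must be disjoint")
  nv <- tree$nv
  big <- nv + 1
  s <- nv + 1L; t <- nv + 2L
  # antiparallel arcs per tree edge; on a tree no augmenting path ever uses
  # both directions of one edge, so arc flows are directly edge-disjoint paths
  ends <- rbind(tree$edge,
                tree$edge[, 2:1, drop = FALSE],
                cbind(s, a), cbind(b, t))
  caps <- c(rep(1, 2L * nrow(tree$edge)), rep(big, length(a) + length(b)))
  g <- igraph::graph_from_edgelist(ends, directed = TRUE)
  mf <- igraph::max_flow(g, source = s, target = t, capacity = caps)
  size <- as.integer(round(mf$value))
  fl <- round(mf$flow)
  ne <- nrow(tree$edge)
  # cancel antiparallel flow (defensive; see note above)
  fwd <- fl[seq_len(ne)]; bwd <- fl[ne + seq_len(ne)]
  canc <- pmin(pmax(fwd, 0), pmax(bwd, 0))
  fl[seq_len(ne)] <- fwd - canc; fl[ne + seq_len(ne)] <- bwd - canc
  paths <- decompose_flow(ends, fl, s, t, size)
  paths <- lapply(paths, function(p) p[p != s & p != t])
  cut_edges <- min_edge_cut_from_flow(tree, a, b, fl[seq_len(ne)], fl[ne + seq_len(ne)])
  structure(list(size = size, witness_cut = cut_edges,
                 witness_paths = paths, kind = "edge"),
            class = "cut_result")
}

# minimum edge cut from a max flow: edges saturated from the source side of
# the residual graph
min_edge_cut_from_flow <- function(tree, a, b, fwd, bwd) {
  nv <- tree$nv
  used <- fwd + bwd                      # 0/1 usage per undirected tree edge
  # residual reachability from A: an edge can be traversed u->v unless its
  # unit capacity is already used in that direction
  reach <- logical(nv); reach[a] <- TRUE
  repeat {
    grew <- FALSE
    for (i in seq_len(nrow(tree$edge))) {
      u <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
      if (reach[u] && !reach[v] && fwd[i] < 1) { reach[v] <- TRUE; grew <- TRUE }
      if (reach[v] && !reach[u] && bwd[i] < 1) { reach[u] <- TRUE; grew <- TRUE }
    }
    if (!grew) break
  }
  sel <- which(reach[tree$edge[, 1L]] != reach[tree$edge[, 2L]])
  tree$edge[sel, , drop = FALSE]
}

#' Vertex cut size nu_T(A|B) with Menger certificates
#'
#' Minimum number of vertices whose removal leaves no component meeting both
#' A and B, via the vertex-splitting max-flow reduction.  The terminals' own
#' split arcs have capacity 1, so the cut is allowed to contain members of
#' A and B (as the theory requires).
#' @param tree a `phylo_graph`.
#' @param A,B disjoint non-empty vertex sets (ids or labels).
#' @return a `cut_result`: `size`, `witness_cut` (integer vertex ids),
#'   `witness_paths` (list of vertex-disjoint A-B paths).
#' @export
nu <- function(tree, A, B) {
  a <- resolve_vertices(tree, A); b <- resolve_vertices(tree, B)
  if (!length(a) || !length(b)) stop("A and B must be non-empty")
  if (length(intersect(a, b))) stop("A and B must be disjoint")
  nv <- tree$nv
  big <- nv + 1
  inn <- function(v) v; out <- function(v) nv + v
  s <- 2L * nv + 1L; t <- 2L * nv + 2L
  ends <- rbind(cbind(inn(seq_len(nv)), out(seq_len(nv))),
                cbind(out(tree$edge[, 1L]), inn(tree$edge[, 2L])),
                cbind(out(tree$edge[, 2L]), inn(tree$edge[, 1L])),
                cbind(s, inn(a)), cbind(out(b), t))
  caps <- c(rep(1, nv), rep(big, 2L * nrow(tree$edge) + length(a) + length(b)))
  g <- igraph::graph_from_edgelist(ends, directed = TRUE)
  mf <- igraph::max_flow(g, source = s, target = t, capacity = caps)
  size <- as.integer(round(mf$value))
  cut_arcs <- as.integer(mf$cut)
  cut_vertices <- sort(cut_arcs[cut_arcs <= nv])   # split arcs are the first nv
  fl <- round(mf$flow)
  paths <- decompose_flow(ends, fl, s, t, size)
  paths <- lapply(paths, function(p) {
    p <- p[p != s & p != t]
    unique(ifelse(p > nv, p - nv, p))    # collapse in/out copies
  })
  structure(list(size = size, witness_cut = cut_vertices,
                 witness_paths = paths, kind = "vertex"),
            class = "cut_result")
}

#' @export
print.cut_result <- function(x, ...) {
  cat(sprintf("%s cut of size %d; %d disjoint witness paths\n",
              x$kind, x$size, length(x$witness_paths)))
  invisible(x)
}

#' Exhaustive minimum vertex cut (test oracle)
#'
#' Tries all vertex subsets in increasing size order and returns the size of
#' the first one whose removal leaves no component meeting both A and B.
#' @param tree a `phylo_graph`.
#' @param A,B disjoint non-empty vertex sets.
#' @return non-negative integer.
#' @export
brute_force_nu <- function(tree, A, B) {
  a <- resolve_vertices(tree, A); b <- resolve_vertices(tree, B)
  if (tree$nv > 18L) stop("tree too large for brute force")
  separated <- function(rm) {
    comp <- components_after_deletion(tree, vertices_removed = rm)
    ca <- unique(comp[setdiff(a, rm)]); cb <- unique(comp[setdiff(b, rm)])
    !length(intersect(ca, cb))
  }
  for (k in 0:tree$nv) {
    if (k == 0L) { if (separated(integer(0))) return(0L); next }
    subsets <- utils::combn(tree$nv, k)
    for (j in seq_len(ncol(subsets)))
      if (separated(subsets[, j])) return(k)
  }
  stop("unreachable")
}

#' Validate a cut_result certificate
#'
#' Re-checks, independently of the flow computation, that the witness paths
#' are pairwise disjoint A-B paths and that removing the witness cut actually
#' separates A from B.  Used by the test suite.
#' @param tree a `phylo_graph`.
#' @param A,B the vertex sets the certificate is for.
#' @param res a `cut_result`.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
validate_cut_result <- function(tree, A, B, res) {
  a <- resolve_vertices(tree, A); b <- resolve_vertices(tree, B)
  if (length(res$witness_paths) != res$size)
    stop("path count does not match cut size")
  for (p in res$witness_paths) {
    if (!(p[1L] %in% a) || !(p[length(p)] %in% b))
      stop("witness path does not join A to B")
    for (i in seq_len(length(p) - 1L)) {
      hit <- any((tree$edge[, 1L] == p[i] & tree$edge[, 2L] == p[i + 1L]) |
                 (tree$edge[, 2L] == p[i] & tree$edge[, 1L] == p[i + 1L]))
      if (!hit) stop("witness path uses a non-edge")
    }
  }
  if (res$kind == "vertex") {
    verts <- unlist(res$witness_paths)
    if (anyDuplicated(verts)) stop("witness paths are not vertex-disjoint")
    if (length(res$witness_cut) != res$size) stop("cut size mismatch")
    comp <- components_after_deletion(tree, vertices_removed = res$witness_cut)
    ca <- unique(comp[setdiff(a, res$witness_cut)])
    cb <- unique(comp[setdiff(b, res$witness_cut)])
    if (length(intersect(ca, cb))) stop("witness vertex cut does not separate")
  } else {
    ekey <- function(u, v) paste(pmin(u, v), pmax(u, v))
    used <- unlist(lapply(res$witness_paths, function(p)
      ekey(p[-length(p)], p[-1L])))
    if (anyDuplicated(used)) stop("witness paths are not edge-disjoint")
    if (nrow(res$witness_cut) != res$size) stop("cut size mismatch")
    rows <- vapply(seq_len(nrow(res$witness_cut)), function(i) {
      which((tree$edge[, 1L] == res$witness_cut[i, 1L] &
             tree$edge[, 2L] == res$witness_cut[i, 2L]) |
            (tree$edge[, 1L] == res$witness_cut[i, 2L] &
             tree$edge[, 2L] == res$witness_cut[i, 1L]))[1L]
    }, integer(1))
    comp <- components_after_deletion(tree, edges_removed = rows)
    if (length(intersect(unique(comp[a]), unique(comp[b]))))
      stop("witness edge cut does not separate")
  }
  invisible(TRUE)
}
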