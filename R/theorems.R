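# Harness operations tying the algebra to the combinatorics:
#  - rank(flat_{A|B}) = r^nu_T(A|B) (and = r^ell on binary trees with leaf
#    subsets);
#  - the distance from a binary tree to the nearest tree containing a split
#    A|B equals nu_T(A|B) - 1, under both SPR and TBR rearrangements;
#  - each of (C1)-(C3) is necessary: zeroing a root entry or an
#    internal-edge entry drops the non-split quartet rank below r^2.

#' Verify the rank formula on one instance
#'
#' Computes the minimum vertex cut nu (and the parsimony length ell when A
#' and B are leaf subsets), builds the flattening, ranks it numerically and
#' — when the parameters carry a rational representation — exactly over two
#' prime fields, and compares against `r^nu`.
#'
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params` passing [check_conditions()].
#' @param A,B disjoint non-empty vertex sets (ids or labels).
#' @param exact use the prime-field certification (requires rational params).
#' @return an object of class `verification_report`.
#' @export
verify_rank_theorem <- function(tree, params, A, B,
                                exact = !is.null(params$rational)) {
  cond <- check_conditions(tree, params)
  if (!cond$all_pass)
    stop("parameters violate (C1)-(C3) (",
         paste(Filter(Negate(is.null),
                      lapply(cond[c("C1", "C2", "C3")], `[[`, "witness")),
               collapse = "; "),
         "); rank degeneration under such parameters is explored by degeneracy_demo()")
  a <- resolve_vertices(tree, A); b <- resolve_vertices(tree, B)
  r <- params$r
  nu_res <- nu(tree, a, b)
  predicted <- r^nu_res$size
  lv <- leaves(tree)
  ell_size <- if (all(c(a, b) %in% lv)) ell(tree, a, b)$size else NA_integer_
  flat <- build_flattening(tree, params, a, b)
  rr <- flattening_rank(flat, predicted_rank = predicted)
  er <- if (exact) exact_flattening_rank(tree, params, a, b) else NULL
  effective <- if (!is.null(er)) er$rank else rr$numerical_rank
  structure(list(
    r = r, A = a, B = b,
    nu = nu_res$size, ell = ell_size,
    predicted_rank = predicted,
    numerical_rank = rr$numerical_rank,
    exact_rank = if (!is.null(er)) er$rank else NULL,
    exact_primes_agree = if (!is.null(er)) er$agree else NA,
    spectrum = rr$singular_values,
    agree = effective == predicted,
    binary_leaf_case = is_binary_tree(tree) && all(c(a, b) %in% lv),
    ell_equals_nu = if (!is.na(ell_size)) ell_size == nu_res$size else NA),
    class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("nu = %d, predicted rank %d^%d = %d; rank = %s; %s\n",
              x$nu, x$r, x$nu, x$predicted_rank,
              if (!is.null(x$exact_rank))
                sprintf("%d (exact)", x$exact_rank)
              else sprintf("%d (numerical)", x$numerical_rank),
              if (x$agree) "AGREE" else "DISAGREE"))
  invisible(x)
}

# --- SPR / TBR neighbourhoods -------------------------------------------

# replace edge row j by its subdivision through a fresh vertex; returns the
# updated structures and the new vertex id
subdivide_row <- function(edge, labels, a, b) {
  row <- which((edge[, 1L] == a & edge[, 2L] == b) |
               (edge[, 1L] == b & edge[, 2L] == a))[1L]
  x <- length(labels) + 1L
  list(edge = rbind(edge[-row, , drop = FALSE], c(a, x), c(x, b)),
       labels = c(labels, NA_character_), point = x)
}

finalize_topology <- function(edge, labels) {
  deg <- tabulate(c(edge[, 1L], edge[, 2L]), nbins = length(labels))
  suppress_degree2(phylo_graph(edge, labels, root = which.max(deg)))
}

#' SPR neighbourhood of a binary tree
#'
#' All distinct topologies obtained by removing an edge and reconnecting one
#' of its endpoints to a point on an edge of the opposite component, with
#' degree-2 vertices suppressed.  The original topology is excluded.
#' @param tree an unrooted binary `phylo_graph` with at least 4 leaves.
#' @return list of `phylo_graph` trees.
#' @export
spr_neighbors <- function(tree) {
  if (length(leaves(tree)) < 4L) stop("need at least 4 leaves")
  if (!is_binary_tree(tree)) stop("rearrangements are defined on binary trees")
  orig <- topology_key(tree)
  found <- new.env(parent = emptyenv())
  out <- list()
  edge <- tree$edge
  for (i in seq_len(nrow(edge))) {
    comp <- components_after_deletion(tree, edges_removed = i)
    for (flip in c(FALSE, TRUE)) {
      u <- if (flip) edge[i, 2L] else edge[i, 1L]   # endpoint being regrafted
      v <- if (flip) edge[i, 1L] else edge[i, 2L]
      vs <- which(comp == comp[v])
      cand <- setdiff(which(edge[, 1L] %in% vs & edge[, 2L] %in% vs), i)
      for (j in cand) {
        sd <- subdivide_row(edge[-i, , drop = FALSE], tree$labels,
                            edge[j, 1L], edge[j, 2L])
        e2 <- rbind(sd$edge, c(sd$point, u))
        tr2 <- finalize_topology(e2, sd$labels)
        key <- topology_key(tr2)
        if (key != orig && is.null(found[[key]])) {
          found[[key]] <- TRUE
          out[[length(out) + 1L]] <- tr2
        }
      }
    }
  }
  out
}

#' TBR neighbourhood of a binary tree
#'
#' All distinct topologies obtained by removing an edge and inserting a new
#' edge between arbitrary points of the two components (SPR moves are the
#' special case where one attachment point is an endpoint of the removed
#' edge, so the SPR neighbourhood is contained in this one).
#' @param tree an unrooted binary `phylo_graph` with at least 4 leaves.
#' @return list of `phylo_graph` trees.
#' @export
tbr_neighbors <- function(tree) {
  if (length(leaves(tree)) < 4L) stop("need at least 4 leaves")
  if (!is_binary_tree(tree)) stop("rearrangements are defined on binary trees")
  orig <- topology_key(tree)
  found <- new.env(parent = emptyenv())
  out <- list()
  edge <- tree$edge
  for (i in seq_len(nrow(edge))) {
    comp <- components_after_deletion(tree, edges_removed = i)
    side <- function(w) {
      vs <- which(comp == comp[w])
      js <- setdiff(which(edge[, 1L] %in% vs & edge[, 2L] %in% vs), i)
      if (length(js)) lapply(js, function(j) list(a = edge[j, 1L], b = edge[j, 2L]))
      else list(list(vertex = w))
    }
    for (pu in side(edge[i, 1L])) for (pv in side(edge[i, 2L])) {
      e2 <- edge[-i, , drop = FALSE]
      lab2 <- tree$labels
      pick <- function(pt) {
        if (!is.null(pt$vertex)) return(pt$vertex)
        sd <- subdivide_row(e2, lab2, pt$a, pt$b)
        e2 <<- sd$edge; lab2 <<- sd$labels
        sd$point
      }
      p1 <- pick(pu); p2 <- pick(pv)
      tr2 <- finalize_topology(rbind(e2, c(p1, p2)), lab2)
      key <- topology_key(tr2)
      if (key != orig && is.null(found[[key]])) {
        found[[key]] <- TRUE
        out[[length(out) + 1L]] <- tr2
      }
    }
  }
  out
}

# BFS layers of the rearrangement graph around `tree`: layers[[d+1]] holds
# the topologies at distance exactly d, up to max_depth
bfs_layers <- function(tree, move, max_depth, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  get_nb <- function(tr) {
    k <- paste0(move, "|", topology_key(tr))
    nb <- cache[[k]]
    if (is.null(nb)) {
      nb <- if (move == "spr") spr_neighbors(tr) else tbr_neighbors(tr)
      cache[[k]] <- nb
    }
    nb
  }
  seen <- new.env(parent = emptyenv())
  seen[[topology_key(tree)]] <- TRUE
  layers <- list(list(tree))
  for (d in seq_len(max_depth)) {
    nxt <- list()
    for (tr in layers[[d]]) for (nb in get_nb(tr)) {
      k <- topology_key(nb)
      if (is.null(seen[[k]])) { seen[[k]] <- TRUE; nxt[[length(nxt) + 1L]] <- nb }
    }
    if (!length(nxt)) break
    layers[[d + 1L]] <- nxt
  }
  layers
}

#' Breadth-first distance to the nearest tree containing a split
#'
#' Explores the SPR or TBR rearrangement graph outward from `tree`,
#' identifying topologies by their canonical split sets, until a tree
#' containing the split is found.
#' @param tree an unrooted binary `phylo_graph`.
#' @param split a `split_spec` over taxon labels.
#' @param move `"spr"` or `"tbr"`.
#' @param max_depth search radius guard.
#' @param cache optional environment memoising neighbourhoods across calls.
#' @return list: `distance` (integer, `NA` if not found within radius) and
#'   `witness` (a tree containing the split, or `NULL`).
#' @export
bfs_split_distance <- function(tree, split, move = c("spr", "tbr"),
                               max_depth = 5L, cache = NULL) {
  move <- match.arg(move)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  get_nb <- function(tr) {
    k <- paste0(move, "|", topology_key(tr))
    nb <- cache[[k]]
    if (is.null(nb)) {
      nb <- if (move == "spr") spr_neighbors(tr) else tbr_neighbors(tr)
      cache[[k]] <- nb
    }
    nb
  }
  seen <- new.env(parent = emptyenv())
  frontier <- list(tree)
  seen[[topology_key(tree)]] <- TRUE
  for (d in 0:max_depth) {
    for (tr in frontier) if (has_split(tr, split))
      return(list(distance = d, witness = tr))
    nxt <- list()
    for (tr in frontier) for (nb in get_nb(tr)) {
      k <- topology_key(nb)
      if (is.null(seen[[k]])) { seen[[k]] <- TRUE; nxt[[length(nxt) + 1L]] <- nb }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  list(distance = NA_integer_, witness = NULL)
}

#' Distance from a tree to the nearest tree containing a split
#'
#' Reports `nu_T(A|B) - 1` as both the SPR and the TBR distance from `tree`
#' to the closest binary tree containing the leaf bipartition `A|B`;
#' optionally certifies the value by exhaustive breadth-first search (small
#' trees only).
#' @param tree an unrooted binary `phylo_graph`.
#' @param A,B a bipartition of the taxon labels.
#' @param certify run the BFS certification (refused above
#'   `max_leaves_certify` leaves, falling back to the formula).
#' @param max_leaves_certify BFS guard.
#' @param cache optional neighbourhood memoisation environment.
#' @return an object of class `distance_report`.
#' @export
split_distance <- function(tree, A, B, certify = FALSE,
                           max_leaves_certify = 7L, cache = NULL) {
  if (!is_binary_tree(tree)) stop("split distances are defined on binary trees")
  A <- as.character(A); B <- as.character(B)
  labs <- leaf_labels(tree)
  if (!setequal(c(A, B), labs) || length(intersect(A, B)))
    stop("A|B must bipartition the taxon set")
  nu_size <- nu(tree, A, B)$size
  claimed <- nu_size - 1L
  bfs_spr <- bfs_tbr <- NA_integer_
  witness <- NULL
  if (certify) {
    if (length(labs) > max_leaves_certify) {
      warning("tree too large for exhaustive certification; reporting nu - 1")
    } else {
      sp <- split_spec(A, B)
      rs <- bfs_split_distance(tree, sp, "spr", cache = cache)
      rt <- bfs_split_distance(tree, sp, "tbr", cache = cache)
      bfs_spr <- rs$distance; bfs_tbr <- rt$distance
      witness <- rs$witness
    }
  }
  structure(list(A = A, B = B, nu = nu_size,
                 spr_distance = claimed, tbr_distance = claimed,
                 bfs_spr_distance = bfs_spr, bfs_tbr_distance = bfs_tbr,
                 witness = witness),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("split %s | %s: nu = %d, SPR/TBR distance = %d",
              paste(x$A, collapse = ","), paste(x$B, collapse = ","),
              x$nu, x$spr_distance))
  if (!is.na(x$bfs_spr_distance))
    cat(sprintf(" (BFS: spr %d, tbr %d)", x$bfs_spr_distance, x$bfs_tbr_distance))
  cat("\n")
  invisible(x)
}

# --- degeneracy of the parameter conditions ------------------------------

# zero one parameter entry and renormalize the affected row so the object
# stays a probability distribution while acquiring the structural zero
zero_param_entry <- function(params, zero) {
  r <- params$r
  rat <- params$rational
  if (zero$kind == "root") {
    i <- zero$i + 1L
    old <- params$root_dist[i]
    if (old >= 1) stop("cannot renormalize: entry carries all the mass")
    params$root_dist[i] <- 0
    params$root_dist <- params$root_dist / sum(params$root_dist)
    if (!is.null(rat)) {
      rat$root_den <- rat$root_den - rat$root_num[i]
      rat$root_num[i] <- 0
    }
  } else if (zero$kind == "edge") {
    key <- ekey(zero$u, zero$v)
    if (is.null(params$mats[[key]])) key <- ekey(zero$v, zero$u)
    if (is.null(params$mats[[key]])) stop("unknown edge ", zero$u, "-", zero$v)
    i <- zero$i + 1L; j <- zero$j + 1L
    M <- params$mats[[key]]
    if (M[i, j] >= 1) stop("cannot renormalize: entry carries all the mass")
    M[i, j] <- 0
    M[i, ] <- M[i, ] / sum(M[i, ])
    params$mats[[key]] <- M
    if (!is.null(rat)) {
      rat$mats[[key]]$den[i] <- rat$mats[[key]]$den[i] - rat$mats[[key]]$num[i, j]
      rat$mats[[key]]$num[i, j] <- 0
    }
  } else stop("zero$kind must be 'root' or 'edge'")
  params$rational <- rat
  params
}

internal_edges <- function(tree) {
  deg <- vertex_degrees(tree)
  sel <- deg[tree$edge[, 1L]] > 1L & deg[tree$edge[, 2L]] > 1L
  tree$edge[sel, , drop = FALSE]
}

#' Demonstrate rank degeneration when (C2) or (C3) fails
#'
#' Zeroes one root-distribution entry or one internal-edge matrix entry
#' (renormalizing the affected row), builds the flattening of a non-split
#' bipartition, and reports its rank.  On a quartet rooted on the internal
#' edge (u,v), gathering terms shows flat_{13|24} = U D V with D diagonal,
#' `D_{ij,ij} = pi_rho(i) P_uv(i,j)` and U, V nonsingular under (C1), so the
#' rank equals the number of nonzero entries of D: zeroing a root entry
#' removes r diagonal entries, zeroing an internal-edge entry removes one,
#' and generic parameters keep the full rank r^2.
#'
#' @param tree a `phylo_graph` (a quartet for the diagonal prediction).
#' @param params a `gmm_params` (rational representation enables exact rank).
#' @param zero `NULL` (control case), `list(kind = "root", i = state)`, or
#'   `list(kind = "edge", u =, v =, i =, j =)` with 0-based states.
#' @param A,B the non-split bipartition to flatten; defaults to the
#'   interleaved leaf pairing `{1,3}|{2,4}` on a quartet.
#' @return list: `rank`, `numerical_rank`, `full_rank`, `dropped`,
#'   `predicted_rank` (quartet diagonal count, when applicable), `zero`.
#' @export
degeneracy_demo <- function(tree, params, zero = NULL, A = NULL, B = NULL) {
  r <- params$r
  lv <- leaves(tree)
  if (is.null(A) || is.null(B)) {
    if (length(lv) != 4L)
      stop("default non-split bipartition requires a quartet; supply A and B")
    A <- lv[c(1L, 3L)]; B <- lv[c(2L, 4L)]
  }
  if (!is.null(zero)) {
    if (zero$kind == "edge") {
      zero$u <- resolve_vertices(tree, zero$u)
      zero$v <- resolve_vertices(tree, zero$v)
    }
    params <- zero_param_entry(params, zero)
  }
  er <- if (!is.null(params$rational))
    exact_flattening_rank(tree, params, A, B)$rank else NULL
  nr <- flattening_rank(build_flattening(tree, params, A, B))$numerical_rank
  # diagonal prediction: valid when the root sits on the internal edge of a
  # quartet and the zeroed entry (if any) is the root or that edge
  predicted <- NA_integer_
  ie <- internal_edges(tree)
  if (length(lv) == 4L && nrow(ie) == 1L && params$root %in% ie[1L, ]) {
    other <- setdiff(ie[1L, ], params$root)
    Puv <- params$mats[[ekey(params$root, other)]]
    predicted <- sum(outer(params$root_dist, rep(1, r)) * Puv > 0)
  }
  rank <- if (!is.null(er)) er else nr
  list(rank = rank, numerical_rank = nr, exact_rank = er,
       full_rank = r^2L, dropped = rank < r^2L,
       predicted_rank = predicted, zero = zero)
}

# --- factorization witnesses --------------------------------------------

# joint probability matrix over two ordered vertex lists that may overlap:
# entries are zero unless the two assignments agree on shared vertices
general_flat_matrix <- function(tree, params, rows, cols) {
  r <- params$r
  U <- unique(c(rows, cols))
  tens <- joint_tensor(tree, params, U)
  ra <- state_assignments(length(rows), r)
  ca <- state_assignments(length(cols), r)
  posr <- match(rows, U); posc <- match(cols, U)
  wgt <- r^(rev(seq_along(U)) - 1L)
  M <- matrix(0, nrow(ra), nrow(ca))
  for (i in seq_len(nrow(ra))) {
    full0 <- rep(NA_integer_, length(U))
    full0[posr] <- ra[i, ]
    for (j in seq_len(nrow(ca))) {
      full <- full0
      ok <- TRUE
      for (k in seq_along(posc)) {
        if (!is.na(full[posc[k]]) && full[posc[k]] != ca[j, k]) { ok <- FALSE; break }
        full[posc[k]] <- ca[j, k]
      }
      if (ok) M[i, j] <- tens[sum(full * wgt) + 1L]
    }
  }
  M
}

#' Conditional-independence factorization across a minimum vertex cut
#'
#' For a minimum vertex cut C separating A from B, the flattening factors
#' as `flat_{A|B} = R S` with `R(f_A, f_C) = pi(X_A = f_A | X_C = f_C)` and
#' `S(f_C, f_B) = pi(X_C = f_C, X_B = f_B)` — the upper-bound half of the
#' rank formula, returned here as a checkable witness.  The cut may
#' intersect A or B; inconsistent assignments contribute zero entries.
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params`.
#' @param A,B disjoint vertex sets.
#' @return list: `C` (the cut), `R`, `S`, `product` (`R %*% S`), `flat`
#'   (the directly computed flattening matrix).
#' @export
cut_factorization <- function(tree, params, A, B) {
  a <- resolve_vertices(tree, A); b <- resolve_vertices(tree, B)
  C <- nu(tree, a, b)$witness_cut
  margC <- as.numeric(joint_tensor(tree, params, C))
  AC <- general_flat_matrix(tree, params, a, C)
  R <- sweep(AC, 2L, margC, "/")
  S <- general_flat_matrix(tree, params, C, b)
  flat <- build_flattening(tree, params, a, b)$matrix
  list(C = C, R = R, S = S, product = R %*% S, flat = flat)
}
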