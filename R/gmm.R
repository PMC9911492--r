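# The general Markov model on a tree: a root distribution pi_rho and one
# row-stochastic r x r transition matrix per edge directed away from the
# root.  Joint pattern probabilities factor as
#   pi(X_V = F) = pi_rho(F(rho)) * prod_{(u,v)} P_uv(F(u), F(v)),
# and marginals over any vertex subset are obtained by summing out the rest
# (message passing / variable elimination on the tree).
#
# Three parameter conditions drive the rank results:
#   (C1) every P_uv is nonsingular;
#   (C2) pi_rho(i) > 0 for every state i;
#   (C3) P_uv(i,j) > 0 for every INTERNAL edge (u,v) and all i, j.
# check_conditions() reports violations; nothing is silently repaired.

ekey <- function(u, v) paste0(u, ">", v)

#' General Markov model parameters
#'
#' @param tree a `phylo_graph`.
#' @param root root vertex (id or label).
#' @param root_dist numeric probability vector of length `r`.
#' @param mats named list of r x r row-stochastic matrices, one per edge
#'   directed away from `root`, with names `"u>v"` in integer-id form.
#' @param rational optional exact representation: `list(root_num, root_den,
#'   mats = list("u>v" = list(num, den)))` with `num` integer matrices and
#'   `den` per-row denominators, such that `num/den` reproduces the numeric
#'   matrices.  Enables certified rank computations over prime fields.
#' @return an object of class `gmm_params`.
#' @export
gmm_params <- function(tree, root, root_dist, mats, rational = NULL) {
  root <- resolve_vertices(tree, root)
  r <- length(root_dist)
  if (r < 2L) stop("need at least two states")
  if (abs(sum(root_dist) - 1) > 1e-12 || any(root_dist < 0))
    stop("root distribution must be a probability vector")
  oriented <- reorient(tree, root)$edge
  want <- ekey(oriented[, 1L], oriented[, 2L])
  if (!setequal(names(mats), want))
    stop("edge matrices must cover exactly the edges directed away from the root")
  for (k in want) {
    M <- mats[[k]]
    if (!is.matrix(M) || any(dim(M) != r)) stop("matrix ", k, " is not r x r")
    if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-12))
      stop("matrix ", k, " is not row-stochastic")
  }
  structure(list(r = as.integer(r), root = root,
                 root_dist = as.numeric(root_dist),
                 mats = mats[want], rational = rational),
            class = "gmm_params")
}

#' @export
print.gmm_params <- function(x, ...) {
  cat(sprintf("gmm_params: r = %d, root = %d, %d edge matrices%s\n",
              x$r, x$root, length(x$mats),
              if (!is.null(x$rational)) " (rational)" else ""))
  invisible(x)
}

# orientation bookkeeping shared by the evaluators: BFS order, parent map,
# and the transition matrix feeding each non-root vertex
model_wiring <- function(tree, params, p = NULL) {
  ot <- reorient(tree, params$root)
  ord <- bfs_order(ot, params$root)
  parent <- integer(tree$nv)
  parent[ot$edge[, 2L]] <- ot$edge[, 1L]
  mats <- vector("list", tree$nv)
  if (is.null(p)) {
    for (i in seq_len(nrow(ot$edge)))
      mats[[ot$edge[i, 2L]]] <- params$mats[[ekey(ot$edge[i, 1L], ot$edge[i, 2L])]]
    root_dist <- params$root_dist
  } else {
    rat <- params$rational
    if (is.null(rat)) stop("modular evaluation requires rational parameters")
    for (i in seq_len(nrow(ot$edge))) {
      k <- ekey(ot$edge[i, 1L], ot$edge[i, 2L])
      num <- rat$mats[[k]]$num; den <- rat$mats[[k]]$den
      M <- num %% p
      for (s in seq_len(params$r)) M[s, ] <- mod_rat(num[s, ], den[s], p)
      mats[[ot$edge[i, 2L]]] <- M
    }
    root_dist <- mod_rat(rat$root_num, rat$root_den, p)
  }
  list(ord = ord, parent = parent, mats = mats, root_dist = root_dist,
       root = params$root)
}

#' Joint probability of a full state assignment
#'
#' `pi_rho(F(rho)) * prod P_uv(F(u), F(v))` over all edges directed away
#' from the root.
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params`.
#' @param F integer vector of length `nv` with states `0..r-1` for every
#'   vertex (index = vertex id).
#' @return a probability.
#' @export
joint_probability <- function(tree, params, F) {
  if (length(F) != tree$nv) stop("F must assign a state to every vertex")
  F <- as.integer(F)
  if (any(F < 0L | F >= params$r)) stop("state out of range")
  w <- model_wiring(tree, params)
  prob <- w$root_dist[F[w$root] + 1L]
  for (v in w$ord[-1L])
    prob <- prob * w$mats[[v]][F[w$parent[v]] + 1L, F[v] + 1L]
  prob
}

#' Marginal probability of a partial character
#'
#' Clamps the domain vertices of `f` to their states and sums out all other
#' vertices by one post-order message-passing sweep.
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params`.
#' @param f a `character_map` (domain may include internal vertices).
#' @return a probability.
#' @export
marginal_prob <- function(tree, params, f) {
  stopifnot(inherits(f, "character_map"))
  if (f$r != params$r) stop("state count mismatch between character and model")
  r <- params$r
  w <- model_wiring(tree, params)
  L <- matrix(1, tree$nv, r)
  for (i in seq_along(f$dom)) {
    row <- numeric(r); row[f$states[i] + 1L] <- 1
    L[f$dom[i], ] <- row
  }
  for (v in rev(w$ord)) {
    if (v == w$root) next
    msg <- as.vector(w$mats[[v]] %*% L[v, ])
    L[w$parent[v], ] <- L[w$parent[v], ] * msg
  }
  sum(w$root_dist * L[w$root, ])
}

#' Joint distribution tensor over an ordered vertex subset
#'
#' Eliminates all vertices outside `vertices` in one tree sweep and returns
#' the joint distribution of the listed vertices as a vector of length
#' `r^m`.  Index convention: with states `s_1..s_m` for the listed vertices
#' in order, the (1-based) position is `1 + sum_k s_k * r^(m-k)` — the last
#' listed vertex varies fastest.
#'
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params`.
#' @param vertices ordered vertex ids or labels.
#' @param p optional prime: evaluate in GF(p) from the rational parameter
#'   representation (exact mode) instead of floating point.
#' @return numeric vector of length `r^m` with attributes `vars` and `r`.
#' @export
joint_tensor <- function(tree, params, vertices, p = NULL) {
  S <- resolve_vertices(tree, vertices)
  if (anyDuplicated(S)) stop("duplicate vertex in tensor query")
  r <- params$r
  m <- length(S)
  w <- model_wiring(tree, params, p = p)
  inS <- logical(tree$nv); inS[S] <- TRUE
  red <- if (is.null(p)) identity else function(x) x %% p
  Lmat <- vector("list", tree$nv)
  Lvars <- vector("list", tree$nv)
  for (v in seq_len(tree$nv)) { Lmat[[v]] <- matrix(1, r, 1L); Lvars[[v]] <- integer(0) }
  for (v in rev(w$ord)) {
    if (v == w$root) next
    P <- w$mats[[v]]
    Lc <- Lmat[[v]]; K <- ncol(Lc)
    if (inS[v]) {
      msg <- matrix(0, r, r * K)
      for (s in seq_len(r))
        msg[, (s - 1L) * K + seq_len(K)] <- outer(P[, s], Lc[s, ])
      msg <- red(msg)
      mvars <- c(v, Lvars[[v]])
    } else {
      msg <- red(P %*% Lc)
      mvars <- Lvars[[v]]
    }
    par <- w$parent[v]
    Ko <- ncol(Lmat[[par]]); Km <- ncol(msg)
    Lmat[[par]] <- red(Lmat[[par]][, rep(seq_len(Ko), each = Km), drop = FALSE] *
                         msg[, rep(seq_len(Km), Ko), drop = FALSE])
    Lvars[[par]] <- c(Lvars[[par]], mvars)
  }
  Lr <- Lmat[[w$root]]
  if (inS[w$root]) {
    res <- as.vector(t(red(Lr * w$root_dist)))
    vars <- c(w$root, Lvars[[w$root]])
  } else {
    res <- as.vector(red(w$root_dist %*% Lr))
    vars <- Lvars[[w$root]]
  }
  # reorder axes from elimination order to the requested order
  if (m > 1L && !identical(vars, S)) {
    arr <- array(res, dim = rep(r, m))          # dims fastest-first = rev(vars)
    perm <- match(rev(S), rev(vars))
    res <- as.vector(aperm(arr, perm))
  }
  structure(res, vars = S, r = r)
}

#' Full site-pattern tensor over the leaves
#'
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params`.
#' @return vector of length `r^n` over leaf ids in increasing order (last
#'   leaf varies fastest), summing to 1.
#' @export
pattern_tensor <- function(tree, params) {
  joint_tensor(tree, params, leaves(tree))
}

#' Check model conditions (C1)-(C3)
#'
#' (C1) every edge matrix nonsingular; (C2) strictly positive root
#' distribution; (C3) strictly positive entries on internal edges (edges
#' between two non-leaf vertices).  Violations are reported with witnesses,
#' never repaired.
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params`.
#' @param det_tol singular-value floor for C1 (absolute determinant).
#' @return list with elements `C1`, `C2`, `C3` (each `list(pass, witness)`)
#'   and `all_pass`.
#' @export
check_conditions <- function(tree, params, det_tol = 1e-12) {
  deg <- vertex_degrees(tree)
  c1 <- list(pass = TRUE, witness = NULL)
  c3 <- list(pass = TRUE, witness = NULL)
  for (k in names(params$mats)) {
    M <- params$mats[[k]]
    if (abs(det(M)) < det_tol && c1$pass)
      c1 <- list(pass = FALSE, witness = sprintf("edge %s: |det| = %.3g", k, abs(det(M))))
    uv <- as.integer(strsplit(k, ">", fixed = TRUE)[[1L]])
    if (deg[uv[1L]] > 1L && deg[uv[2L]] > 1L && any(M <= 0) && c3$pass) {
      ij <- which(M <= 0, arr.ind = TRUE)[1L, ]
      c3 <- list(pass = FALSE,
                 witness = sprintf("internal edge %s: entry (%d,%d) = 0", k, ij[1L], ij[2L]))
    }
  }
  c2 <- if (all(params$root_dist > 0)) list(pass = TRUE, witness = NULL)
        else list(pass = FALSE,
                  witness = sprintf("root state %d has zero probability",
                                    which(params$root_dist <= 0)[1L] - 1L))
  list(C1 = c1, C2 = c2, C3 = c3,
       all_pass = c1$pass && c2$pass && c3$pass)
}

#' Marginal state distribution at every vertex
#'
#' Forward propagation from the root: `pi_v = pi_u %*% P_uv`.
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params`.
#' @return matrix `nv x r` of marginal distributions.
#' @export
vertex_marginals <- function(tree, params) {
  w <- model_wiring(tree, params)
  pv <- matrix(NA_real_, tree$nv, params$r)
  pv[w$root, ] <- w$root_dist
  for (v in w$ord[-1L])
    pv[v, ] <- as.vector(pv[w$parent[v], ] %*% w$mats[[v]])
  pv
}

#' Move the root of a parameterisation
#'
#' The new root distribution is the marginal state distribution at the new
#' root; every edge whose orientation flips receives the Bayes-reversed
#' matrix `P_vu(i,j) = pi_v(j) P_vu_old(j,i) / pi_u(i)`.  All pattern
#' probabilities over the leaves are unchanged.  Requires strictly positive
#' vertex marginals (guaranteed under (C1)-(C3)).
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params`.
#' @param new_root vertex id or label.
#' @return a `gmm_params` rooted at `new_root` (floating-point; the exact
#'   rational representation does not survive the divisions and is dropped).
#' @export
reroot_params <- function(tree, params, new_root) {
  nr <- resolve_vertices(tree, new_root)
  if (nr == params$root) return(params)
  pv <- vertex_marginals(tree, params)
  if (any(pv <= 0))
    stop("reroot requires strictly positive vertex marginals; check (C1)-(C3)")
  new_edges <- reorient(tree, nr)$edge
  mats <- list()
  for (i in seq_len(nrow(new_edges))) {
    u <- new_edges[i, 1L]; v <- new_edges[i, 2L]
    old <- params$mats[[ekey(u, v)]]
    if (!is.null(old)) {
      mats[[ekey(u, v)]] <- old
    } else {
      Q <- params$mats[[ekey(v, u)]]       # old orientation v -> u
      M <- t(Q * pv[v, ]) / pv[u, ]        # M(i,j) = pi_v(j) Q(j,i) / pi_u(i)
      M <- M / rowSums(M)                  # absorb roundoff
      mats[[ekey(u, v)]] <- M
    }
  }
  gmm_params(tree, nr, pv[nr, ], mats)
}

# integer composition of `total` into `r` parts, each >= minimum, with
# proportions following `w` (largest-remainder rounding)
integer_composition <- function(w, total, minimum = 1L) {
  r <- length(w)
  spare <- total - r * minimum
  if (spare < 0L) stop("denominator too small for the entry floor")
  base <- w / sum(w) * spare
  x <- floor(base)
  deficit <- spare - sum(x)
  if (deficit > 0) {
    top <- order(base - x, decreasing = TRUE)[seq_len(deficit)]
    x[top] <- x[top] + 1
  }
  as.numeric(x + minimum)
}

#' Seeded generic parameter generator
#'
#' Rows and the root distribution are drawn from the flat Dirichlet; any
#' matrix with `|det| < min_det`, or any root/internal-edge entry below
#' `min_entry`, triggers a resample (all generated entries are kept strictly
#' positive for simplicity, which also satisfies (C3) automatically).  With
#' `rational = TRUE` every row is an integer composition of `denom`, giving
#' an exact representation for certified rank computations.
#'
#' @param tree a `phylo_graph`.
#' @param r state count (>= 2).
#' @param seed integer seed (results are deterministic given the seed).
#' @param min_entry entry floor for the root distribution and all matrices.
#' @param min_det determinant floor for (C1) genericity.
#' @param rational store an exact integer/denominator representation.
#' @param denom common row denominator in rational mode.
#' @param budget resampling budget per matrix.
#' @return a `gmm_params` that passes [check_conditions()].
#' @export
random_generic_params <- function(tree, r, seed = NULL, min_entry = 1e-3,
                                  min_det = 1e-6, rational = FALSE,
                                  denom = 1000L, budget = 1000L) {
  if (r < 2L) stop("r must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  minnum <- max(1L, ceiling(min_entry * denom))
  draw_row <- function() {
    for (i in seq_len(budget)) {
      w <- stats::rgamma(r, 1)
      if (rational) {
        num <- integer_composition(w, denom, minnum)
        return(list(row = num / denom, num = num, den = denom))
      }
      row <- w / sum(w)
      if (min(row) >= min_entry) return(list(row = row))
    }
    stop("resampling budget exhausted while drawing a probability row")
  }
  draw_matrix <- function() {
    for (i in seq_len(budget)) {
      rows <- lapply(seq_len(r), function(i) draw_row())
      M <- do.call(rbind, lapply(rows, `[[`, "row"))
      if (abs(det(M)) < min_det) next
      if (min(M) < min_entry && !rational) next
      out <- list(M = M)
      if (rational) {
        out$num <- do.call(rbind, lapply(rows, `[[`, "num"))
        out$den <- rep(denom, r)
      }
      return(out)
    }
    stop("resampling budget exhausted while drawing a transition matrix")
  }
  rd <- draw_row()
  oriented <- reorient(tree, tree$root)$edge
  mats <- list(); rmats <- list()
  for (i in seq_len(nrow(oriented))) {
    k <- ekey(oriented[i, 1L], oriented[i, 2L])
    dm <- draw_matrix()
    mats[[k]] <- dm$M
    if (rational) rmats[[k]] <- list(num = dm$num, den = dm$den)
  }
  rational_rep <- if (rational)
    list(root_num = rd$num, root_den = rd$den, mats = rmats) else NULL
  gmm_params(tree, tree$root, rd$row, mats, rational = rational_rep)
}

#' Simulate an alignment of iid sites
#'
#' Root-to-leaf sampling of `n_sites` independent site patterns.
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params`.
#' @param n_sites number of sites (>= 0).
#' @param seed optional integer seed.
#' @return integer matrix (leaves x sites, states `0..r-1`) with taxon labels
#'   as row names.
#' @export
simulate_alignment <- function(tree, params, n_sites, seed = NULL) {
  if (n_sites < 0L) stop("n_sites must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  r <- params$r
  w <- model_wiring(tree, params)
  states <- matrix(0L, tree$nv, n_sites)
  states[w$root, ] <- sample.int(r, n_sites, replace = TRUE,
                                 prob = w$root_dist) - 1L
  for (v in w$ord[-1L]) {
    ps <- states[w$parent[v], ]
    for (s in seq_len(r) - 1L) {
      idx <- which(ps == s)
      if (length(idx))
        states[v, idx] <- sample.int(r, length(idx), replace = TRUE,
                                     prob = w$mats[[v]][s + 1L, ]) - 1L
    }
  }
  lv <- leaves(tree)
  out <- states[lv, , drop = FALSE]
  rownames(out) <- tree$labels[lv]
  out
}

#' Default presentation alphabet for r states
#'
#' Two states map to purine/pyrimidine codes R/Y, four to nucleotides; other
#' state counts use capital letters.  Purely an I/O convention; all internal
#' computation is on integer states `0..r-1`.
#' @param r state count.
#' @return character vector of length `r`.
#' @export
default_alphabet <- function(r) {
  if (r == 2L) c("R", "Y")
  else if (r == 4L) c("A", "C", "G", "T")
  else if (r <= 26L) LETTERS[seq_len(r)]
  else stop("no default alphabet for r > 26")
}

#' Write an alignment to FASTA
#' @param aln integer state matrix from [simulate_alignment()].
#' @param file output path.
#' @param alphabet symbols for states `0..r-1` (default [default_alphabet()]).
#' @param r state count (needed if `alphabet` is `NULL` and the alignment
#'   does not use all states).
#' @export
write_alignment_fasta <- function(aln, file, alphabet = NULL, r = NULL) {
  if (is.null(alphabet)) {
    if (is.null(r)) r <- max(aln) + 1L
    alphabet <- default_alphabet(r)
  }
  seqs <- lapply(seq_len(nrow(aln)), function(i) alphabet[aln[i, ] + 1L])
  seqinr::write.fasta(seqs, names = rownames(aln), file.out = file)
  invisible(file)
}

#' Read an alignment from FASTA
#' @param file FASTA path.
#' @param alphabet symbols for states `0..r-1`.
#' @param r state count (used to pick a default alphabet).
#' @return integer state matrix with taxon row names.
#' @export
read_alignment_fasta <- function(file, alphabet = NULL, r = NULL) {
  if (is.null(alphabet)) {
    if (is.null(r)) stop("supply alphabet or r")
    alphabet <- default_alphabet(r)
  }
  seqs <- seqinr::read.fasta(file, forceDNAtolower = FALSE, as.string = FALSE)
  m <- do.call(rbind, lapply(seqs, function(s)
    match(toupper(as.character(s)), alphabet) - 1L))
  if (anyNA(m)) stop("alignment contains symbols outside the alphabet")
  rownames(m) <- names(seqs)
  storage.mode(m) <- "integer"
  m
}

#' Write model parameters to YAML
#'
#' Matrices are keyed `parent>child` using vertex labels where available and
#' `#id` for unlabeled internal vertices.
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params`.
#' @param file output path.
#' @export
write_params_yaml <- function(tree, params, file) {
  vname <- function(v) ifelse(is.na(tree$labels[v]), paste0("#", v), tree$labels[v])
  mats <- list()
  for (k in names(params$mats)) {
    uv <- as.integer(strsplit(k, ">", fixed = TRUE)[[1L]])
    mats[[paste0(vname(uv[1L]), ">", vname(uv[2L]))]] <-
      lapply(seq_len(params$r), function(i) as.numeric(params$mats[[k]][i, ]))
  }
  yaml::write_yaml(list(r = params$r, root = vname(params$root),
                        root_dist = as.numeric(params$root_dist),
                        matrices = mats), file, precision = 17L)
  invisible(file)
}

#' Read model parameters from YAML
#' @param tree the `phylo_graph` the parameters belong to.
#' @param file YAML path written by [write_params_yaml()] (or hand-authored
#'   in the same layout).
#' @return a `gmm_params`.
#' @export
read_params_yaml <- function(tree, file) {
  y <- yaml::read_yaml(file)
  vid <- function(s) {
    if (grepl("^#[0-9]+$", s)) as.integer(sub("#", "", s, fixed = TRUE))
    else resolve_vertices(tree, s)
  }
  mats <- list()
  for (k in names(y$matrices)) {
    uv <- strsplit(k, ">", fixed = TRUE)[[1L]]
    M <- do.call(rbind, lapply(y$matrices[[k]], as.numeric))
    mats[[ekey(vid(uv[1L]), vid(uv[2L]))]] <- M
  }
  gmm_params(tree, vid(y$root), as.numeric(y$root_dist), mats)
}
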