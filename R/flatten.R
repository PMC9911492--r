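# Flattenings: matrix unfoldings of the site-pattern probability tensor.
#
# For disjoint vertex subsets A and B, flat_{A|B}(f_A, f_B) =
# pi(X_A = f_A, X_B = f_B), an r^|A| x r^|B| matrix.  Index convention
# throughout: the row index of the assignment f_A is
#   sum_k f_A(a_k) * r^(|A| - 1 - k)        (0-based, last vertex fastest),
# i.e. rows enumerate 00..0, 00..1, ..., matching the usual p_RRRR, p_RRRY,
# p_RRYR, ... presentation; columns likewise for B.

#' Build the flattening matrix for a vertex bipartition
#'
#' Entries are exact model marginals with all vertices outside A and B
#' (leaves or internal) summed out.
#'
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params`.
#' @param A,B disjoint non-empty ordered vertex sets (ids or labels); the
#'   given order fixes the row/column order.
#' @param p optional prime modulus: compute the matrix of residues in GF(p)
#'   from the rational parameter representation (exact mode).
#' @return an object of class `flattening`: fields `r`, `row_vertices`,
#'   `col_vertices`, `matrix`, `mod` (the prime, or `NULL`).
#' @export
build_flattening <- function(tree, params, A, B, p = NULL) {
  a <- resolve_vertices(tree, A); b <- resolve_vertices(tree, B)
  if (!length(a) || !length(b)) stop("A and B must be non-empty")
  if (length(intersect(a, b))) stop("A and B must be disjoint")
  r <- params$r
  if (r^(length(a) + length(b)) > 2^24)
    stop("flattening would exceed the 2^24-entry cap")
  # request order (B, A): the A block then varies fastest, which is exactly
  # the column-major layout of an r^|A| x r^|B| matrix
  tens <- joint_tensor(tree, params, c(b, a), p = p)
  M <- matrix(as.numeric(tens), nrow = r^length(a))
  structure(list(r = r, row_vertices = a, col_vertices = b,
                 matrix = M, mod = p),
            class = "flattening")
}

#' @export
print.flattening <- function(x, ...) {
  cat(sprintf("flattening: %d x %d (r = %d)%s\n",
              nrow(x$matrix), ncol(x$matrix), x$r,
              if (!is.null(x$mod)) sprintf(" over GF(%d)", x$mod) else ""))
  invisible(x)
}

# enumerate all assignments to m vertices in index order (rows = assignments,
# last vertex fastest); used for layout tests and marginalization matrices
state_assignments <- function(m, r) {
  idx <- seq_len(r^m) - 1L
  out <- matrix(0L, r^m, m)
  for (k in seq_len(m)) out[, k] <- (idx %/% r^(m - k)) %% r
  out
}

#' Numerical rank report for a flattening
#'
#' SVD-based.  The default tolerance is `sigma_max * 1e-9`; true flattening
#' ranks are powers of r, so for generic parameters on small trees the
#' spectrum shows a large gap, reported as a diagnostic.  When the
#' flattening was built over GF(p) the rank is instead computed exactly by
#' elimination.
#'
#' @param flat a `flattening` (or plain matrix).
#' @param tol absolute tolerance; default `1e-9 * sigma_max`.
#' @param k split-score parameter (score sums singular values beyond the
#'   `r^k` largest).
#' @param predicted_rank optional predicted rank `r^nu` to record.
#' @return an object of class `rank_report`: `singular_values`,
#'   `numerical_rank`, `exact_rank` (GF(p) mode only), `tolerance`,
#'   `spectral_gap`, `split_score`, `predicted_rank`.
#' @export
flattening_rank <- function(flat, tol = NULL, k = 1L, predicted_rank = NULL) {
  M <- if (inherits(flat, "flattening")) flat$matrix else as.matrix(flat)
  if (!length(M)) stop("empty matrix")
  if (inherits(flat, "flattening") && !is.null(flat$mod)) {
    er <- mod_rank(M, flat$mod)
    return(structure(list(singular_values = NULL, numerical_rank = NA_integer_,
                          exact_rank = er, tolerance = NULL,
                          spectral_gap = NULL, split_score = NULL,
                          predicted_rank = predicted_rank,
                          mod = flat$mod),
                     class = "rank_report"))
  }
  sv <- svd(M, nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- 1e-9 * sv[1L]
  nr <- sum(sv > tol)
  gap <- if (nr >= 1L && nr < length(sv) && sv[nr + 1L] > 0)
    sv[nr] / sv[nr + 1L] else Inf
  r <- if (inherits(flat, "flattening")) flat$r else NULL
  score <- if (!is.null(r) && r^k <= min(dim(M)))
    split_score(flat, k = k) else NULL
  structure(list(singular_values = sv, numerical_rank = nr,
                 exact_rank = NULL, tolerance = tol, spectral_gap = gap,
                 split_score = score, predicted_rank = predicted_rank,
                 mod = NULL),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  if (!is.null(x$exact_rank))
    cat(sprintf("rank %d (exact, GF(%d))", x$exact_rank, x$mod))
  else
    cat(sprintf("rank %d (numerical, tol %.2e, gap %.2e)",
                x$numerical_rank, x$tolerance, x$spectral_gap))
  if (!is.null(x$predicted_rank)) cat(sprintf("; predicted %d", x$predicted_rank))
  cat("\n")
  invisible(x)
}

#' Split score of a flattening
#'
#' Sum of the singular values beyond the largest `r^k`, divided by the sum
#' of all singular values.  Zero exactly when the rank is at most `r^k`;
#' with `k = 1` (the default) this is the usual split score: splits that
#' belong to the tree score 0 on exact probabilities.
#' @param flat a `flattening` (floating-point mode).
#' @param k non-negative integer.
#' @return a number in `[0, 1]`.
#' @export
split_score <- function(flat, k = 1L) {
  M <- if (inherits(flat, "flattening")) flat$matrix else as.matrix(flat)
  r <- if (inherits(flat, "flattening")) flat$r else stop("need a flattening")
  if (!is.null(flat$mod)) stop("split scores are defined for numeric flattenings")
  if (k < 0L) stop("k must be non-negative")
  keep <- r^k
  if (keep > min(dim(M)))
    stop("r^k exceeds the smaller matrix dimension")
  sv <- svd(M, nu = 0, nv = 0)$d
  sum(sv[-seq_len(keep)]) / sum(sv)
}

#' Certified flattening rank over prime fields
#'
#' Builds the flattening in GF(p) for each prime from the exact rational
#' parameter representation and returns the elimination rank.  Ranks modulo
#' different primes can only under-estimate the rational rank, so the
#' maximum over primes is reported, with a flag for inter-prime agreement.
#' @param tree a `phylo_graph`.
#' @param params a `gmm_params` carrying a rational representation.
#' @param A,B disjoint vertex sets.
#' @param primes primes below 2^25 (default two built-in).
#' @return list: `rank`, `per_prime`, `agree`.
#' @export
exact_flattening_rank <- function(tree, params, A, B, primes = FR_PRIMES) {
  ranks <- vapply(primes, function(p) {
    fl <- build_flattening(tree, params, A, B, p = p)
    mod_rank(fl$matrix, p)
  }, numeric(1))
  list(rank = as.integer(max(ranks)), per_prime = as.integer(ranks),
       agree = length(unique(ranks)) == 1L)
}

#' Empirical flattening from an alignment
#'
#' Site-pattern relative frequencies arranged with the same index convention
#' as [build_flattening()]; the data-facing analogue of the exact
#' flattening.  Splits must be over leaf labels.
#' @param aln integer state matrix (taxa x sites) with taxon row names.
#' @param A,B disjoint taxon label sets.
#' @param r state count (default inferred from the alignment).
#' @return a `flattening` whose entries sum to 1.
#' @export
empirical_flattening <- function(aln, A, B, r = max(aln) + 1L) {
  A <- as.character(A); B <- as.character(B)
  if (length(intersect(A, B))) stop("A and B must be disjoint")
  miss <- setdiff(c(A, B), rownames(aln))
  if (length(miss)) stop("unknown taxon: ", miss[1L])
  n <- ncol(aln)
  if (!n) stop("empty alignment")
  enc <- function(taxa) {
    idx <- rep(0, n)
    for (k in seq_along(taxa))
      idx <- idx * r + aln[taxa[k], ]
    idx + 1
  }
  rows <- enc(A); cols <- enc(B)
  M <- matrix(0, r^length(A), r^length(B))
  for (i in seq_len(n)) M[rows[i], cols[i]] <- M[rows[i], cols[i]] + 1
  structure(list(r = as.integer(r), row_vertices = A, col_vertices = B,
                 matrix = M / n, mod = NULL),
            class = "flattening")
}

#' Marginalization matrix between nested flattenings
#'
#' The 0-1 matrix `U` with `U[f', f] = 1` iff the assignment `f` to
#' `vertices` restricts to `f'` on `sub`.  For `A' <= A`, `B' <= B`,
#' `flat_{A'|B'} = U_A flat_{A|B} t(U_B)` — the marginalization-
#' monotonicity witness for rank comparisons.
#' @param sub ordered subset of `vertices`.
#' @param vertices ordered vertex list of the larger flattening side.
#' @param r state count.
#' @return an `r^|sub| x r^|vertices|` 0-1 matrix.
#' @export
marginalization_matrix <- function(sub, vertices, r) {
  pos <- match(sub, vertices)
  if (anyNA(pos)) stop("sub must be a subset of vertices")
  big <- state_assignments(length(vertices), r)
  restricted <- big[, pos, drop = FALSE]
  rows <- as.vector(restricted %*% r^(rev(seq_along(pos)) - 1L)) + 1L
  U <- matrix(0, r^length(sub), r^length(vertices))
  U[cbind(rows, seq_len(nrow(big)))] <- 1
  U
}
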