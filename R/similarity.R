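#' Fuse per-source similarity matrices into an overall similarity
#'
#' The overall drug (or miRNA) similarity is the element-wise weighted mean
#' of the per-source matrices, `sum(w_i * S_i) / sum(w_i)`.  With the default
#' unit weights this is the plain arithmetic mean of the sources.
#'
#' @param matrices list of similarity matrices over identical, identically
#'   ordered entity ids (see [similarity_matrix()]).
#' @param weights non-negative weights, one per matrix; at least one must be
#'   positive.  Default: unit weight for every source.
#' @param kind kind tag for the fused output, `"fused_drug"` or
#'   `"fused_mirna"`.
#' @return the fused similarity matrix.
#' @export
fuse_similarities <- function(matrices, weights = rep(1, length(matrices)),
                              kind = c("fused_drug", "fused_mirna")) {
  kind <- match.arg(kind)
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("at least one similarity matrix is required")
  }
  if (length(weights) != length(matrices)) {
    stop("one weight per similarity matrix is required")
  }
  if (any(weights < 0) || any(!is.finite(weights))) {
    stop("weights must be finite and non-negative")
  }
  if (sum(weights) <= 0) stop("at least one weight must be positive")
  ids <- rownames(matrices[[1L]])
  for (S in matrices) {
    if (!identical(rownames(S), ids)) {
      stop("all similarity matrices must share identical, identically ordered ids")
    }
  }
  fused <- Reduce(`+`, Map(`*`, matrices, weights)) / sum(weights)
  similarity_matrix(fused, ids = ids, kind = kind)
}

#' p-nearest-neighbour weight mask of a similarity matrix
#'
#' For each entity, its p-neighbourhood `N_p(i)` holds the `p` most similar
#' *other* entities (descending similarity, ties broken by ascending index
#' for determinism).  The mask is
#' `G_ij = 1` if the membership is mutual, `0` if neither entity is in the
#' other's neighbourhood, and `0.5` one-sided; `G_ii = 1`.  Because
#' membership depends only on similarity ranks, the mask is invariant to any
#' strictly increasing transform of the similarities.
#'
#' @param S similarity matrix.
#' @param p neighbourhood size, `1 <= p <= nrow(S) - 1`.
#' @return square matrix with entries in `{0, 0.5, 1}`.
#' @export
knn_weight_mask <- function(S, p) {
  n <- nrow(S)
  if (length(p) != 1L || p < 1L || p > n - 1L) {
    stop(sprintf("p must be in [1, %d]", n - 1L))
  }
  p <- as.integer(p)
  # member[i, j] == TRUE iff i is among the p nearest neighbours of j
  member <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    cand <- setdiff(seq_len(n), j)
    nb <- cand[order(-S[cand, j], cand)][seq_len(p)]
    member[nb, j] <- TRUE
  }
  G <- (member + t(member)) / 2
  diag(G) <- 1
  dimnames(G) <- dimnames(S)
  G
}

#' Sparsify a similarity matrix with a neighbourhood mask
#'
#' Element-wise product `S * G`; symmetric because both factors are.
#'
#' @param S similarity matrix.
#' @param G weight mask from [knn_weight_mask()] (same shape as `S`).
#' @return sparse similarity matrix `S*`.
#' @export
sparsify_similarity <- function(S, G) {
  if (!all(dim(S) == dim(G))) stop("similarity and mask shapes differ")
  out <- unclass(S) * G
  attr(out, "kind") <- NULL
  dimnames(out) <- dimnames(S)
  out
}

#' Build the neighbourhood graph of an entity space
#'
#' Composes [knn_weight_mask()] and [sparsify_similarity()], then forms the
#' degree matrix `D` (`D_ii = sum_l S*_il`) and the graph Laplacian
#' `L = D - S*` used for manifold regularization of the factorization.  By
#' construction every row of `L` sums to zero and `L` is positive
#' semi-definite: `x' L x = 1/2 * sum_ij S*_ij (x_i - x_j)^2 >= 0`.
#'
#' @inheritParams knn_weight_mask
#' @return an object of class `sim_graph`: a list with elements
#'   `entity_ids`, `mask` (G), `s_sparse` (S*), `degree` (the diagonal of D)
#'   and `laplacian` (L).
#' @export
build_graph <- function(S, p = 5) {
  G <- knn_weight_mask(S, p)
  Ss <- sparsify_similarity(S, G)
  deg <- rowSums(Ss)
  L <- diag(deg, nrow(Ss)) - Ss
  dimnames(L) <- dimnames(Ss)
  structure(
    list(entity_ids = rownames(S), p = as.integer(p), mask = G,
         s_sparse = Ss, degree = deg, laplacian = L),
    class = "sim_graph"
  )
}

#' @export
print.sim_graph <- function(x, ...) {
  cat(sprintf("<sim_graph> %d entities, p = %d, %.0f retained edges\n",
              length(x$entity_ids), x$p,
              (sum(x$mask > 0) - length(x$entity_ids)) / 2))
  invisible(x)
}

#' Misalign a similarity matrix by permuting its entities
#'
#' Applies one random permutation to the rows and columns of `S` while
#' keeping the original id labels in place.  Symmetry, range and the
#' similarity value distribution are preserved, but the link between an id
#' and its similarity profile is destroyed — the negative control used to
#' show that the side information, not its marginal distribution, drives
#' prediction performance.
#'
#' @param S similarity matrix.
#' @param seed optional integer seed for the permutation.
#' @return permuted similarity matrix with the original dimnames.
#' @export
permute_similarity <- function(S, seed = NULL) {
  perm <- with_rng_seed(seed, sample.int(nrow(S)))
  out <- unclass(S)[perm, perm]
  dimnames(out) <- dimnames(S)
  attr(out, "kind") <- attr(S, "kind")
  out
}

# Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the global stream untouched.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
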