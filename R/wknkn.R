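#' Repair an association matrix with weighted K-nearest-known-neighbour profiles
#'
#' Sparse association matrices carry many false negatives: unobserved pairs
#' are recorded as 0.  This preprocessing step replaces unknown zeros with a
#' likelihood score borrowed from the interaction profiles of each entity's
#' most similar *known* neighbours (entities with at least one recorded
#' association), so that the factorization does not treat every 0 as a
#' confident negative.
#'
#' For drug `l`, candidate neighbours are ranked by descending similarity
#' `SD(i, l)` (self excluded, ties broken by ascending index) and the `K`
#' nearest known ones contribute their profiles:
#'
#' \deqn{Yd(l) = \frac{\sum_{i=1}^{K} \alpha^{i-1}\, SD(d_i, l)\, Y(d_i)}
#'                    {\sum_{i=1}^{K} SD(d_i, l)}}
#'
#' Note the denominator carries the similarities but not the rank-decay
#' \eqn{\alpha^{i-1}}; with \eqn{\alpha < 1} the profile is therefore a
#' damped, not a convex, combination.  This asymmetry is deliberate and kept
#' exactly as defined.  The symmetric construction over miRNA columns gives
#' `Ym`; the two are averaged, `Ydm = (Yd + Ym) / 2` (clipped at 1 against
#' numeric drift), and merged with the observed matrix by element-wise
#' maximum, so observed 1s always survive unchanged.
#'
#' When an entity has fewer than `K` known neighbours all available ones are
#' used (with a consolidated warning); an entity with a zero similarity sum
#' over its neighbours contributes an all-zero profile.
#'
#' @param Y binary drug x miRNA association matrix ([association_matrix()]).
#' @param SD,SM fused drug and miRNA similarity matrices, id-aligned with
#'   the rows / columns of `Y`.
#' @param K number of nearest known neighbours (default 3).
#' @param alpha rank-decay factor in `(0, 1]` (default 0.9).
#' @param known_only if `TRUE` (default) only entities with at least one
#'   recorded association are eligible neighbours; `FALSE` ranks all
#'   neighbours regardless of their profiles.
#' @return a list of class `wknkn_result` with elements `y_new` (the
#'   repaired real-valued association matrix, `>= Y` element-wise), `y_drug`
#'   (`Yd`), `y_mirna` (`Ym`), and the parameters used.
#' @export
wknkn_profiles <- function(Y, SD, SM, K = 3, alpha = 0.9, known_only = TRUE) {
  stopifnot(is.matrix(Y), is.matrix(SD), is.matrix(SM))
  if (K < 1 || K != round(K)) stop("K must be a positive integer")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  align_ids(rownames(Y), rownames(SD), "drug")
  align_ids(colnames(Y), rownames(SM), "miRNA")

  Yd <- neighbour_profiles(Y, SD, K, alpha, known_only, margin = 1L)
  Ym <- neighbour_profiles(Y, SM, K, alpha, known_only, margin = 2L)
  Ydm <- pmin((Yd + Ym) / 2, 1)
  y_new <- pmax(unclass(Y), Ydm)
  dimnames(y_new) <- dimnames(Y)
  structure(
    list(y_new = y_new, y_drug = Yd, y_mirna = Ym,
         K = as.integer(K), alpha = alpha, known_only = known_only),
    class = "wknkn_result"
  )
}

align_ids <- function(a, b, what) {
  if (is.null(a) || is.null(b) || !identical(a, b)) {
    stop(sprintf("%s ids of the association and similarity matrices must be identical and identically ordered", what))
  }
  invisible(TRUE)
}

# Profile reconstruction along one margin: margin 1 = drug rows ranked by SD,
# margin 2 = miRNA columns ranked by SM.  Returns a matrix shaped like Y.
neighbour_profiles <- function(Y, S, K, alpha, known_only, margin) {
  M <- if (margin == 1L) unclass(Y) else t(unclass(Y))
  n <- nrow(M)
  out <- matrix(0, n, ncol(M))
  known <- rowSums(M) > 0
  short <- 0L
  for (l in seq_len(n)) {
    cand <- setdiff(seq_len(n), l)
    if (known_only) cand <- cand[known[cand]]
    if (length(cand) == 0L) next
    cand <- cand[order(-S[cand, l], cand)]
    if (length(cand) < K) short <- short + 1L
    nb <- cand[seq_len(min(K, length(cand)))]
    sims <- S[nb, l]
    denom <- sum(sims)
    if (denom <= 0) next
    theta <- alpha^(seq_along(nb) - 1L) * sims
    out[l, ] <- crossprod(M[nb, , drop = FALSE], theta) / denom
  }
  if (short > 0L) {
    warning(sprintf(
      "%d %s profile(s) had fewer than K = %d known neighbours; used all available",
      short, if (margin == 1L) "drug" else "miRNA", K
    ))
  }
  res <- if (margin == 1L) out else t(out)
  dimnames(res) <- dimnames(Y)
  res
}

#' @export
print.wknkn_result <- function(x, ...) {
  filled <- sum(x$y_new > 0) - sum(x$y_new == 1)
  cat(sprintf(
    "<wknkn_result> %d x %d, K = %d, alpha = %g; %d zero entries given a likelihood score\n",
    nrow(x$y_new), ncol(x$y_new), x$K, x$alpha, filled
  ))
  invisible(x)
}
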