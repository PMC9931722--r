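#' Objective value of the graph-regularized factorization
#'
#' Evaluates
#' \deqn{\|Y - W^\top H\|_F^2
#'       + \lambda\,[\mathrm{tr}(W L_d W^\top) + \mathrm{tr}(H L_m H^\top)]
#'       + \beta\,[\|W\|_F^2 + \|H\|_F^2]}
#' where `Ld`, `Lm` are the graph Laplacians of the sparsified drug and
#' miRNA similarity spaces.  The trace form of the graph terms equals the
#' pairwise form `1/2 * sum_ij S*_ij ||w_i - w_j||^2` summed over ordered
#' pairs (i.e. `sum_{i<=j}` over unordered ones).
#'
#' @param Y association matrix (n drugs x m miRNAs), real-valued.
#' @param W,H non-negative factor matrices, `k x n` and `k x m`.
#' @param Gd,Gm drug and miRNA [build_graph()] objects.
#' @param lam graph regularization coefficient (lambda).
#' @param beta Tikhonov (Frobenius) regularization coefficient.
#' @return a single non-negative number.
#' @export
gnmf_objective <- function(Y, W, H, Gd, Gm, lam = 1, beta = 0.02) {
  if (any(W < 0) || any(H < 0)) stop("factors must be non-negative")
  R <- Y - crossprod(W, H)
  sum(R * R) +
    lam * (sum((W %*% Gd$laplacian) * W) + sum((H %*% Gm$laplacian) * H)) +
    beta * (sum(W * W) + sum(H * H))
}

#' One multiplicative update sweep
#'
#' Applies the Gauss-Seidel multiplicative rules: `W` is updated first,
#'
#' \deqn{W \leftarrow W \circ \frac{H Y^\top + \lambda W S_D^*}
#'                                {H H^\top W + \beta W + \lambda W D_d + \epsilon}}
#'
#' then `H` using the already-updated `W`,
#'
#' \deqn{H \leftarrow H \circ \frac{W Y + \lambda H S_M^*}
#'                                {W W^\top H + \beta H + \lambda H D_m + \epsilon}}
#'
#' Zeros in a factor are fixed points of its rule, and non-negativity is
#' preserved exactly.  With `jacobi = TRUE` both factors are updated from
#' the same previous iterate (the simultaneous form of the derivation).
#'
#' @inheritParams gnmf_objective
#' @param eps guard added to every denominator entry (the raw rules divide
#'   by possibly-zero entries); set to 0 only on strictly positive problems.
#' @param jacobi update `H` from the pre-update `W`?
#' @return list with the updated `W` and `H`.
#' @export
gnmf_update_step <- function(Y, W, H, Gd, Gm, lam = 1, beta = 0.02,
                             eps = 1e-12, jacobi = FALSE) {
  Sd <- Gd$s_sparse; dd <- Gd$degree
  Sm <- Gm$s_sparse; dm <- Gm$degree
  Wref <- W
  W <- W * (tcrossprod(H, Y) + lam * W %*% Sd) /
    (tcrossprod(H) %*% W + beta * W + lam * sweep(W, 2L, dd, `*`) + eps)
  if (!all(is.finite(W))) stop("non-finite entries in W after update")
  Wh <- if (jacobi) Wref else W
  H <- H * (Wh %*% Y + lam * H %*% Sm) /
    (tcrossprod(Wh) %*% H + beta * H + lam * sweep(H, 2L, dm, `*`) + eps)
  if (!all(is.finite(H))) stop("non-finite entries in H after update")
  list(W = W, H = H)
}

#' Fit the graph-regularized non-negative factorization
#'
#' Decomposes the (repaired) association matrix as `Y ~ t(W) %*% H` with
#' `k`-dimensional non-negative latent factors per drug (`W`, `k x n`) and
#' per miRNA (`H`, `k x m`), minimizing [gnmf_objective()] by multiplicative
#' updates.  Both factors are initialized i.i.d. uniform on `(0, 1)` scaled
#' by `sqrt(mean(Y) / k)` so the initial reconstruction matches the data
#' magnitude; the draw is controlled by `seed`, and identical seeds give
#' bit-identical fits.
#'
#' Iteration stops when, for every column of `W` *and* every column of `H`,
#' the squared norm of the per-column change falls to `tol` or below
#' (default `1e-4`, applied to the raw unnormalized columns), or after
#' `max_iter` sweeps (then `converged = FALSE` with a warning).
#'
#' @inheritParams gnmf_update_step
#' @param k subspace dimensionality, `k < min(n, m)` (default 35).
#' @param max_iter iteration cap (default 1000).
#' @param tol per-column squared-change threshold (default 1e-4).
#' @param seed integer seed for the factor initialization; `NULL` uses the
#'   current RNG stream.
#' @return an object of class `gnmf_fit`: list with `W`, `H`, `objective`
#'   (value after every sweep), `iterations`, `converged`, the
#'   regularization settings and the seed.
#' @seealso [predict.gnmf_fit()], [generics::tidy()], [generics::glance()]
#' @export
gnmf_fit <- function(Y, Gd, Gm, k = 35, lam = 1, beta = 0.02,
                     max_iter = 1000, tol = 1e-4, eps = 1e-12,
                     seed = NULL, jacobi = FALSE) {
  n <- nrow(Y); m <- ncol(Y)
  if (k >= min(n, m)) {
    stop(sprintf("k = %d must be smaller than min(n, m) = %d", k, min(n, m)))
  }
  if (!identical(rownames(Y), Gd$entity_ids) ||
      !identical(colnames(Y), Gm$entity_ids)) {
    stop("graph entity ids must match the association matrix ids")
  }
  Y <- unclass(Y)
  scale <- sqrt(max(mean(Y), .Machine$double.xmin) / k)
  init <- with_rng_seed(seed, list(
    W = matrix(runif(k * n), k, n) * scale,
    H = matrix(runif(k * m), k, m) * scale
  ))
  W <- init$W; H <- init$H
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    upd <- gnmf_update_step(Y, W, H, Gd, Gm, lam, beta, eps, jacobi)
    dW <- max(colSums((upd$W - W)^2))
    dH <- max(colSums((upd$H - H)^2))
    W <- upd$W; H <- upd$H
    objective <- c(objective, gnmf_objective(Y, W, H, Gd, Gm, lam, beta))
    if (dW <= tol && dH <= tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("factorization did not converge in %d iterations", max_iter))
  }
  structure(
    list(W = W, H = H, objective = objective, iterations = iter,
         converged = converged, k = as.integer(k), lam = lam, beta = beta,
         tol = tol, eps = eps, seed = seed,
         drug_ids = rownames(Y), mirna_ids = colnames(Y)),
    class = "gnmf_fit"
  )
}

#' Predicted association scores
#'
#' The completed association matrix `Y* = t(W) %*% H`; every entry is a
#' non-negative score, and within each drug row the highest-scoring miRNAs
#' are the strongest candidates.
#'
#' @param object a [gnmf_fit()] object.
#' @param ... unused.
#' @return drug x miRNA score matrix with the fit's identifiers as dimnames.
#' @export
predict.gnmf_fit <- function(object, ...) {
  scores <- crossprod(object$W, object$H)
  dimnames(scores) <- list(object$drug_ids, object$mirna_ids)
  scores
}

#' @export
print.gnmf_fit <- function(x, ...) {
  cat(sprintf(
    "<gnmf_fit> k = %d, lambda = %g, beta = %g; %d iterations (%s), objective %.6g\n",
    x$k, x$lam, x$beta, x$iterations,
    if (x$converged) "converged" else "not converged",
    x$objective[length(x$objective)]
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-iteration objective trace of a fit
#'
#' @param x a `gnmf_fit` object.
#' @param ... unused.
#' @return tibble with columns `iteration` and `objective`.
#' @method tidy gnmf_fit
#' @export
tidy.gnmf_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$objective), objective = x$objective)
}

#' One-row summary of a fit
#'
#' @param x a `gnmf_fit` object.
#' @param ... unused.
#' @return one-row tibble: `k`, `lambda`, `beta`, `iterations`, `converged`,
#'   `objective` (final value).
#' @method glance gnmf_fit
#' @export
glance.gnmf_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, lambda = x$lam, beta = x$beta,
    iterations = x$iterations, converged = x$converged,
    objective = x$objective[length(x$objective)]
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Objective trace plot
#'
#' Monotone decrease of the objective across multiplicative-update sweeps.
#'
#' @param object a `gnmf_fit` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gnmf_fit
#' @export
autoplot.gnmf_fit <- function(object, ...) {
  df <- tidy.gnmf_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "objective (log scale)",
                  title = sprintf("k = %d, lambda = %g, beta = %g",
                                  object$k, object$lam, object$beta))
}

#' @importFrom ggplot2 .data
NULL
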