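#' Partition known association pairs into cross-validation folds
#'
#' The positive (known) drug-miRNA pairs are divided uniformly at random
#' into `n_folds` subsets of as-equal-as-possible size (sizes differ by at
#' most one).  Only positives are partitioned; the zero cells form the
#' negative universe shared by every fold.
#'
#' @param Y binary association matrix.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed making the partition reproducible.
#' @return object of class `fold_split`: a tibble with columns `drug_id`,
#'   `mirna_id`, `row`, `col`, `fold`, plus `n_folds` and `seed` attributes.
#' @export
make_folds <- function(Y, n_folds = 5, seed = NULL) {
  pos <- which(unclass(Y) == 1, arr.ind = TRUE)
  if (nrow(pos) < n_folds) {
    stop(sprintf("need at least %d positive pairs for %d folds, have %d",
                 n_folds, n_folds, nrow(pos)))
  }
  fold <- with_rng_seed(seed,
    sample(rep(seq_len(n_folds), length.out = nrow(pos))))
  out <- tibble::tibble(
    drug_id = rownames(Y)[pos[, 1L]],
    mirna_id = colnames(Y)[pos[, 2L]],
    row = as.integer(pos[, 1L]),
    col = as.integer(pos[, 2L]),
    fold = as.integer(fold)
  )
  structure(out, n_folds = as.integer(n_folds), seed = seed,
            class = c("fold_split", class(out)))
}

#' Area under the ROC curve (rank statistic)
#'
#' Tie-corrected AUC: the probability that a uniformly chosen positive
#' outscores a uniformly chosen negative, with ties counting one half.
#' Computed from midranks, so it is invariant under any strictly increasing
#' transform of the scores.
#'
#' @param scores numeric vector of prediction scores.
#' @param labels 0/1 vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0L || N == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Classification metrics at a fixed specificity
#'
#' Chooses the smallest score cutoff whose true-negative rate reaches the
#' requested specificity, classifies `score > threshold` as positive, and
#' reports sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, accuracy
#' `(TN+TP)/(TN+TP+FN+FP)` and `F1 = 2*Pre*Sen/(Pre+Sen)`.  When no
#' positive call is made, precision and F1 are reported as 0 with a warning.
#'
#' @inheritParams auc_score
#' @param specificity target true-negative rate in `(0, 1)` (default 0.85,
#'   the usual operating point for this evaluation protocol).
#' @return one-row tibble: `threshold`, `specificity_achieved`, `sen`,
#'   `pre`, `acc`, `f1`.
#' @export
metrics_at_specificity <- function(scores, labels, specificity = 0.85) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (specificity <= 0 || specificity >= 1) {
    stop("specificity must be in (0, 1)")
  }
  neg <- sort(scores[labels == 0])
  pos <- scores[labels == 1]
  N <- length(neg)
  P <- length(pos)
  if (P == 0L || N == 0L) stop("both classes must be present")
  # smallest cutoff t with #(neg <= t) / N >= specificity
  threshold <- neg[ceiling(specificity * N)]
  TN <- sum(neg <= threshold)
  FP <- N - TN
  TP <- sum(pos > threshold)
  FN <- P - TP
  sen <- TP / (TP + FN)
  if (TP + FP == 0L) {
    warning("no positive calls at this specificity; precision and F1 set to 0")
    pre <- 0
    f1 <- 0
  } else {
    pre <- TP / (TP + FP)
    f1 <- if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen)
  }
  tibble::tibble(
    threshold = threshold,
    specificity_achieved = TN / N,
    sen = sen, pre = pre,
    acc = (TN + TP) / (TN + TP + FN + FP),
    f1 = f1
  )
}

#' Count known pairs recovered in each drug's top-ranked fraction
#'
#' For every drug the miRNAs are ranked by predicted score (descending, ties
#' by ascending column index) and the known associations falling inside the
#' top `ceiling(q * m)` ranks are counted; the total over drugs is returned.
#' Used with a model trained on all known associations to measure how much
#' of the training signal the completed matrix places at the top of each
#' drug's ranking.
#'
#' @param scores drug x miRNA score matrix.
#' @param Y binary association matrix of the same shape.
#' @param q top fraction in `(0, 1]` (e.g. 0.10, 0.15, 0.20).
#' @return integer count of recovered known pairs.
#' @export
top_fraction_recovery <- function(scores, Y, q) {
  stopifnot(all(dim(scores) == dim(Y)), q > 0, q <= 1)
  m <- ncol(scores)
  top <- ceiling(q * m)
  recovered <- 0L
  for (i in seq_len(nrow(scores))) {
    ord <- order(-scores[i, ], seq_len(m))
    recovered <- recovered + sum(unclass(Y)[i, ord[seq_len(top)]] == 1)
  }
  as.integer(recovered)
}

#' Ranked candidate miRNAs for one drug
#'
#' Sorts a drug's predicted scores in descending order (equal scores broken
#' by miRNA id, lexicographically, for determinism), optionally dropping the
#' drug's already-known miRNAs first.
#'
#' @param scores drug x miRNA score matrix with dimnames.
#' @param Y binary association matrix (used to flag/exclude known pairs).
#' @param drug_id drug to rank candidates for.
#' @param top_n number of candidates to return (default all).
#' @param exclude_known drop miRNAs already associated with the drug?
#' @return tibble with columns `rank`, `mirna_id`, `score`, `known`.
#' @export
rank_candidates <- function(scores, Y, drug_id, top_n = Inf,
                            exclude_known = TRUE) {
  if (!drug_id %in% rownames(scores)) {
    stop(sprintf("unknown drug id '%s'", drug_id))
  }
  s <- scores[drug_id, ]
  known <- unclass(Y)[drug_id, ] == 1
  out <- tibble::tibble(mirna_id = colnames(scores), score = unname(s),
                        known = unname(known))
  if (exclude_known) out <- out[!out$known, ]
  out <- out[order(-out$score, out$mirna_id), ]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "mirna_id", "score", "known")]
  if (is.finite(top_n)) out <- head(out, top_n)
  out
}

#' Fit the full prediction pipeline on one training matrix
#'
#' Convenience composition of the stages: optional nearest-known-neighbour
#' repair of `Y`, graph construction from the fused similarities, and the
#' regularized factorization.  Returns the fit together with the completed
#' score matrix.
#'
#' @param Y binary association matrix.
#' @param drug_sim,mirna_sim fused similarity matrices aligned with `Y`.
#' @param wknkn apply the nearest-known-neighbour repair first? (`FALSE`
#'   reproduces the ablated variant that factorizes the raw matrix.)
#' @param K,alpha repair parameters, see [wknkn_profiles()].
#' @param p graph neighbourhood size, see [build_graph()].
#' @param k,lam,beta,max_iter,tol,eps,seed solver settings, see [gnmf_fit()].
#' @return list of class `dma_fit`: `fit` (the [gnmf_fit()] object),
#'   `scores` (`t(W) %*% H`), `y_train` (the matrix actually factorized).
#' @export
dma_fit <- function(Y, drug_sim, mirna_sim, wknkn = TRUE, K = 3, alpha = 0.9,
                    p = 5, k = 35, lam = 1, beta = 0.02, max_iter = 1000,
                    tol = 1e-4, eps = 1e-12, seed = NULL) {
  Gd <- build_graph(drug_sim, p)
  Gm <- build_graph(mirna_sim, p)
  y_train <- if (wknkn) {
    wknkn_profiles(Y, drug_sim, mirna_sim, K = K, alpha = alpha)$y_new
  } else {
    unclass(Y)
  }
  fit <- gnmf_fit(y_train, Gd, Gm, k = k, lam = lam, beta = beta,
                  max_iter = max_iter, tol = tol, eps = eps, seed = seed)
  structure(list(fit = fit, scores = predict(fit), y_train = y_train),
            class = "dma_fit")
}

#' Cross-validated evaluation of the prediction pipeline
#'
#' The known pairs are split into folds ([make_folds()]).  For each fold its
#' positives are masked to 0 in a training copy of `Y`; the pipeline
#' (optional nearest-known-neighbour repair, then the regularized
#' factorization — similarity graphs are built once, since they do not
#' depend on `Y`) is fitted on the training copy only, so held-out labels
#' never reach the training stage.  Scores for the held-out positives are
#' then compared against the scores of all pairs that are zero in the *full*
#' known matrix (the conventional negative universe for association
#' prediction, where unknowns count as negatives): per-fold AUC and
#' fixed-specificity metrics are computed and aggregated as mean and
#' standard deviation; a pooled AUC over all folds' scores is also reported.
#'
#' @inheritParams dma_fit
#' @param n_folds number of folds (default 5).
#' @param cv_seed seed for the fold partition (kept separate from the
#'   factorization seed so either can be varied alone).
#' @param seed base seed for factor initialization; fold `f` uses
#'   `seed + f - 1`.
#' @param specificity operating point for the threshold metrics.
#' @return object of class `gnmf_cv`: list with `per_fold` (tibble of fold,
#'   auc, sen, pre, acc, f1, threshold, iterations, converged), `mean_auc`,
#'   `sd_auc`, `pooled_auc`, `folds` (the [make_folds()] object), `roc`
#'   (per-fold scores and labels) and `settings`.
#' @export
gnmf_cv <- function(Y, drug_sim, mirna_sim, wknkn = TRUE, K = 3, alpha = 0.9,
                    p = 5, k = 35, lam = 1, beta = 0.02, max_iter = 1000,
                    tol = 1e-4, eps = 1e-12, n_folds = 5, cv_seed = NULL,
                    seed = NULL, specificity = 0.85) {
  Gd <- build_graph(drug_sim, p)
  Gm <- build_graph(mirna_sim, p)
  folds <- make_folds(Y, n_folds, cv_seed)
  Yfull <- unclass(Y)
  neg_idx <- which(Yfull == 0)
  rows <- list()
  roc <- list()
  for (f in seq_len(n_folds)) {
    held <- folds[folds$fold == f, ]
    Ytr <- Yfull
    Ytr[cbind(held$row, held$col)] <- 0
    dimnames(Ytr) <- dimnames(Yfull)
    if (wknkn) {
      Ytr <- wknkn_profiles(Ytr, drug_sim, mirna_sim, K = K,
                            alpha = alpha)$y_new
    }
    fit <- gnmf_fit(Ytr, Gd, Gm, k = k, lam = lam, beta = beta,
                    max_iter = max_iter, tol = tol, eps = eps,
                    seed = if (is.null(seed)) NULL else seed + f - 1L)
    scores <- predict(fit)
    test_scores <- c(scores[cbind(held$row, held$col)], scores[neg_idx])
    test_labels <- c(rep(1, nrow(held)), rep(0, length(neg_idx)))
    met <- metrics_at_specificity(test_scores, test_labels, specificity)
    rows[[f]] <- tibble::tibble(
      fold = f,
      auc = auc_score(test_scores, test_labels),
      sen = met$sen, pre = met$pre, acc = met$acc, f1 = met$f1,
      threshold = met$threshold,
      iterations = fit$iterations, converged = fit$converged
    )
    roc[[f]] <- list(scores = test_scores, labels = test_labels)
  }
  per_fold <- do.call(rbind, rows)
  pooled <- auc_score(unlist(lapply(roc, `[[`, "scores")),
                      unlist(lapply(roc, `[[`, "labels")))
  structure(
    list(per_fold = per_fold,
         mean_auc = mean(per_fold$auc), sd_auc = sd(per_fold$auc),
         pooled_auc = pooled, folds = folds, roc = roc,
         settings = list(wknkn = wknkn, K = K, alpha = alpha, p = p, k = k,
                         lam = lam, beta = beta, max_iter = max_iter,
                         tol = tol, n_folds = n_folds, cv_seed = cv_seed,
                         seed = seed, specificity = specificity)),
    class = "gnmf_cv"
  )
}

#' @export
print.gnmf_cv <- function(x, ...) {
  cat(sprintf("<gnmf_cv> %d-fold CV%s: mean AUC %.4f +/- %.4f (pooled %.4f)\n",
              x$settings$n_folds,
              if (x$settings$wknkn) "" else " (no neighbour repair)",
              x$mean_auc, x$sd_auc, x$pooled_auc))
  print(x$per_fold)
  invisible(x)
}

#' Per-fold metrics of a cross-validation run
#'
#' @param x a `gnmf_cv` object.
#' @param ... unused.
#' @return tibble, one row per fold: `fold`, `auc`, `sen`, `pre`, `acc`,
#'   `f1`, `threshold`, `iterations`, `converged`.
#' @method tidy gnmf_cv
#' @export
tidy.gnmf_cv <- function(x, ...) x$per_fold

#' One-row summary of a cross-validation run
#'
#' @param x a `gnmf_cv` object.
#' @param ... unused.
#' @return one-row tibble with fold count, mean/sd AUC, pooled AUC and the
#'   mean threshold metrics.
#' @method glance gnmf_cv
#' @export
glance.gnmf_cv <- function(x, ...) {
  tibble::tibble(
    n_folds = x$settings$n_folds,
    mean_auc = x$mean_auc, sd_auc = x$sd_auc, pooled_auc = x$pooled_auc,
    mean_sen = mean(x$per_fold$sen), mean_pre = mean(x$per_fold$pre),
    mean_acc = mean(x$per_fold$acc), mean_f1 = mean(x$per_fold$f1)
  )
}

roc_points <- function(scores, labels) {
  ord <- order(-scores)
  labels <- labels[ord]
  tibble::tibble(
    fpr = c(0, cumsum(labels == 0) / sum(labels == 0)),
    tpr = c(0, cumsum(labels == 1) / sum(labels == 1))
  )
}

#' ROC curves of a cross-validation run
#'
#' One ROC curve per fold, with the chance diagonal for reference.
#'
#' @param object a `gnmf_cv` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gnmf_cv
#' @export
autoplot.gnmf_cv <- function(object, ...) {
  dfs <- lapply(seq_along(object$roc), function(f) {
    pts <- roc_points(object$roc[[f]]$scores, object$roc[[f]]$labels)
    pts$fold <- factor(f)
    pts
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$fold)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = "fold",
                  title = sprintf("mean AUC %.4f +/- %.4f",
                                  object$mean_auc, object$sd_auc))
}
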