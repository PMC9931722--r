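# Independent brute-force oracles used to pin down expected values.  Each is
# a straight-line transcription of the defining formula, sharing no code with
# the implementation it checks.

# random symmetric similarity matrix with unit diagonal
rand_sim <- function(n, ids = paste0("e", seq_len(n)),
                     kind = "fused_drug") {
  A <- matrix(runif(n * n), n, n)
  similarity_matrix((A + t(A)) / 2, ids = ids, kind = kind)
}

rand_assoc <- function(n, m, prob = 0.3) {
  Y <- matrix(rbinom(n * m, 1, prob), n, m)
  if (all(Y == 0)) Y[1, 1] <- 1
  association_matrix(Y, paste0("d", seq_len(n)), paste0("m", seq_len(m)))
}

# weighted K-nearest-known-neighbour profiles, element by element
oracle_wknkn <- function(Y, SD, SM, K, alpha) {
  Y <- unclass(Y); SD <- unclass(SD); SM <- unclass(SM)
  n <- nrow(Y); m <- ncol(Y)
  Yd <- matrix(0, n, m)
  for (l in seq_len(n)) {
    others <- setdiff(seq_len(n), l)
    others <- others[rowSums(Y)[others] > 0]
    if (length(others) == 0L) next
    ord <- others[order(-SD[others, l], others)]
    use <- ord[seq_len(min(K, length(ord)))]
    den <- sum(SD[use, l])
    if (den <= 0) next
    acc <- rep(0, m)
    for (i in seq_along(use)) {
      acc <- acc + alpha^(i - 1) * SD[use[i], l] * Y[use[i], ]
    }
    Yd[l, ] <- acc / den
  }
  Ym <- matrix(0, n, m)
  for (q in seq_len(m)) {
    others <- setdiff(seq_len(m), q)
    others <- others[colSums(Y)[others] > 0]
    if (length(others) == 0L) next
    ord <- others[order(-SM[others, q], others)]
    use <- ord[seq_len(min(K, length(ord)))]
    den <- sum(SM[use, q])
    if (den <= 0) next
    acc <- rep(0, n)
    for (j in seq_along(use)) {
      acc <- acc + alpha^(j - 1) * SM[use[j], q] * Y[, use[j]]
    }
    Ym[, q] <- acc / den
  }
  pmax(Y, pmin((Yd + Ym) / 2, 1))
}

# mutual / one-sided / non-neighbour mask by explicit set construction
oracle_knn_mask <- function(S, p) {
  S <- unclass(S)
  n <- nrow(S)
  np <- lapply(seq_len(n), function(i) {
    cand <- setdiff(seq_len(n), i)
    cand[order(-S[cand, i], cand)][seq_len(p)]
  })
  G <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        G[i, j] <- 1
      } else {
        in_j <- i %in% np[[j]]
        in_i <- j %in% np[[i]]
        G[i, j] <- if (in_j && in_i) 1 else if (!in_j && !in_i) 0 else 0.5
      }
    }
  }
  G
}

# degree and Laplacian by an explicit double loop over entries
oracle_laplacian <- function(Sstar) {
  n <- nrow(Sstar)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (l in seq_len(n)) D[i, i] <- D[i, i] + Sstar[i, l]
  }
  list(degree = diag(D), laplacian = D - Sstar)
}

# pairwise-difference form of the regularized objective:
# ||Y - W'H||_F^2 + lam * sum_{i<=j} S*_ij ||w_i - w_j||^2 (both spaces)
#   + beta * (||W||^2 + ||H||^2)
oracle_objective_pairwise <- function(Y, W, H, Sd, Sm, lam, beta) {
  recon <- 0
  for (i in seq_len(nrow(Y))) {
    for (j in seq_len(ncol(Y))) {
      recon <- recon + (Y[i, j] - sum(W[, i] * H[, j]))^2
    }
  }
  rd <- 0
  for (i in seq_len(ncol(W))) {
    for (j in seq_len(ncol(W))) {
      rd <- rd + sum((W[, i] - W[, j])^2) * Sd[i, j]
    }
  }
  rd <- rd / 2
  rm_ <- 0
  for (i in seq_len(ncol(H))) {
    for (j in seq_len(ncol(H))) {
      rm_ <- rm_ + sum((H[, i] - H[, j])^2) * Sm[i, j]
    }
  }
  rm_ <- rm_ / 2
  recon + lam * (rd + rm_) + beta * (sum(W^2) + sum(H^2))
}

# classical multiplicative-update NMF (A ~ U V, U = t(W), V = H), written in
# the conventional orientation; sequential U-then-V sweep
oracle_classical_nmf <- function(A, U, V, iters) {
  for (t in seq_len(iters)) {
    U <- U * (A %*% t(V)) / (U %*% V %*% t(V))
    V <- V * (t(U) %*% A) / (t(U) %*% U %*% V)
  }
  list(U = U, V = V)
}

# AUC as the explicit average over positive x negative pairs, ties = 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}
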