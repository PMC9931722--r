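#' Generate a synthetic drug-miRNA benchmark dataset
#'
#' Produces data with the statistical structure the prediction model
#' assumes: a low-rank non-negative association signal and similarity
#' matrices correlated with the latent factors.  Latent factors `W0`
#' (`r x n`) and `H0` (`r x m`) are drawn with i.i.d. squared-normal entries
#' — non-negative and heavy-tailed, so the top-quantile thresholding below
#' yields the skewed per-drug association counts seen in curated association
#' data rather than a flat degree distribution.  The truth matrix is
#' `t(W0) %*% H0`; the binary association matrix marks its
#' `round(density * n * m)` largest entries.  Each similarity matrix is the
#' cosine similarity of the latent factor columns blended with an
#' independent symmetric uniform noise matrix at mixing weight `noise`
#' (diagonal forced to 1), so the four drug views and two miRNA views are
#' independently corrupted looks at the same factor geometry — at
#' `noise = 0` the views coincide, at `noise = 1` they carry no factor
#' information.
#'
#' The defaults mirror the scale of the curated reference corpus this class
#' of model is applied to: tens of drugs, a few hundred miRNAs, and an
#' association density of about 6%.
#'
#' @param n number of drugs (default 40).
#' @param m number of miRNAs (default 300).
#' @param r planted rank, `r < min(n, m)` (default 5).
#' @param density fraction of pairs marked as associated, in `(0, 0.5)`
#'   (default 0.06).
#' @param noise similarity corruption weight in `[0, 1]` (default 0.2).
#' @param seed integer seed; the dataset is a deterministic function of it.
#' @return object of class `dma_dataset`: list with `assoc` (binary
#'   association matrix), `drug_sims` (4 similarity matrices: chemical,
#'   phenotype, side-effect, gene views), `mirna_sims` (2: phenotype, gene),
#'   `truth` (latent score matrix), `w0`/`h0` (the planted factors),
#'   `rank`, `seed`, `params`.
#' @export
generate_dataset <- function(n = 40, m = 300, r = 5, density = 0.06,
                             noise = 0.2, seed = NULL) {
  if (r >= min(n, m)) stop("r must be smaller than min(n, m)")
  if (density <= 0 || density >= 0.5) stop("density must be in (0, 0.5)")
  if (noise < 0 || noise > 1) stop("noise must be in [0, 1]")
  drug_ids <- sprintf("drug%03d", seq_len(n))
  mirna_ids <- sprintf("mir%04d", seq_len(m))
  ds <- with_rng_seed(seed, {
    W0 <- matrix(rnorm(r * n)^2, r, n)
    H0 <- matrix(rnorm(r * m)^2, r, m)
    truth <- crossprod(W0, H0)
    n_pos <- round(density * n * m)
    cutoff <- sort(truth, decreasing = TRUE)[n_pos]
    Y <- matrix(as.numeric(truth >= cutoff), n, m)
    Cd <- cosine_columns(W0)
    Cm <- cosine_columns(H0)
    drug_kinds <- c("drug_chemical", "drug_phenotype", "drug_side_effect",
                    "drug_gene")
    mirna_kinds <- c("mirna_phenotype", "mirna_gene")
    drug_sims <- lapply(drug_kinds, function(kind) {
      similarity_matrix(blend_noise(Cd, noise), ids = drug_ids, kind = kind)
    })
    names(drug_sims) <- drug_kinds
    mirna_sims <- lapply(mirna_kinds, function(kind) {
      similarity_matrix(blend_noise(Cm, noise), ids = mirna_ids, kind = kind)
    })
    names(mirna_sims) <- mirna_kinds
    dimnames(truth) <- list(drug_ids, mirna_ids)
    colnames(W0) <- drug_ids
    colnames(H0) <- mirna_ids
    list(
      assoc = association_matrix(Y, drug_ids, mirna_ids),
      drug_sims = drug_sims, mirna_sims = mirna_sims, truth = truth,
      w0 = W0, h0 = H0
    )
  })
  structure(
    c(ds, list(rank = as.integer(r), seed = seed,
               params = list(n = as.integer(n), m = as.integer(m),
                             r = as.integer(r), density = as.numeric(density),
                             noise = as.numeric(noise)))),
    class = "dma_dataset"
  )
}

# Cosine similarity between the columns of X (values in [0, 1] for
# non-negative X).
cosine_columns <- function(X) {
  cp <- crossprod(X)
  nrm <- sqrt(diag(cp))
  nrm[nrm == 0] <- 1
  cp / outer(nrm, nrm)
}

# Mix a similarity matrix with an independent symmetric uniform noise
# matrix; unit diagonal, clipped to [0, 1].
blend_noise <- function(C, noise) {
  n <- nrow(C)
  A <- matrix(runif(n * n), n, n)
  S <- (1 - noise) * C + noise * (A + t(A)) / 2
  diag(S) <- 1
  pmin(pmax(S, 0), 1)
}

#' Fused similarities of a synthetic dataset
#'
#' Unit-weight fusion of the dataset's per-source drug and miRNA
#' similarity views (see [fuse_similarities()]).
#'
#' @param ds a [generate_dataset()] object.
#' @return list with elements `drug` and `mirna`, the fused matrices.
#' @export
fuse_dataset <- function(ds) {
  list(
    drug = fuse_similarities(unname(ds$drug_sims), kind = "fused_drug"),
    mirna = fuse_similarities(unname(ds$mirna_sims), kind = "fused_mirna")
  )
}

#' @export
print.dma_dataset <- function(x, ...) {
  cat(sprintf(
    "<dma_dataset> %d drugs x %d miRNAs, rank %d, %d associations (%.2f%%), noise %g, seed %s\n",
    x$params$n, x$params$m, x$rank, sum(x$assoc),
    100 * mean(x$assoc), x$params$noise,
    if (is.null(x$seed)) "none" else x$seed
  ))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' All matrices are written in the dense labelled delimited format
#' ([write_matrix_tsv()]) together with a `manifest.yaml` recording every
#' generator parameter and the seed, so the dataset can be reproduced
#' bit-identically or reloaded with [read_dataset()].
#'
#' @param ds a [generate_dataset()] object.
#' @param dir destination directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    assoc = file.path(dir, "assoc.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_matrix_tsv(ds$assoc, paths[["assoc"]])
  write_matrix_tsv(ds$truth, paths[["truth"]])
  for (kind in names(ds$drug_sims)) {
    p <- file.path(dir, paste0(kind, ".tsv"))
    write_matrix_tsv(ds$drug_sims[[kind]], p)
    paths[[kind]] <- p
  }
  for (kind in names(ds$mirna_sims)) {
    p <- file.path(dir, paste0(kind, ".tsv"))
    write_matrix_tsv(ds$mirna_sims[[kind]], p)
    paths[[kind]] <- p
  }
  manifest <- file.path(dir, "manifest.yaml")
  writeLines(c(
    sprintf("n: %d", ds$params$n),
    sprintf("m: %d", ds$params$m),
    sprintf("r: %d", ds$params$r),
    sprintf("density: %.17g", ds$params$density),
    sprintf("noise: %.17g", ds$params$noise),
    sprintf("seed: %s", if (is.null(ds$seed)) "null" else ds$seed)
  ), manifest)
  paths[["manifest"]] <- manifest
  invisible(paths)
}

#' Reload a synthetic dataset written by [write_dataset()]
#'
#' @param dir directory containing the files and `manifest.yaml`.
#' @return a `dma_dataset` object (the `truth` matrix is reloaded from
#'   disk; factors themselves are not stored).
#' @export
read_dataset <- function(dir) {
  manifest <- file.path(dir, "manifest.yaml")
  if (!file.exists(manifest)) stop("manifest.yaml not found in ", dir)
  kv <- strsplit(readLines(manifest), ": ", fixed = TRUE)
  params <- setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  seed <- if (identical(params$seed, "null")) NULL else as.integer(params$seed)
  assoc <- read_association_matrix(file.path(dir, "assoc.tsv"), "dense")
  truth <- as.matrix(read.table(file.path(dir, "truth.tsv"), sep = "\t",
                                header = TRUE, row.names = 1L,
                                check.names = FALSE))
  drug_kinds <- c("drug_chemical", "drug_phenotype", "drug_side_effect",
                  "drug_gene")
  mirna_kinds <- c("mirna_phenotype", "mirna_gene")
  drug_sims <- setNames(lapply(drug_kinds, function(kind) {
    read_similarity_matrix(file.path(dir, paste0(kind, ".tsv")), kind = kind)
  }), drug_kinds)
  mirna_sims <- setNames(lapply(mirna_kinds, function(kind) {
    read_similarity_matrix(file.path(dir, paste0(kind, ".tsv")), kind = kind)
  }), mirna_kinds)
  structure(
    list(assoc = assoc, drug_sims = drug_sims, mirna_sims = mirna_sims,
         truth = truth, rank = as.integer(params$r), seed = seed,
         params = list(n = as.integer(params$n), m = as.integer(params$m),
                       r = as.integer(params$r),
                       density = as.numeric(params$density),
                       noise = as.numeric(params$noise))),
    class = "dma_dataset"
  )
}
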