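#' @importFrom stats sd setNames runif rnorm
#' @importFrom utils read.table write.table head
NULL

SIM_KINDS <- c(
  "drug_chemical", "drug_phenotype", "drug_side_effect", "drug_gene",
  "mirna_phenotype", "mirna_gene", "fused_drug", "fused_mirna"
)

#' Construct a labelled drug-miRNA association matrix
#'
#' Validates and labels a drug x miRNA association matrix.  On ingest the
#' matrix is binary (1 = experimentally supported association, 0 = unknown);
#' after nearest-known-neighbour repair (see [wknkn_profiles()]) entries are
#' real-valued likelihoods in `[0, 1]`.
#'
#' @param values numeric matrix, drugs in rows, miRNAs in columns.
#' @param drug_ids,mirna_ids character vectors of unique identifiers; default
#'   to the dimnames of `values`.
#' @param binary if `TRUE` (the ingest contract) every entry must be exactly
#'   0 or 1; if `FALSE` entries may be any finite value in `[0, 1]`.
#' @return the validated matrix with `drug_ids` as rownames and `mirna_ids`
#'   as colnames.
#' @export
association_matrix <- function(values, drug_ids = rownames(values),
                               mirna_ids = colnames(values), binary = TRUE) {
  values <- as.matrix(values)
  if (length(values) == 0L) {
    stop("association matrix is empty")
  }
  if (is.null(drug_ids) || is.null(mirna_ids)) {
    stop("association matrix requires drug and miRNA identifiers")
  }
  drug_ids <- as.character(drug_ids)
  mirna_ids <- as.character(mirna_ids)
  if (length(drug_ids) != nrow(values) || length(mirna_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  check_unique_ids(drug_ids, "drug")
  check_unique_ids(mirna_ids, "miRNA")
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) {
    stop("association matrix contains non-finite values")
  }
  if (binary) {
    bad <- which(values != 0 & values != 1, arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf(
        "non-binary association value %g at drug '%s', miRNA '%s'",
        values[bad[1, 1], bad[1, 2]], drug_ids[bad[1, 1]], mirna_ids[bad[1, 2]]
      ))
    }
  } else if (any(values < 0 | values > 1)) {
    stop("association values must lie in [0, 1]")
  }
  dimnames(values) <- list(drug_ids, mirna_ids)
  values
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf(
      "duplicate %s identifier(s): %s", what,
      paste(head(dup, 5L), collapse = ", ")
    ))
  }
  invisible(ids)
}

#' Construct a labelled similarity matrix
#'
#' A square symmetric matrix of pairwise similarities in `[0, 1]` over one
#' entity type (drugs or miRNAs).  Self-similarity is defined as 1: all the
#' similarity measures the pipeline consumes (chemical structure, indication
#' phenotype, side effect, gene functional consistency) are reflexive, so the
#' diagonal is forced to 1 at construction.
#'
#' @param values square numeric matrix.
#' @param ids character identifiers for rows/columns; default rownames.
#' @param kind one of `r paste0('"', SIM_KINDS, '"', collapse = ", ")`.
#' @param sym_tol maximum admissible row/column asymmetry; larger asymmetry
#'   is an error, smaller is symmetrized as `(S + t(S)) / 2`.
#' @param clip_tol maximum admissible excursion outside `[0, 1]` (numeric
#'   drift is clipped, real violations are errors).
#' @return validated symmetric matrix with unit diagonal, ids as dimnames and
#'   a `"kind"` attribute.
#' @export
similarity_matrix <- function(values, ids = rownames(values), kind = "fused_drug",
                              sym_tol = 1e-6, clip_tol = 1e-9) {
  kind <- match.arg(kind, SIM_KINDS)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop(sprintf("similarity matrix must be square, got %d x %d",
                 nrow(values), ncol(values)))
  }
  if (length(values) == 0L) stop("similarity matrix is empty")
  if (is.null(ids)) stop("similarity matrix requires entity identifiers")
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) {
    stop("identifier length does not match matrix dimension")
  }
  check_unique_ids(ids, "entity")
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("similarity matrix contains non-finite values")
  asym <- max(abs(values - t(values)))
  if (asym > sym_tol) {
    stop(sprintf("similarity matrix asymmetry %.3g exceeds tolerance %.1g",
                 asym, sym_tol))
  }
  values <- (values + t(values)) / 2
  excursion <- max(0, max(values) - 1, -min(values))
  if (excursion > clip_tol) {
    stop(sprintf("similarity values outside [0, 1] by %.3g", excursion))
  }
  values[values < 0] <- 0
  values[values > 1] <- 1
  diag(values) <- 1
  dimnames(values) <- list(ids, ids)
  attr(values, "kind") <- kind
  values
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

#' Read a drug-miRNA association matrix from disk
#'
#' Two on-disk representations are supported.  `dense`: delimited text with
#' miRNA ids as the header row and drug ids in the first column.  `edge_list`:
#' two columns `(drug_id, mirna_id)`, one association per row; duplicates
#' collapse to a single 1 and the entity universe is taken from the rows in
#' first-appearance order unless explicit id vectors are supplied.
#'
#' @param path file path.
#' @param format `"dense"` or `"edge_list"`.
#' @param delim field delimiter; `NULL` auto-detects tab/comma/whitespace.
#' @param drug_ids,mirna_ids optional explicit entity universes for edge
#'   lists (rows referencing unknown ids are an error).
#' @param header does the edge list carry a header row?
#' @return a validated binary association matrix (see [association_matrix()]).
#' @export
read_association_matrix <- function(path, format = c("dense", "edge_list"),
                                    delim = NULL, drug_ids = NULL,
                                    mirna_ids = NULL, header = FALSE) {
  format <- match.arg(format)
  if (is.null(delim)) delim <- detect_delim(path)
  if (format == "dense") {
    df <- read.table(path, sep = delim, header = TRUE, row.names = 1L,
                     check.names = FALSE, stringsAsFactors = FALSE)
    return(association_matrix(as.matrix(df)))
  }
  df <- read.table(path, sep = delim, header = header,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("edge list must have two columns (drug_id, mirna_id)")
  d <- df[[1L]]
  m <- df[[2L]]
  if (is.null(drug_ids)) drug_ids <- unique(d)
  if (is.null(mirna_ids)) mirna_ids <- unique(m)
  bad_d <- setdiff(d, drug_ids)
  bad_m <- setdiff(m, mirna_ids)
  if (length(bad_d) || length(bad_m)) {
    stop(sprintf("edge list references unknown ids: %s",
                 paste(head(c(bad_d, bad_m), 5L), collapse = ", ")))
  }
  Y <- matrix(0, length(drug_ids), length(mirna_ids),
              dimnames = list(drug_ids, mirna_ids))
  Y[cbind(match(d, drug_ids), match(m, mirna_ids))] <- 1
  association_matrix(Y)
}

#' Read a similarity matrix from disk
#'
#' Dense labelled delimited text (header row and first column of entity ids).
#' Mild asymmetry (at most `1e-6`) is symmetrized, the diagonal is forced to
#' 1, and values are clipped to `[0, 1]` only when the excursion is numeric
#' drift (at most `1e-9`).
#'
#' @inheritParams read_association_matrix
#' @param kind similarity kind tag, see [similarity_matrix()].
#' @param ids optional reference identifier list; a mismatch is an error
#'   naming the missing/extra ids (the factorization needs full similarity
#'   support for every entity, so absent entities are never imputed).
#' @return a validated similarity matrix.
#' @export
read_similarity_matrix <- function(path, kind = "fused_drug", delim = NULL,
                                   ids = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  df <- read.table(path, sep = delim, header = TRUE, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  S <- similarity_matrix(as.matrix(df), kind = kind)
  if (!is.null(ids)) {
    ids <- as.character(ids)
    missing <- setdiff(ids, rownames(S))
    extra <- setdiff(rownames(S), ids)
    if (length(missing) || length(extra)) {
      stop(sprintf(
        "similarity ids do not match reference: missing [%s], extra [%s]",
        paste(head(missing, 5L), collapse = ", "),
        paste(head(extra, 5L), collapse = ", ")
      ))
    }
    S <- similarity_matrix(S[ids, ids, drop = FALSE], kind = kind)
  }
  S
}

#' Write a labelled matrix as delimited text
#'
#' Dense labelled format: header row of column ids, first column of row ids.
#' The written file round-trips through [read_association_matrix()] /
#' [read_similarity_matrix()].
#'
#' @param x labelled numeric matrix.
#' @param path destination file.
#' @param delim field delimiter (tab by default).
#' @export
write_matrix_tsv <- function(x, path, delim = "\t") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate a score matrix as ranked predictions
#'
#' Flattens a drug x miRNA score matrix into a tibble of
#' `(drug_id, mirna_id, score)` sorted by score descending (ties broken by
#' drug then miRNA id for determinism), optionally dropping pairs already
#' known in `Y`.
#'
#' @param scores drug x miRNA numeric matrix with dimnames.
#' @param Y optional binary association matrix; known pairs (`Y == 1`) are
#'   dropped when supplied.
#' @return a tibble with columns `drug_id`, `mirna_id`, `score`.
#' @export
score_table <- function(scores, Y = NULL) {
  stopifnot(is.matrix(scores), !is.null(dimnames(scores)))
  out <- tibble::tibble(
    drug_id = rep(rownames(scores), times = ncol(scores)),
    mirna_id = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores)
  )
  if (!is.null(Y)) {
    stopifnot(all(dim(Y) == dim(scores)))
    out <- out[as.vector(Y[rownames(scores), colnames(scores)]) == 0, ]
  }
  out[order(-out$score, out$drug_id, out$mirna_id), ]
}
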