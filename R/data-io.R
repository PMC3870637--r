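#' Expression dataset
#'
#' Container for an n samples x p genes expression matrix with binary
#' class labels.  `Y[i] = 1` marks a case (e.g. tumour) sample and
#' `Y[i] = 0` a control.
#'
#' @param X numeric matrix, n samples x p genes.
#' @param Y binary vector of length n (values in \{0, 1\}).
#' @param gene_ids character vector of p unique gene identifiers.
#' @param sample_ids character vector of n sample identifiers.
#' @return An object of class `expr_data`: a list with elements `X`,
#'   `Y`, `gene_ids`, `sample_ids`.
#' @export
expr_data <- function(X, Y, gene_ids = NULL, sample_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (n < 2L || p < 1L) stop("need at least 2 samples and 1 gene")
  if (is.null(gene_ids)) gene_ids <- colnames(X)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- rownames(X)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  gene_ids <- as.character(gene_ids); sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != p) stop("gene_ids length must equal ncol(X)")
  if (length(sample_ids) != n) stop("sample_ids length must equal nrow(X)")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ID: ",
                                    gene_ids[duplicated(gene_ids)][1L])
  Y <- as.integer(Y)
  if (length(Y) != n) stop("Y length must equal nrow(X)")
  if (!all(Y %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (anyNA(X) || any(!is.finite(X))) stop("X contains missing or non-finite values")
  dimnames(X) <- list(sample_ids, gene_ids)
  structure(list(X = X, Y = Y, gene_ids = gene_ids, sample_ids = sample_ids),
            class = "expr_data")
}

#' @export
print.expr_data <- function(x, ...) {
  cat(sprintf("expr_data: %d samples x %d genes (%d cases, %d controls)\n",
              nrow(x$X), ncol(x$X), sum(x$Y == 1L), sum(x$Y == 0L)))
  invisible(x)
}

#' @export
dim.expr_data <- function(x) dim(x$X)

#' Subset an expression dataset
#'
#' @param ds an [expr_data] object.
#' @param samples,genes index vectors (integer, logical or character ID).
#' @return A new `expr_data` restricted to the requested rows/columns.
#' @export
subset_expr <- function(ds, samples = NULL, genes = NULL) {
  X <- ds$X; Y <- ds$Y
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, ds$sample_ids)
    X <- X[samples, , drop = FALSE]; Y <- Y[samples]
  }
  if (!is.null(genes)) {
    if (is.character(genes)) genes <- match(genes, ds$gene_ids)
    X <- X[, genes, drop = FALSE]
  }
  expr_data(X, Y, colnames(X), rownames(X))
}

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix and class labels from delimited text
#'
#' The expression file must have one header row and one leading ID
#' column.  The labels file has two columns, `sample_id` and `label`
#' (0/1); samples are matched to labels by ID, never by position.
#'
#' @param expr_path path to the TSV/CSV expression matrix.
#' @param labels_path path to the two-column TSV/CSV labels file.
#' @param orientation `"genes_by_samples"` (rows are genes; the common
#'   microarray layout, the default) or `"samples_by_genes"`.
#' @return An [expr_data] object in samples x genes orientation.
#' @export
read_expression <- function(expr_path, labels_path,
                            orientation = c("genes_by_samples", "samples_by_genes")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(expr_path, sep = delim_for(expr_path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  M <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric cell in expression matrix")
  storage.mode(M) <- "double"
  if (anyNA(M)) stop("non-numeric or missing cell in expression matrix")
  rownames(M) <- ids
  if (orientation == "genes_by_samples") M <- t(M)
  if (anyDuplicated(colnames(M))) {
    stop("duplicate gene ID: ", colnames(M)[duplicated(colnames(M))][1L])
  }
  lab <- utils::read.delim(labels_path, sep = delim_for(labels_path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(lab) < 2L) stop("labels file needs columns (sample_id, label)")
  lab_ids <- as.character(lab[[1L]])
  lab_val <- lab[[2L]]
  if (!all(lab_val %in% c(0, 1))) stop("label value outside {0, 1}")
  miss <- setdiff(lab_ids, rownames(M))
  if (length(miss)) stop("unknown sample ID in labels: ", miss[1L])
  miss2 <- setdiff(rownames(M), lab_ids)
  if (length(miss2)) stop("sample without label: ", miss2[1L])
  Y <- as.integer(lab_val[match(rownames(M), lab_ids)])
  expr_data(M, Y, colnames(M), rownames(M))
}

#' Write an expression dataset to delimited text
#'
#' Writes the matrix (genes by samples by default, mirroring
#' [read_expression]) and, optionally, the labels file.
#'
#' @param ds an [expr_data] object.
#' @param expr_path output path for the expression matrix.
#' @param labels_path optional output path for the labels file.
#' @param orientation layout of the written matrix.
#' @return Invisibly, `expr_path`.
#' @export
write_expression <- function(ds, expr_path, labels_path = NULL,
                             orientation = c("genes_by_samples", "samples_by_genes")) {
  orientation <- match.arg(orientation)
  sep <- delim_for(expr_path)
  M <- if (orientation == "genes_by_samples") t(ds$X) else ds$X
  df <- data.frame(id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    utils::write.table(data.frame(sample_id = ds$sample_ids, label = ds$Y),
                       labels_path, sep = delim_for(labels_path),
                       quote = FALSE, row.names = FALSE)
  }
  invisible(expr_path)
}

#' Preprocess expression values: threshold, filter, log10, standardize
#'
#' Reproduces the classic oligonucleotide-array preprocessing: raw
#' intensities are optionally clipped to `[floor, ceil]`; genes are kept
#' only when `max/min >= min_fold` and `max - min >= min_diff`; the
#' surviving values are log10-transformed and each gene is standardized
#' to zero mean and unit (sample, n-1 denominator) variance across
#' samples.  Genes with zero variance are dropped with a warning.
#'
#' @param ds an [expr_data] object with strictly positive values (after
#'   flooring) so the log is defined.
#' @param do_threshold_filter apply the clipping/filter step?
#' @param floor,ceil clipping bounds for raw intensities.
#' @param min_fold,min_diff fold-change and absolute-difference filters.
#' @param log10_transform apply the base-10 log?
#' @param standardize per-gene standardization across samples?
#' @return A new [expr_data] with filtered, transformed columns.
#' @export
preprocess_expr <- function(ds, do_threshold_filter = FALSE,
                            floor = 100, ceil = 16000,
                            min_fold = 5, min_diff = 500,
                            log10_transform = TRUE, standardize = TRUE) {
  X <- ds$X
  if (do_threshold_filter) {
    X[X < floor] <- floor
    X[X > ceil] <- ceil
    mx <- apply(X, 2L, max)
    mn <- apply(X, 2L, min)
    keep <- (mx / mn >= min_fold) & (mx - mn >= min_diff)
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) < 1L) stop("no genes survive filtering")
  if (log10_transform) {
    if (any(X <= 0)) stop("non-positive value entering log10")
    X <- log10(X)
  }
  if (standardize) {
    v <- apply(X, 2L, stats::var)
    zero <- v <= .Machine$double.eps * 100
    if (any(zero)) {
      warning(sum(zero), " zero-variance gene(s) dropped before standardization")
      X <- X[, !zero, drop = FALSE]
      if (ncol(X) < 1L) stop("no genes survive filtering")
    }
    X <- scale(X)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
  }
  expr_data(X, ds$Y, colnames(X), ds$sample_ids)
}

#' Two-sample pooled t-statistics per gene
#'
#' @param ds an [expr_data] object; both classes need at least 2 samples.
#' @return Numeric vector of length p (class 1 mean minus class 0 mean,
#'   pooled-variance denominator).  A gene with zero pooled variance gets
#'   t = 0 when the class means agree and +/-Inf otherwise.
#' @export
gene_t_statistics <- function(ds) {
  g1 <- ds$Y == 1L; g0 <- ds$Y == 0L
  n1 <- sum(g1); n0 <- sum(g0)
  if (n1 < 2L || n0 < 2L) stop("each class needs at least 2 samples")
  m1 <- colMeans(ds$X[g1, , drop = FALSE])
  m0 <- colMeans(ds$X[g0, , drop = FALSE])
  v1 <- apply(ds$X[g1, , drop = FALSE], 2L, stats::var)
  v0 <- apply(ds$X[g0, , drop = FALSE], 2L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  d <- m1 - m0
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  names(t) <- ds$gene_ids
  t
}

#' Rank genes by absolute t-statistic and keep the top k
#'
#' The marginal screen used to form the starting gene set before the
#' Bayesian search.  Ties in |t| are broken by original gene index.
#'
#' @param ds an [expr_data] object.
#' @param k number of genes to retain (`k <= p`).
#' @return Integer vector of k gene indices, |t|-descending.
#' @export
t_prescreen <- function(ds, k) {
  p <- ncol(ds$X)
  if (k > p) stop("k must not exceed the number of genes")
  t <- gene_t_statistics(ds)
  ord <- order(-abs(t), seq_len(p))
  ord[seq_len(k)]
}

#' Write a gene ranking as TSV
#'
#' Columns: rank, gene_id, and the ranking statistic.
#'
#' @param ranking a data.frame from [inclusion_probabilities], or any
#'   data.frame with `gene_id` plus a statistic column.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
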