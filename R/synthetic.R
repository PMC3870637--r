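#' Specification of a synthetic probit dataset
#'
#' Describes the generative recipe used by [generate_synthetic]: a
#' sparse-support latent probit model `Z = alpha + X beta + eps`,
#' `Y = 1{Z > 0}`, with standard-normal (optionally block-correlated)
#' expression values.  The default design mirrors the simulation study
#' the method is benchmarked on: 500 genes of which 15 carry signal,
#' 200 training and 40 testing samples.
#'
#' @param n_train,n_test sample sizes.
#' @param p number of genes.
#' @param true_support indices of the signal genes; default the first
#'   `k` indices spread evenly across 1..p.
#' @param k number of signal genes (used when `true_support` is NULL).
#' @param beta_true effect sizes for the support; default alternating
#'   +1/-1 (strong, balanced signal).
#' @param alpha_true intercept; default 0 (balanced classes).
#' @param correlation within-block correlation in [0, 0.95]; signal
#'   genes each head a block of `block_size` correlated genes.
#' @param block_size block width when `correlation > 0`.
#' @param seed integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_train = 200, n_test = 40, p = 500,
                       true_support = NULL, k = 15,
                       beta_true = NULL, alpha_true = 0,
                       correlation = 0, block_size = 5, seed = 1) {
  if (is.null(true_support)) {
    true_support <- unique(round(seq(1, p, length.out = k)))
  }
  true_support <- sort(as.integer(true_support))
  k <- length(true_support)
  if (anyDuplicated(true_support)) stop("true_support indices must be distinct")
  if (k > p || any(true_support < 1L) || any(true_support > p)) {
    stop("true_support must lie in 1..p")
  }
  if (is.null(beta_true)) beta_true <- rep_len(c(1, -1), k)
  if (length(beta_true) != k) stop("beta_true must match the support size")
  if (correlation < 0 || correlation > 0.95) stop("correlation must be in [0, 0.95]")
  structure(list(n_train = n_train, n_test = n_test, p = p,
                 true_support = true_support, beta_true = beta_true,
                 alpha_true = alpha_true, correlation = correlation,
                 block_size = block_size, seed = as.integer(seed)),
            class = "synth_spec")
}

draw_probit_data <- function(spec, n, ids_prefix) {
  p <- spec$p
  X <- matrix(stats::rnorm(n * p), n, p)
  if (spec$correlation > 0) {
    # signal gene j heads a block of block_size genes sharing a factor
    rho <- spec$correlation
    for (j in spec$true_support) {
      block <- j:min(j + spec$block_size - 1L, p)
      f <- X[, j]
      for (b in setdiff(block, j)) {
        X[, b] <- sqrt(rho) * f + sqrt(1 - rho) * X[, b]
      }
    }
  }
  beta <- numeric(p)
  beta[spec$true_support] <- spec$beta_true
  Z <- spec$alpha_true + drop(X %*% beta) + stats::rnorm(n)
  Y <- as.integer(Z > 0)
  list(X = X, Y = Y, Z = Z,
       ids = paste0(ids_prefix, seq_len(n)))
}

#' Generate a synthetic probit dataset with known sparse support
#'
#' Draws training and test sets from the latent probit law described by
#' the [synth_spec]; the generated labels satisfy `Y = 1{Z > 0}`
#' exactly.  If either set comes out single-class, the whole dataset is
#' re-drawn (up to 100 attempts) before erroring.
#'
#' @param spec a [synth_spec].
#' @return List with `train` and `test` ([expr_data] objects; `test` is
#'   NULL when `n_test = 0`) and `truth` (support, effects, intercept,
#'   latent draws, seed, attempt count).
#' @export
generate_synthetic <- function(spec) {
  set.seed(spec$seed)
  gene_ids <- paste0("g", seq_len(spec$p))
  for (attempt in seq_len(100L)) {
    tr <- draw_probit_data(spec, spec$n_train, "train")
    te <- if (spec$n_test > 0) draw_probit_data(spec, spec$n_test, "test") else NULL
    ok <- length(unique(tr$Y)) == 2L &&
      (is.null(te) || length(unique(te$Y)) == 2L)
    if (ok) {
      train <- expr_data(tr$X, tr$Y, gene_ids, tr$ids)
      test <- if (!is.null(te)) expr_data(te$X, te$Y, gene_ids, te$ids)
      truth <- list(support = spec$true_support, beta = spec$beta_true,
                    alpha = spec$alpha_true, Z_train = tr$Z,
                    Z_test = if (!is.null(te)) te$Z,
                    seed = spec$seed, attempts = attempt)
      return(list(train = train, test = test, truth = truth))
    }
  }
  stop("degenerate specification: one class empty after 100 attempts")
}

#' Frozen tiny test instance
#'
#' A fixed n = 4, p = 3 dataset used by the enumeration and quadrature
#' oracles.  The third column is twice the first, so the design is
#' deliberately rank-deficient (rank 2) to exercise the pseudoinverse.
#'
#' @return An [expr_data] with hand-written values; repeated calls are
#'   bit-identical.
#' @export
tiny_fixture <- function() {
  X <- cbind(c(1.0, -1.0, 0.5, 2.0),
             c(0.3, 1.2, -0.7, 0.4),
             c(2.0, -2.0, 1.0, 4.0))
  expr_data(X, c(1L, 0L, 1L, 0L),
            gene_ids = c("gA", "gB", "gC"),
            sample_ids = c("s1", "s2", "s3", "s4"))
}
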