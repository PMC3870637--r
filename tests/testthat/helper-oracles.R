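# Dense-route oracles used across tests.  These deliberately avoid the
# package's low-rank code paths: the pseudoinverse comes from MASS::ginv
# and determinants/inverses from base dense linear algebra.

dense_sigma <- function(X, sel, cc, h) {
  n <- nrow(X)
  S <- diag(n) + h
  if (length(sel)) {
    Xs <- X[, sel, drop = FALSE]
    S <- S + cc * Xs %*% MASS::ginv(crossprod(Xs)) %*% t(Xs)
  }
  S
}

dense_logdet <- function(S) as.numeric(determinant(S, logarithm = TRUE)$modulus)

dense_quad <- function(S, z) drop(crossprod(z, solve(S, z)))

# unnormalized log posterior over gamma configurations given (Z, c),
# computed entirely through the dense route
dense_gamma_log_post <- function(X, Z, cc, h, pi) {
  p <- ncol(X)
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  apply(configs, 1L, function(g) {
    sel <- which(g == 1)
    S <- dense_sigma(X, sel, cc, h)
    -0.5 * dense_logdet(S) - 0.5 * dense_quad(S, Z) +
      sum(g * log(pi) + (1 - g) * log(1 - pi))
  })
}

gamma_key <- function(sel, p) paste(as.integer(seq_len(p) %in% sel), collapse = "")

# random PSD test matrix, optionally rank deficient
random_psd <- function(n, rank = n) {
  A <- matrix(rnorm(n * rank), n, rank)
  tcrossprod(A)
}

# small random dataset with both classes present
random_dataset <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  Y <- rep_len(c(1L, 0L), n)
  expr_data(X, Y)
}
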