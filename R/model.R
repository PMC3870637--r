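#' Model configuration
#'
#' Collects the prior settings of the probit variable-selection model:
#' the intercept prior variance `h` (alpha ~ N(0, h)), the per-gene
#' inclusion prior probabilities `pi` (gamma_i ~ Bernoulli(pi_i)), and
#' optionally a fixed value for the g-prior scale `c` (when set, the
#' Metropolis-Hastings c-update is disabled and the chain runs at that
#' constant, for comparisons against the inverse-gamma hyperprior
#' IG(1/2, n/2) that is used otherwise).
#'
#' @param h intercept prior variance (> 0); default 100 (diffuse).
#' @param pi inclusion prior probability, scalar in (0,1) or vector of
#'   length p; default 0.005, encoding an a-priori small gene set.
#' @param fixed_c optional fixed g-prior scale (> 0).
#' @param rtol relative eigenvalue/singular-value cutoff used for all
#'   pseudoinverse and numerical-rank decisions.
#' @return An object of class `model_config`.
#' @export
model_config <- function(h = 100, pi = 0.005, fixed_c = NULL, rtol = 1e-10) {
  stopifnot(is.numeric(h), length(h) == 1L, h >= 0)
  if (any(pi <= 0 | pi >= 1)) stop("all inclusion priors pi must lie in (0, 1)")
  if (!is.null(fixed_c) && fixed_c <= 0) stop("fixed_c must be positive")
  stopifnot(rtol > 0)
  structure(list(h = h, pi = pi, fixed_c = fixed_c, rtol = rtol),
            class = "model_config")
}

expand_pi <- function(cfg, p) {
  pi <- cfg$pi
  if (length(pi) == 1L) pi <- rep(pi, p)
  if (length(pi) != p) stop("pi must be scalar or length p")
  pi
}

#' Moore-Penrose pseudoinverse of a symmetric PSD matrix
#'
#' Computed by eigendecomposition; eigenvalues at or below
#' `rtol * max(eigenvalue)` are treated as zero.
#'
#' @param M symmetric positive semi-definite matrix.
#' @param rtol relative cutoff for the numerical rank.
#' @return List with `pinv` (the pseudoinverse), `values` (the nonzero
#'   eigenvalues of the pseudoinverse, i.e. reciprocals of the retained
#'   eigenvalues of `M`), and `rank`.
#' @export
pinv_psd <- function(M, rtol = 1e-10) {
  M <- as.matrix(M)
  scale <- max(abs(M), 1)
  if (max(abs(M - t(M))) > 1e-10 * scale) stop("matrix is not symmetric")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- e$values > rtol * max(e$values, 0)
  r <- sum(keep)
  if (r == 0L) {
    return(list(pinv = matrix(0, nrow(M), ncol(M)), values = numeric(0), rank = 0L))
  }
  V <- e$vectors[, keep, drop = FALSE]
  inv_vals <- 1 / e$values[keep]
  list(pinv = V %*% (inv_vals * t(V)), values = inv_vals, rank = r)
}

#' Marginal latent covariance operator Sigma_gamma
#'
#' Builds the n x n covariance of the latent vector after the intercept
#' and regression coefficients are integrated out,
#' `Sigma = I_n + h 11' + c X_g (X_g' X_g)^+ X_g'`,
#' as a low-rank operator: the projector term equals `Q Q'` with `Q` an
#' orthonormal basis of the selected columns' span, so determinant,
#' inverse and quadratic forms cost O(n m^2) instead of O(n^3).
#'
#' @param X n x p expression matrix.
#' @param selected integer indices of the selected genes (may be empty,
#'   may exceed n in number; rank deficiency is handled by the
#'   pseudoinverse).
#' @param c g-prior scale (> 0).
#' @param h intercept prior variance (>= 0).
#' @param rtol numerical-rank cutoff.
#' @return An object of class `sigma_op` with the basis `Q`, its rank
#'   `m`, and the cached log-determinant.
#' @export
build_sigma <- function(X, selected, c, h, rtol = 1e-10) {
  stopifnot(c > 0, h >= 0)
  X <- as.matrix(X)
  selected <- sort(as.integer(selected))
  Q <- cpp_orth_basis(X[, selected, drop = FALSE], rtol)
  n <- nrow(X)
  st <- cpp_sigma_stats(Q, h, c, numeric(n))
  structure(list(n = n, h = h, c = c, Q = Q, m = ncol(Q),
                 selected = selected, logdet = st[["logdet"]]),
            class = "sigma_op")
}

#' @export
print.sigma_op <- function(x, ...) {
  cat(sprintf("sigma_op: n = %d, m = %d selected-span dimensions, c = %g, h = %g\n",
              x$n, x$m, x$c, x$h))
  invisible(x)
}

#' Log-determinant of a `sigma_op`
#' @param op a [build_sigma] operator.
#' @return `log|Sigma|`.
#' @export
sigma_logdet <- function(op) op$logdet

#' Quadratic form `z' Sigma^{-1} z` of a `sigma_op`
#' @param op a [build_sigma] operator.
#' @param z numeric vector of length n.
#' @return The scalar quadratic form, computed through the low-rank
#'   (Woodbury) route.
#' @export
sigma_quad <- function(op, z) {
  stopifnot(length(z) == op$n)
  cpp_sigma_stats(op$Q, op$h, op$c, as.numeric(z))[["quad"]]
}

#' Dense materialization of a `sigma_op`
#' @param x a [build_sigma] operator.
#' @param ... unused.
#' @return The dense n x n matrix `I + h 11' + c QQ'`.
#' @export
as.matrix.sigma_op <- function(x, ...) {
  S <- diag(x$n) + x$h
  if (x$m > 0) S <- S + x$c * tcrossprod(x$Q)
  S
}

#' Dense precision matrix `Sigma^{-1}` of a `sigma_op`
#'
#' Uses the Woodbury identity on the rank-(m+1) structure; needed for
#' the single-site latent conditionals.
#'
#' @param op a [build_sigma] operator.
#' @return The dense n x n precision matrix.
#' @export
sigma_precision <- function(op) {
  n <- op$n
  W <- cbind(rep(sqrt(op$h), n), if (op$m > 0) sqrt(op$c) * op$Q)
  K <- diag(ncol(W)) + crossprod(W)
  diag(n) - W %*% solve(K, t(W))
}

#' Log density of the inverse-gamma hyperprior on c
#'
#' The reference prior IG(1/2, n/2), normalized:
#' `log pi(c) = (1/2) log(n/2) - log Gamma(1/2) - (3/2) log c - n/(2c)`.
#'
#' @param c evaluation point(s), > 0.
#' @param n training sample size (the prior scale is n/2).
#' @return Log density value(s).
#' @export
log_prior_c <- function(c, n) {
  if (any(c <= 0)) stop("c must be positive")
  0.5 * log(n / 2) - lgamma(0.5) - 1.5 * log(c) - n / (2 * c)
}

#' Marginalized log posterior density of (Z, gamma, c)
#'
#' The unnormalized log density of the collapsed model in which the
#' intercept and the selected coefficients have been integrated out
#' analytically, excluding the sign-indicator terms (those are enforced
#' by the truncated sampler, not evaluated here):
#' `-1/2 log|Sigma_g| - 1/2 Z' Sigma_g^{-1} Z
#'  + sum_i [g_i log pi_i + (1-g_i) log(1-pi_i)] + log pi(c)`.
#'
#' @param Z latent vector of length n (finite).
#' @param selected integer indices with gamma = 1.
#' @param c g-prior scale (> 0).
#' @param X n x p expression matrix.
#' @param cfg a [model_config].
#' @return The scalar log density.
#' @export
log_marginal <- function(Z, selected, c, X, cfg) {
  if (c <= 0) stop("c must be positive")
  if (any(!is.finite(Z))) stop("Z must be finite")
  n <- nrow(X); p <- ncol(X)
  pi <- expand_pi(cfg, p)
  Q <- cpp_orth_basis(X[, selected, drop = FALSE], cfg$rtol)
  st <- cpp_sigma_stats(Q, cfg$h, c, as.numeric(Z))
  g <- rep(0L, p); g[selected] <- 1L
  -0.5 * st[["logdet"]] - 0.5 * st[["quad"]] +
    sum(g * log(pi) + (1 - g) * log1p(-pi)) +
    log_prior_c(c, n)
}
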