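#' One full truncated-normal sweep of the latent vector Z
#'
#' Single-site Gibbs updates of Z under its joint N(0, Sigma_gamma)
#' distribution restricted to the sign regions implied by Y: each Z_i is
#' drawn from the univariate conditional of the joint given the others,
#' truncated to (0, Inf) when Y_i = 1 and to (-Inf, 0] when Y_i = 0.
#'
#' @param Z current latent vector (length n).
#' @param op a [build_sigma] operator matching the current (gamma, c),
#'   or a dense precision matrix via `precision`.
#' @param Y binary response vector.
#' @param precision optional precomputed dense precision `Sigma^{-1}`
#'   (saves refactorization when sweeping repeatedly at fixed gamma, c).
#' @return The updated latent vector; every entry satisfies the sign
#'   constraint of its Y value.
#' @export
update_Z <- function(Z, op, Y, precision = NULL) {
  if (is.null(precision)) precision <- sigma_precision(op)
  cpp_update_Z(as.numeric(Z), precision, as.integer(Y))
}

#' Conditional inclusion probability of one gene
#'
#' `p(gamma_i = 1 | gamma_(-i), Z, c) = (1 + ((1 - pi_i)/pi_i) rho)^{-1}`
#' with `rho = |Sigma_1 Sigma_0^{-1}|^{1/2}
#' exp{Z'(Sigma_1^{-1} - Sigma_0^{-1})Z / 2}`, where Sigma_1/Sigma_0 set
#' gene i in/out of the selection.  Evaluated in log space.
#'
#' @param i gene index.
#' @param Z latent vector.
#' @param selected currently selected gene indices (with or without i).
#' @param c g-prior scale.
#' @param X expression matrix.
#' @param cfg a [model_config].
#' @return The inclusion probability in (0, 1).
#' @export
gamma_flip_prob <- function(i, Z, selected, c, X, cfg) {
  if (c <= 0) stop("c must be positive")
  pi <- expand_pi(cfg, ncol(X))
  sel1 <- sort(unique(c(selected, i)))
  sel0 <- setdiff(sel1, i)
  st1 <- cpp_sigma_stats(cpp_orth_basis(X[, sel1, drop = FALSE], cfg$rtol),
                         cfg$h, c, as.numeric(Z))
  st0 <- cpp_sigma_stats(cpp_orth_basis(X[, sel0, drop = FALSE], cfg$rtol),
                         cfg$h, c, as.numeric(Z))
  logrho <- 0.5 * (st1[["logdet"]] - st0[["logdet"]]) +
    0.5 * (st1[["quad"]] - st0[["quad"]])
  if (is.nan(logrho)) stop("non-finite log rho for gene ", i)
  1 / (1 + exp(log1p(-pi[i]) - log(pi[i]) + logrho))
}

#' One systematic sweep of the inclusion indicators
#'
#' Visits genes in index order 1..p; each gamma_i is redrawn from its
#' full conditional (see [gamma_flip_prob]), with the low-rank
#' Sigma factors updated incrementally after each accepted change.
#' Exactly one uniform random number is consumed per gene.
#'
#' @param Z latent vector.
#' @param selected currently selected gene indices.
#' @param c g-prior scale.
#' @param X expression matrix.
#' @param cfg a [model_config].
#' @return List with the new `selected` (sorted), the orthonormal basis
#'   `Q` of the new selection's span, and the cached `logdet`/`quad`.
#' @export
update_gamma <- function(Z, selected, c, X, cfg) {
  pi <- expand_pi(cfg, ncol(X))
  res <- cpp_gamma_sweep(as.matrix(X), as.numeric(Z),
                         as.integer(sort(selected)) - 1L,
                         cfg$h, c, log1p(-pi) - log(pi), cfg$rtol)
  res$sel <- as.integer(res$sel)
  names(res)[names(res) == "sel"] <- "selected"
  res
}

#' Log full conditional of the g-prior scale c (as a function factory)
#'
#' Returns a vectorized function `f(c)` evaluating
#' `log p(c | Z, gamma) = -1/2 log|Sigma| - 1/2 Z'Sigma^{-1}Z
#'  - (3/2) log c - n/(2c)` up to a constant.  All Z- and gamma-dependent
#' quantities are precomputed so each evaluation is O(m).
#'
#' @param Z latent vector.
#' @param selected selected gene indices.
#' @param X expression matrix.
#' @param h intercept prior variance.
#' @param rtol numerical-rank cutoff.
#' @return A function of `c` (vectorized).
#' @export
c_log_posterior <- function(Z, selected, X, h, rtol = 1e-10) {
  Q <- cpp_orth_basis(X[, selected, drop = FALSE], rtol)
  c_log_posterior_Q(Q, Z, h)
}

# same, from a precomputed basis
c_log_posterior_Q <- function(Q, Z, h) {
  n <- length(Z); m <- ncol(Q)
  a <- if (m) colSums(Q) else numeric(0)
  zq <- if (m) drop(crossprod(Q, Z)) else numeric(0)
  s1 <- sum(Z); zz <- sum(Z * Z)
  aa <- sum(a * a); t_az <- sum(a * zq); zq2 <- sum(zq * zq)
  d <- 1 + h * n
  function(c) {
    e <- d - h * c * aa / (1 + c)
    logdet <- m * log1p(c) + log(e)
    u0 <- sqrt(h) * s1
    bu1 <- sqrt(h) * c * t_az
    x0 <- (u0 - bu1 / (1 + c)) / e
    uKu <- u0 * x0 + (c * zq2 - x0 * bu1) / (1 + c)
    -0.5 * logdet - 0.5 * (zz - uKu) - 1.5 * log(c) - n / (2 * c)
  }
}

#' Mode-centered truncated-normal proposal for the c-update
#'
#' Maximizes the log full conditional of c over `log c` in
#' `[log(1e-3), log(1e6)]` (Brent) to obtain `c_opt`, then builds the
#' perturbation proposal `c* = c_opt + eps`, `eps ~ N(0, sigma^2)`
#' truncated to `(-c_opt + 1e-6, Inf)` so the proposal support is all of
#' `(1e-6, Inf)`.  Because the conditional of c has a polynomial right
#' tail, a curvature-based width is too narrow; `sigma` is instead set
#' to the distance from the mode to the point where the log conditional
#' has fallen by `drop` (6 by default, found by doubling), floored at
#' the Laplace width and at `0.1 * c_opt`.
#'
#' @param logpost function from [c_log_posterior].
#' @param lower_c,upper_c optimization bounds for c.
#' @param drop log-density drop defining the right-tail reach of the
#'   proposal.
#' @return List with `mu`, `sigma`, `lower`, `upper`, `c_opt`.
#' @export
make_c_proposal <- function(logpost, lower_c = 1e-3, upper_c = 1e6, drop = 6) {
  opt <- tryCatch(
    stats::optimize(function(lc) logpost(exp(lc)),
                    c(log(lower_c), log(upper_c)), maximum = TRUE),
    error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  c_opt <- exp(opt$maximum)
  del <- 1e-4 * c_opt
  d2 <- (logpost(c_opt + del) - 2 * logpost(c_opt) + logpost(c_opt - del)) / del^2
  s_lap <- if (is.finite(d2) && d2 < 0) 1 / sqrt(-d2) else 0
  f0 <- logpost(c_opt)
  c_hi <- c_opt
  while (c_hi < upper_c && logpost(c_hi) > f0 - drop) c_hi <- 2 * c_hi
  sigma <- max(c_hi - c_opt, s_lap, 0.1 * c_opt)
  list(mu = 0, sigma = sigma, lower = -c_opt + 1e-6, upper = Inf, c_opt = c_opt)
}

# one truncated-normal draw by inverse CDF (lower bound is always below
# the mean here, so no tail-precision issue arises)
rtrunc_norm1 <- function(prop) {
  plo <- stats::pnorm(prop$lower, prop$mu, prop$sigma)
  phi <- if (is.finite(prop$upper)) stats::pnorm(prop$upper, prop$mu, prop$sigma) else 1
  stats::qnorm(stats::runif(1, plo, phi), prop$mu, prop$sigma)
}

#' Metropolis-Hastings update of the g-prior scale c
#'
#' Proposes `c* = c_opt + eps` from the mode-centered truncated-normal
#' proposal and accepts with probability
#' `min{1, [p(c*|.)/p(c_old|.)] [q(c_old - c_opt)/q(c* - c_opt)]}`;
#' a q evaluation outside the truncation support forces that density to
#' zero.  Consumes exactly two uniforms per call.
#'
#' @param c_old current value of c.
#' @param Z latent vector (used when `logpost` is not supplied).
#' @param selected selected gene indices.
#' @param X expression matrix.
#' @param h intercept prior variance.
#' @param rtol numerical-rank cutoff.
#' @param proposal optional precomputed proposal from [make_c_proposal];
#'   when `NULL` it is derived afresh from the current (Z, gamma).
#' @param logpost optional precomputed log conditional from
#'   [c_log_posterior].
#' @return List with `c` (the retained value), `accepted`, `c_opt`,
#'   `sigma`.
#' @export
update_c <- function(c_old, Z, selected, X, h, rtol = 1e-10,
                     proposal = NULL, logpost = NULL) {
  if (is.null(logpost)) logpost <- c_log_posterior(Z, selected, X, h, rtol)
  if (is.null(proposal)) proposal <- make_c_proposal(logpost)
  if (is.null(proposal)) {   # optimizer failure: keep the current value
    warning("c-proposal optimization failed; keeping current c")
    return(list(c = c_old, accepted = FALSE, c_opt = NA_real_, sigma = NA_real_))
  }
  eps <- rtrunc_norm1(proposal)
  c_new <- proposal$c_opt + eps
  eps_old <- c_old - proposal$c_opt
  logq_old <- if (eps_old > proposal$lower && eps_old < proposal$upper) {
    stats::dnorm(eps_old, proposal$mu, proposal$sigma, log = TRUE)
  } else -Inf
  logq_new <- stats::dnorm(eps, proposal$mu, proposal$sigma, log = TRUE)
  logR <- logpost(c_new) - logpost(c_old) + logq_old - logq_new
  u <- stats::runif(1)
  accepted <- is.finite(logR) && log(u) < min(0, logR)
  if (identical(c_new, c_old)) accepted <- TRUE
  list(c = if (accepted) c_new else c_old, accepted = accepted,
       c_opt = proposal$c_opt, sigma = proposal$sigma)
}

#' Run the three-block MCMC sampler
#'
#' Each iteration performs (1) a truncated-normal sweep of the latent
#' vector Z, (2) a systematic Bernoulli sweep of the inclusion
#' indicators gamma, and (3) a Metropolis-Hastings update of the g-prior
#' scale c (skipped when `cfg$fixed_c` is set).  States after `burn_in`
#' are retained every `thin`-th iteration.  The default protocol
#' (`burn_in = 12000`, `thin = 30`, 6700 retained draws) matches the
#' full-analysis settings; scale `n_iter` down for cross-validation
#' splits.
#'
#' @param ds an [expr_data] object (standardized expression values).
#' @param cfg a [model_config].
#' @param n_iter total iterations; default `burn_in + thin * draws`.
#' @param burn_in discarded initial iterations.
#' @param thin retain every `thin`-th post-burn-in state.
#' @param draws number of retained draws used to derive the default
#'   `n_iter` (ignored when `n_iter` is given).
#' @param seed integer seed; identical seeds and inputs give bit-identical
#'   chains.
#' @param init optional initial state: list with any of `Z`, `selected`,
#'   `c`.  Defaults: gamma empty, c = n, Z_i = +0.5/-0.5 by Y_i.
#' @param fixed_gamma optional integer vector of gene indices: when
#'   given, gamma is held at exactly this selection (Step 2 is skipped),
#'   which turns the sampler into the posterior of the plain g-prior
#'   probit model on those genes.  Used when refitting on a chosen gene
#'   subset for prediction.
#' @param verbose print progress every 1000 iterations?
#' @return An object of class `gsg_chain`: retained draws `Z` (M x n),
#'   `gamma` (M x p logical), `c` (length M), the c acceptance rate, and
#'   the run settings.
#' @export
run_chain <- function(ds, cfg = model_config(), n_iter = NULL,
                      burn_in = 12000, thin = 30, draws = 6700,
                      seed = 1, init = NULL, fixed_gamma = NULL,
                      verbose = FALSE) {
  if (is.null(n_iter)) n_iter <- burn_in + thin * draws
  stopifnot(n_iter > burn_in, thin >= 1)
  if (length(unique(ds$Y)) < 2L) stop("both classes must be present")
  X <- ds$X
  n <- nrow(X); p <- ncol(X)
  pi <- expand_pi(cfg, p)
  logit_pr <- log1p(-pi) - log(pi)
  set.seed(as.integer(seed))

  sel <- sort(as.integer(fixed_gamma %||% init$selected %||% integer(0)))
  cc <- init$c %||% (if (is.null(cfg$fixed_c)) n else cfg$fixed_c)
  if (!is.null(cfg$fixed_c)) cc <- cfg$fixed_c
  Z <- init$Z %||% ifelse(ds$Y == 1L, 0.5, -0.5)

  M <- floor((n_iter - burn_in) / thin)
  Zdraws <- matrix(NA_real_, M, n)
  Gdraws <- matrix(FALSE, M, p)
  cdraws <- numeric(M)
  n_acc <- 0L; n_cup <- 0L
  Q <- cpp_orth_basis(X[, sel, drop = FALSE], cfg$rtol)

  k <- 0L
  for (t in seq_len(n_iter)) {
    # Step 1: Z | gamma, c
    W <- cbind(rep(sqrt(cfg$h), n), if (ncol(Q) > 0) sqrt(cc) * Q)
    K <- diag(ncol(W)) + crossprod(W)
    Omega <- diag(n) - W %*% solve(K, t(W))
    Z <- cpp_update_Z(Z, Omega, ds$Y)
    # Step 2: gamma | Z, c (skipped when the selection is held fixed)
    if (is.null(fixed_gamma)) {
      sw <- cpp_gamma_sweep(X, Z, sel - 1L, cfg$h, cc, logit_pr, cfg$rtol)
      sel <- as.integer(sw$sel)
      Q <- sw$Q
    }
    # Step 3: c | Z, gamma
    if (is.null(cfg$fixed_c)) {
      logpost <- c_log_posterior_Q(Q, Z, cfg$h)
      up <- update_c(cc, Z, sel, X, cfg$h, cfg$rtol, logpost = logpost)
      cc <- up$c
      n_cup <- n_cup + 1L
      if (up$accepted) n_acc <- n_acc + 1L
    }
    if (any(!is.finite(Z)) || !is.finite(cc)) {
      stop("non-finite state at iteration ", t)
    }
    if (t > burn_in && (t - burn_in) %% thin == 0L) {
      k <- k + 1L
      Zdraws[k, ] <- Z
      Gdraws[k, sel] <- TRUE
      cdraws[k] <- cc
    }
    if (verbose && t %% 1000L == 0L) {
      message(sprintf("iter %d: p_gamma = %d, c = %.2f", t, length(sel), cc))
    }
  }

  structure(list(Z = Zdraws[seq_len(k), , drop = FALSE],
                 gamma = Gdraws[seq_len(k), , drop = FALSE],
                 c = cdraws[seq_len(k)],
                 acceptance_rate_c = if (n_cup > 0) n_acc / n_cup else NA_real_,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed, cfg = cfg,
                 gene_ids = ds$gene_ids, sample_ids = ds$sample_ids,
                 Y = ds$Y),
            class = "gsg_chain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gsg_chain <- function(x, ...) {
  cat(sprintf(paste0("gsg_chain: %d retained draws (burn-in %d, thin %d)\n",
                     "  mean model size %.2f, c acceptance rate %.3f\n"),
              nrow(x$gamma), x$burn_in, x$thin,
              mean(rowSums(x$gamma)),
              x$acceptance_rate_c))
  invisible(x)
}

#' Export a chain trace as CSV
#'
#' Columns: iteration (retained index), c, p_gamma (model size), and the
#' selected gene IDs (semicolon separated).
#'
#' @param chain a [run_chain] result.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(chain, path) {
  sel_ids <- apply(chain$gamma, 1L, function(g)
    paste(chain$gene_ids[g], collapse = ";"))
  df <- data.frame(iteration = seq_len(nrow(chain$gamma)),
                   c = chain$c,
                   p_gamma = rowSums(chain$gamma),
                   selected_gene_ids = sel_ids,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = TRUE, row.names = FALSE)
  invisible(path)
}
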