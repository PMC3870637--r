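#' Bayesian predictive probabilities for new samples
#'
#' For each retained draw (Z, gamma, c) the latent value of a new sample
#' is jointly Gaussian with the training latents under the same
#' marginalized covariance structure, built on the (n+1)-row stacked
#' design.  The per-draw probability of class 1 is
#' `P(Z_new > 0 | Z) = Phi(m* / s*)` from that Gaussian conditional, and
#' the reported probability is the average over draws.
#'
#' @param chain a [run_chain] result fitted on `ds_train`.
#' @param ds_train the training [expr_data] (same gene set/order as the
#'   chain).
#' @param X_new matrix of new samples (rows), standardized with the
#'   training genes' transform; columns must match the training genes
#'   (checked by name when column names are present).
#' @param genes optional integer indices of a fixed gene set: when
#'   given, every draw's prediction uses this selection (the
#'   select-then-classify protocol); when `NULL`, each draw uses its own
#'   gamma (the fully Bayesian average).
#' @return A data.frame of class `gsg_prediction` with `sample_id`,
#'   `probability` (of class 1) and `label` (1 iff probability >= 0.5;
#'   an exact 0.5 tie classifies as 1).
#' @export
predict_proba <- function(chain, ds_train, X_new, genes = NULL) {
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new)) &&
      !identical(colnames(X_new), ds_train$gene_ids)) {
    stop("gene IDs of X_new do not match the training data")
  }
  if (ncol(X_new) != ncol(ds_train$X)) {
    stop("gene IDs of X_new do not match the training data")
  }
  h <- chain$cfg$h; rtol <- chain$cfg$rtol
  q <- nrow(X_new)
  if (is.null(genes)) {
    pat <- apply(chain$gamma, 1L, function(g) paste(which(g), collapse = ","))
    prob <- numeric(q)
    for (pt in unique(pat)) {
      idx <- which(pat == pt)
      sel <- if (nzchar(pt)) as.integer(strsplit(pt, ",")[[1L]]) else integer(0)
      pp <- pred_probs_fixed(chain$Z[idx, , drop = FALSE], chain$c[idx],
                             ds_train$X, X_new, sel, h, rtol)
      prob <- prob + colSums(pp)
    }
    prob <- prob / nrow(chain$gamma)
  } else {
    pp <- pred_probs_fixed(chain$Z, chain$c, ds_train$X, X_new,
                           as.integer(genes), h, rtol)
    prob <- colMeans(pp)
  }
  out <- data.frame(sample_id = rownames(X_new) %||% paste0("new", seq_len(q)),
                    probability = prob,
                    label = as.integer(prob >= 0.5),
                    stringsAsFactors = FALSE)
  class(out) <- c("gsg_prediction", "data.frame")
  out
}

# per-draw class-1 probabilities (M x q) under a fixed gene selection
pred_probs_fixed <- function(Zdraws, cdraws, X_train, X_new, selected, h, rtol) {
  n <- ncol(Zdraws); M <- nrow(Zdraws); q <- nrow(X_new)
  Xs <- X_train[, selected, drop = FALSE]
  Zs <- rowSums(Zdraws)
  out <- matrix(NA_real_, M, q)
  for (j in seq_len(q)) {
    Xe <- rbind(Xs, X_new[j, selected, drop = FALSE])
    Qe <- cpp_orth_basis(Xe, rtol)
    m <- ncol(Qe)
    A1 <- Qe[seq_len(n), , drop = FALSE]
    q2 <- if (m > 0) Qe[n + 1L, ] else numeric(0)
    a1 <- if (m > 0) colSums(A1) else numeric(0)
    G <- crossprod(A1)
    ZQ <- Zdraws %*% A1                      # M x m
    hn <- h * n
    for (t in seq_len(M)) {
      cc <- cdraws[t]
      K1 <- diag(m + 1L)
      K1[1L, 1L] <- 1 + hn
      if (m > 0) {
        b <- sqrt(h * cc) * a1
        K1[1L, -1L] <- b
        K1[-1L, 1L] <- b
        K1[-1L, -1L] <- K1[-1L, -1L] + cc * G
      }
      w2 <- c(sqrt(h), if (m > 0) sqrt(cc) * q2)
      u <- c(sqrt(h) * Zs[t], if (m > 0) sqrt(cc) * ZQ[t, ])
      sol <- solve(K1, cbind(u, w2))
      mu <- sum(w2 * sol[, 1L])
      s2 <- 1 + sum(w2 * sol[, 2L])
      out[t, j] <- stats::pnorm(mu / sqrt(s2))
    }
  }
  out
}

#' Harmonic-mean estimator of a leave-one-out predictive probability
#'
#' `M / sum_t (1 / p_t)`, computed in log space.  This is the
#' importance-sampling identity that turns per-draw conditional
#' predictive probabilities (draws made under the full data) into an
#' estimate of `p(Y_i | Y_(-i), X)`.
#'
#' @param p per-draw probabilities in (0, 1]; a zero triggers a warning
#'   and a returned value of 0.
#' @return The harmonic mean.
#' @export
loocv_estimate <- function(p) {
  if (length(p) < 1L) stop("need at least one draw")
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (any(p == 0)) {
    warning("zero predictive probability; returning 0")
    return(0)
  }
  nl <- -log(p)
  mx <- max(nl)
  exp(log(length(p)) - mx - log(sum(exp(nl - mx))))
}

#' Internal leave-one-out predictive assessment from one chain
#'
#' For each retained draw, each training sample's latent value is
#' conditioned on the others under N(0, Sigma_gamma); the probability
#' that its sign matches the observed label is the per-draw conditional
#' predictive probability, combined across draws by the harmonic-mean
#' estimator ([loocv_estimate]).
#'
#' @param chain a [run_chain] result.
#' @param ds_train the training [expr_data].
#' @return A data.frame with `sample_id`, `truth`, `prob_observed`
#'   (estimate of p(Y_i | Y_(-i))), `prob_case` (probability of class
#'   1), `label`, plus attributes `error_rate` and `accuracy`.
#' @export
loocv_internal <- function(chain, ds_train) {
  M <- nrow(chain$Z); n <- ncol(chain$Z)
  h <- chain$cfg$h; rtol <- chain$cfg$rtol
  Y <- ds_train$Y
  pat <- apply(chain$gamma, 1L, function(g) paste(which(g), collapse = ","))
  pmat <- matrix(NA_real_, M, n)
  for (pt in unique(pat)) {
    idx <- which(pat == pt)
    sel <- if (nzchar(pt)) as.integer(strsplit(pt, ",")[[1L]]) else integer(0)
    Q <- cpp_orth_basis(ds_train$X[, sel, drop = FALSE], rtol)
    for (t in idx) {
      W <- cbind(rep(sqrt(h), n), if (ncol(Q) > 0) sqrt(chain$c[t]) * Q)
      K <- diag(ncol(W)) + crossprod(W)
      Omega <- diag(n) - W %*% solve(K, t(W))
      z <- chain$Z[t, ]
      oz <- drop(Omega %*% z)
      dg <- diag(Omega)
      mu <- z - oz / dg
      sdv <- 1 / sqrt(dg)
      p1 <- stats::pnorm(mu / sdv)          # P(Z_i > 0 | Z_(-i))
      pmat[t, ] <- ifelse(Y == 1L, p1, 1 - p1)
    }
  }
  prob_obs <- apply(pmat, 2L, loocv_estimate)
  prob_case <- ifelse(Y == 1L, prob_obs, 1 - prob_obs)
  label <- as.integer(prob_case >= 0.5)
  out <- data.frame(sample_id = ds_train$sample_ids, truth = Y,
                    prob_observed = prob_obs, prob_case = prob_case,
                    label = label, stringsAsFactors = FALSE)
  attr(out, "error_rate") <- mean(label != Y)
  attr(out, "accuracy") <- 1 - mean(label != Y)
  out
}

#' Select-then-classify on a held-out test set
#'
#' The full pipeline on a train/test split: t-statistic prescreen of the
#' training data to `prescreen_k` genes, the Bayesian search on that
#' starting set, selection of the `p_star` genes with the highest
#' posterior inclusion probabilities, and Bayesian predictive
#' classification of the test samples using the selected genes.
#'
#' @param ds_train,ds_test [expr_data] objects over the same genes.
#' @param p_star number of genes used for classification.
#' @param prescreen_k size of the starting set (default 50).
#' @param cfg a [model_config].
#' @param burn_in,thin,draws chain settings for the per-split sampler
#'   (shorter than the full-analysis defaults).
#' @param refit refit the g-prior probit posterior on the selected genes
#'   (gamma fixed) before predicting?  When `FALSE`, the selection
#'   chain's own (Z, c) draws are reused with gamma held at the
#'   selection.
#' @param seed integer seed.
#' @return List with `predictions` (data.frame incl. truth), `accuracy`,
#'   `error_rate`, `selected` (gene IDs), `ranking`, and the `chain`.
#' @export
bayes_classify <- function(ds_train, ds_test, p_star = 10, prescreen_k = 50,
                           cfg = model_config(), burn_in = 2000, thin = 10,
                           draws = 1000, refit = TRUE, seed = 1) {
  if (!identical(ds_train$gene_ids, ds_test$gene_ids)) {
    stop("gene IDs of the test data do not match the training data")
  }
  keep <- t_prescreen(ds_train, min(prescreen_k, ncol(ds_train$X)))
  tr <- subset_expr(ds_train, genes = keep)
  chain <- run_chain(tr, cfg, burn_in = burn_in, thin = thin, draws = draws,
                     seed = seed)
  ranking <- inclusion_probabilities(chain)
  sel <- select_top(ranking, p_star)
  X_new <- ds_test$X[, keep, drop = FALSE]
  if (refit && p_star > 0) {
    trs <- subset_expr(tr, genes = sel)
    chain2 <- run_chain(trs, cfg, burn_in = max(1000, burn_in %/% 2),
                        thin = max(5, thin %/% 2), draws = draws,
                        seed = seed + 1L, fixed_gamma = seq_along(sel))
    pred <- predict_proba(chain2, trs, X_new[, sel, drop = FALSE])
  } else {
    pred <- predict_proba(chain, tr, X_new, genes = sel)
  }
  pred$truth <- ds_test$Y
  err <- mean(pred$label != pred$truth)
  list(predictions = pred, accuracy = 1 - err, error_rate = err,
       selected = tr$gene_ids[sel], ranking = ranking, chain = chain)
}

#' External leave-one-out cross-validation of the full pipeline
#'
#' The selection-bias-free protocol: for every sample, (i) remove it;
#' (ii) rank genes by |t| on the remaining samples and keep the top
#' `prescreen_k` as the starting set; (iii) run the Bayesian search and
#' keep the `p_star` genes with the highest inclusion probabilities;
#' (iv) classify the removed sample from those genes via the Bayesian
#' predictive.  The error rate is the fraction misclassified.
#'
#' @param ds an [expr_data] object.
#' @param cfg a [model_config].
#' @param p_star number of genes used for classification.
#' @param prescreen_k size of the per-split starting set (default 50).
#' @param burn_in,thin,draws per-split chain settings.
#' @param refit refit the g-prior probit posterior on the selected genes
#'   before predicting (as in [bayes_classify])?
#' @param seed base seed; split i runs at `seed + i`.
#' @return List with `error_rate`, `accuracy`, `results` (per-sample
#'   data.frame), `p_star`, `seed`.
#' @export
external_loocv <- function(ds, cfg = model_config(), p_star = 10,
                           prescreen_k = 50, burn_in = 2000, thin = 10,
                           draws = 1000, refit = TRUE, seed = 1) {
  n <- nrow(ds$X)
  if (n < 3L) stop("need at least 3 samples")
  prob <- numeric(n); label <- integer(n)
  for (i in seq_len(n)) {
    tr <- subset_expr(ds, samples = setdiff(seq_len(n), i))
    if (length(unique(tr$Y)) < 2L) stop("single-class training set at split ", i)
    keep <- t_prescreen(tr, min(prescreen_k, ncol(tr$X)))
    trk <- subset_expr(tr, genes = keep)
    chain <- run_chain(trk, cfg, burn_in = burn_in, thin = thin,
                       draws = draws, seed = seed + i)
    sel <- select_top(inclusion_probabilities(chain), p_star)
    xnew <- ds$X[i, keep, drop = FALSE]
    if (refit && p_star > 0) {
      trs <- subset_expr(trk, genes = sel)
      chain2 <- run_chain(trs, cfg, burn_in = max(1000, burn_in %/% 2),
                          thin = max(5, thin %/% 2), draws = draws,
                          seed = seed + i + 100000L,
                          fixed_gamma = seq_along(sel))
      pred <- predict_proba(chain2, trs, xnew[, sel, drop = FALSE])
    } else {
      pred <- predict_proba(chain, trk, xnew, genes = sel)
    }
    prob[i] <- pred$probability
    label[i] <- pred$label
  }
  err <- mean(label != ds$Y)
  list(error_rate = err, accuracy = 1 - err,
       results = data.frame(sample_id = ds$sample_ids, truth = ds$Y,
                            probability = prob, label = label,
                            stringsAsFactors = FALSE),
       p_star = p_star, seed = seed)
}

fit_probit <- function(X, y, ridge = 1e-2) {
  X <- as.matrix(X)
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial("probit"),
               control = stats::glm.control(maxit = 100)))
  if (fit$converged && all(is.finite(stats::coef(fit)))) {
    return(list(type = "glm", fit = fit))
  }
  warning("probit fit did not converge; using ridge-stabilized fit")
  Xd <- cbind(1, X)
  nll <- function(b) {
    eta <- pmin(pmax(drop(Xd %*% b), -30), 30)
    -sum(stats::pnorm(eta, log.p = TRUE) * y +
           stats::pnorm(-eta, log.p = TRUE) * (1 - y)) +
      ridge * sum(b[-1L]^2) / 2
  }
  b <- stats::optim(rep(0, ncol(Xd)), nll, method = "BFGS",
                    control = list(maxit = 500))$par
  list(type = "ridge", coef = b)
}

predict_probit <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (model$type == "glm") {
    colnames(Xnew) <- paste0("V", seq_len(ncol(Xnew)))
    as.numeric(stats::predict(model$fit, newdata = as.data.frame(Xnew),
                              type = "response"))
  } else {
    stats::pnorm(drop(cbind(1, Xnew) %*% model$coef))
  }
}

#' Single-marker baseline: t-test screen plus probit regression
#'
#' Selects the `p_star` genes with the largest |t| and fits a
#' maximum-likelihood probit regression on them; classification at a
#' 0.5 threshold.  With `loocv = TRUE`, both the screen and the fit are
#' redone inside every leave-one-out split (the same splits the Bayesian
#' pipeline uses); with `ds_test`, the model is fitted once on the full
#' training data and applied to the test set.
#'
#' @param ds training [expr_data].
#' @param p_star number of genes.
#' @param ds_test optional test [expr_data].
#' @param loocv run leave-one-out on `ds` instead of a test set?
#' @return List with `error_rate`, `accuracy` and a per-sample `results`
#'   data.frame.
#' @export
ttest_probit_baseline <- function(ds, p_star, ds_test = NULL, loocv = FALSE) {
  if (loocv) {
    n <- nrow(ds$X)
    prob <- numeric(n)
    for (i in seq_len(n)) {
      tr <- subset_expr(ds, samples = setdiff(seq_len(n), i))
      sel <- t_prescreen(tr, p_star)
      m <- fit_probit(tr$X[, sel, drop = FALSE], tr$Y)
      prob[i] <- predict_probit(m, ds$X[i, sel, drop = FALSE])
    }
    truth <- ds$Y
    ids <- ds$sample_ids
  } else {
    if (is.null(ds_test)) stop("supply ds_test or set loocv = TRUE")
    sel <- t_prescreen(ds, p_star)
    m <- fit_probit(ds$X[, sel, drop = FALSE], ds$Y)
    prob <- predict_probit(m, ds_test$X[, sel, drop = FALSE])
    truth <- ds_test$Y
    ids <- ds_test$sample_ids
  }
  label <- as.integer(prob >= 0.5)
  err <- mean(label != truth)
  list(error_rate = err, accuracy = 1 - err,
       results = data.frame(sample_id = ids, truth = truth,
                            probability = prob, label = label,
                            stringsAsFactors = FALSE))
}
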