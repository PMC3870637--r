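test_that("harmonic-mean estimator satisfies its exact identities", {
  expect_equal(loocv_estimate(rep(0.37, 25)), 0.37, tolerance = 1e-12)
  expect_equal(loocv_estimate(c(0.5, 1.0)), 2 / 3, tolerance = 1e-12)
  # AM-HM inequality on random inputs
  set.seed(6)
  for (r in 1:20) {
    p <- runif(sample(2:40, 1), 0.01, 1)
    expect_lte(loocv_estimate(p), mean(p) + 1e-12)
  }
  # tiny probabilities must not underflow the log-space computation
  expect_equal(loocv_estimate(c(1e-300, 1e-300)), 1e-300, tolerance = 1e-12)
  expect_warning(z <- loocv_estimate(c(0.5, 0)), "zero")
  expect_identical(z, 0)
})

test_that("with no genes and no intercept variance every prediction is 1/2", {
  set.seed(40)
  n <- 10
  X <- matrix(rnorm(n * 4), n, 4)
  ds <- expr_data(X, rep_len(c(1L, 0L), n))
  cfg <- model_config(h = 0, pi = 0.01)
  chain <- structure(list(Z = matrix(rnorm(5 * n), 5, n),
                          gamma = matrix(FALSE, 5, 4),
                          c = rep(2, 5), cfg = cfg,
                          gene_ids = ds$gene_ids),
                     class = "gsg_chain")
  pred <- predict_proba(chain, ds, matrix(rnorm(8), 2, 4))
  expect_equal(pred$probability, c(0.5, 0.5), tolerance = 1e-12)
  expect_identical(pred$label, c(1L, 1L))   # 0.5 tie classifies as case
})

test_that("negating the latent draws and labels mirrors the probability", {
  set.seed(41)
  n <- 12
  X <- matrix(rnorm(n * 3), n, 3)
  ds <- expr_data(X, rep_len(c(1L, 0L), n))
  cfg <- model_config(h = 2, pi = 0.2)
  Z <- matrix(rnorm(20 * n, sd = 2), 20, n)
  mk <- function(Zm) structure(list(Z = Zm, gamma = matrix(c(TRUE, FALSE, TRUE),
                                                           20, 3, byrow = TRUE),
                                    c = runif(20, 1, 10), cfg = cfg,
                                    gene_ids = ds$gene_ids),
                               class = "gsg_chain")
  xn <- matrix(rnorm(3), 1, 3)
  set.seed(9); p1 <- predict_proba(mk(Z), ds, xn)$probability
  set.seed(9); p2 <- predict_proba(mk(-Z), ds, xn)$probability
  expect_equal(p1, 1 - p2, tolerance = 1e-10)
})

test_that("a training-identical case point classifies towards its own class", {
  d <- generate_synthetic(synth_spec(n_train = 40, n_test = 0, p = 10, k = 2,
                                     beta_true = c(3, -3), seed = 77))
  tr <- d$train
  ch <- run_chain(tr, model_config(h = 10, pi = 0.1), burn_in = 300, thin = 3,
                  draws = 200, seed = 2)
  case_idx <- which(tr$Y == 1L)[1]
  ctrl_idx <- which(tr$Y == 0L)[1]
  pred <- predict_proba(ch, tr, tr$X[c(case_idx, ctrl_idx), , drop = FALSE])
  expect_gt(pred$probability[1], 0.5)
  expect_lt(pred$probability[2], 0.5)
})

test_that("internal LOOCV probabilities are calibrated on a strong-signal fit", {
  d <- generate_synthetic(synth_spec(n_train = 30, n_test = 0, p = 6, k = 2,
                                     beta_true = c(3, -3), seed = 13))
  ch <- run_chain(d$train, model_config(h = 10, pi = 0.1), burn_in = 300,
                  thin = 3, draws = 200, seed = 4)
  res <- loocv_internal(ch, d$train)
  expect_true(all(res$prob_observed >= 0 & res$prob_observed <= 1))
  expect_equal(attr(res, "error_rate") + attr(res, "accuracy"), 1)
  # most samples should be predicted correctly under strong signal
  expect_lt(attr(res, "error_rate"), 0.35)
})

test_that("external LOOCV runs the full per-split protocol", {
  d <- generate_synthetic(synth_spec(n_train = 14, n_test = 0, p = 12, k = 2,
                                     beta_true = c(4, -4), seed = 19))
  res <- external_loocv(d$train, model_config(h = 10, pi = 0.1), p_star = 2,
                        prescreen_k = 6, burn_in = 150, thin = 3, draws = 60,
                        seed = 5)
  expect_equal(res$error_rate + res$accuracy, 1)
  expect_identical(nrow(res$results), 14L)
  expect_true(all(res$results$label %in% c(0L, 1L)))
  expect_lt(res$error_rate, 0.5)
})

test_that("probit baseline is exact on a separable single marker", {
  X <- cbind(c(-3, -2.5, -2, 2, 2.5, 3), rnorm(6))
  ds <- expr_data(X, c(0L, 0L, 0L, 1L, 1L, 1L))
  # resubstitution: classify the training set itself
  res <- ttest_probit_baseline(ds, p_star = 1, ds_test = ds)
  expect_identical(res$error_rate, 0)
  expect_identical(res$accuracy, 1)
})

test_that("baseline supports the standard p* choices and LOOCV splits", {
  d <- generate_synthetic(synth_spec(n_train = 30, n_test = 10, p = 20, k = 3,
                                     beta_true = c(2, -2, 2), seed = 23))
  for (ps in c(6, 10, 14)) {
    res <- ttest_probit_baseline(d$train, ps, ds_test = d$test)
    expect_equal(res$error_rate + res$accuracy, 1)
  }
  res_cv <- ttest_probit_baseline(d$train, 3, loocv = TRUE)
  expect_identical(nrow(res_cv$results), 30L)
  expect_equal(res_cv$error_rate, mean(res_cv$results$label != d$train$Y))
})

test_that("select-then-classify pipeline reports coherent accuracy", {
  d <- generate_synthetic(synth_spec(n_train = 40, n_test = 16, p = 30, k = 3,
                                     beta_true = c(3, -3, 3), seed = 29))
  res <- bayes_classify(d$train, d$test, p_star = 3, prescreen_k = 10,
                        cfg = model_config(h = 10, pi = 0.1),
                        burn_in = 300, thin = 3, draws = 150, seed = 6)
  expect_equal(res$error_rate + res$accuracy, 1)
  expect_identical(nrow(res$predictions), 16L)
  expect_length(res$selected, 3L)
  expect_gt(res$accuracy, 0.5)
})
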