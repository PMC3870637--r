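test_that("latent updates respect the sign regions and half-normal moments", {
  set.seed(21)
  n <- 400
  Y <- rep_len(c(1L, 0L), n)
  X <- matrix(rnorm(n * 2), n, 2)
  # gamma empty, h = 0: Sigma = I, conditionals are independent N(0,1) truncated
  op <- build_sigma(X, integer(0), c = 1, h = 0)
  draws <- matrix(NA_real_, 50, n)
  Z <- ifelse(Y == 1L, 0.5, -0.5)
  P <- sigma_precision(op)
  for (s in 1:50) {
    Z <- update_Z(Z, op, Y, precision = P)
    draws[s, ] <- Z
  }
  expect_true(all(draws[, Y == 1L] > 0))
  expect_true(all(draws[, Y == 0L] <= 0))
  # half-normal mean sqrt(2/pi), 2e4 draws per sign
  expect_equal(mean(draws[, Y == 1L]), sqrt(2 / pi), tolerance = 0.03)
  expect_equal(mean(-draws[, Y == 0L]), sqrt(2 / pi), tolerance = 0.03)
})

test_that("bivariate truncated sweep matches a rejection-sampling oracle", {
  set.seed(33)
  X <- cbind(c(1, 0.8))
  op <- build_sigma(X, 1L, c = 3, h = 0.5)
  S <- as.matrix(op)
  Y <- c(1L, 0L)
  # oracle: rejection sampling from N(0, S) keeping the orthant
  L <- t(chol(S))
  raw <- t(L %*% matrix(rnorm(2 * 2e5), 2))
  keep <- raw[raw[, 1] > 0 & raw[, 2] <= 0, ]
  # Gibbs: run the single-site sweep and collect its stationary samples
  P <- sigma_precision(op)
  Z <- c(0.5, -0.5)
  got <- matrix(NA_real_, 2e4, 2)
  for (s in seq_len(2e4)) {
    Z <- update_Z(Z, op, Y, precision = P)
    got[s, ] <- Z
  }
  se <- apply(keep, 2, sd) / sqrt(nrow(keep) / 10)   # generous
  expect_equal(colMeans(got), colMeans(keep), tolerance = 0.05)
  expect_equal(apply(got, 2, sd), apply(keep, 2, sd), tolerance = 0.05)
})

test_that("flip probability reduces to the prior for an uninformative gene", {
  set.seed(3)
  n <- 6
  X <- matrix(rnorm(n * 3), n, 3)
  X[, 2] <- 0                     # zero column: rho = 1 exactly
  Z <- rnorm(n)
  for (pi0 in c(0.5, 0.005)) {
    cfg <- model_config(h = 10, pi = pi0)
    expect_equal(gamma_flip_prob(2, Z, c(1L), 4, X, cfg), pi0,
                 tolerance = 1e-12)
  }
  # a duplicated gene is also uninformative given its copy is selected
  X[, 2] <- 2 * X[, 1]
  cfg <- model_config(h = 10, pi = 0.2)
  expect_equal(gamma_flip_prob(2, Z, c(1L), 4, X, cfg), 0.2, tolerance = 1e-10)
})

test_that("flip probability agrees with the dense two-configuration ratio", {
  ds <- tiny_fixture()
  X <- ds$X
  set.seed(8)
  Z <- rnorm(4)
  cfg <- model_config(h = 1, pi = 0.3)
  for (i in 1:3) {
    for (others in list(integer(0), setdiff(1:3, i)[1])) {
      sel1 <- sort(unique(c(others, i)))
      l1 <- log_marginal(Z, sel1, 2.2, X, cfg)
      l0 <- log_marginal(Z, setdiff(sel1, i), 2.2, X, cfg)
      want <- 1 / (1 + exp(l0 - l1))
      expect_equal(gamma_flip_prob(i, Z, others, 2.2, X, cfg), want,
                   tolerance = 1e-9)
    }
  }
})

test_that("extreme inclusion priors dominate an uninformative likelihood", {
  set.seed(14)
  n <- 6
  X <- matrix(0, n, 3)            # all columns zero: rho = 1 for every gene
  Z <- rnorm(n)
  low <- model_config(h = 1, pi = 1e-12)
  hi <- model_config(h = 1, pi = 1 - 1e-12)
  set.seed(1)
  expect_length(update_gamma(Z, integer(0), 2, X, low)$selected, 0L)
  set.seed(1)
  expect_length(update_gamma(Z, integer(0), 2, X, hi)$selected, 3L)
})

test_that("c-update returns the conditional mode and accepts identity proposals", {
  set.seed(10)
  n <- 15
  X <- matrix(rnorm(n * 4), n, 4)
  Z <- rnorm(n)
  f <- c_log_posterior(Z, c(1L, 3L), X, 100)
  prop <- make_c_proposal(f)
  expect_gte(f(prop$c_opt), f(0.5 * prop$c_opt))
  expect_gte(f(prop$c_opt), f(2 * prop$c_opt))
  # an essentially-identity proposal (sigma -> 0 around c_opt = c_old) accepts
  tiny <- list(mu = 0, sigma = 1e-12, lower = -prop$c_opt + 1e-6, upper = Inf,
               c_opt = prop$c_opt)
  up <- update_c(prop$c_opt, Z, c(1L, 3L), X, 100, proposal = tiny, logpost = f)
  expect_true(up$accepted)
  expect_equal(up$c, prop$c_opt, tolerance = 1e-9)
})

test_that("chains are reproducible and respect retention and sign invariants", {
  ds <- random_dataset(20, 8, seed = 55)
  cfg <- model_config(h = 10, pi = 0.1)
  ch1 <- run_chain(ds, cfg, burn_in = 200, thin = 5, draws = 60, seed = 42)
  ch2 <- run_chain(ds, cfg, burn_in = 200, thin = 5, draws = 60, seed = 42)
  expect_identical(ch1$gamma, ch2$gamma)
  expect_identical(ch1$Z, ch2$Z)
  expect_identical(ch1$c, ch2$c)
  expect_identical(nrow(ch1$Z), 60L)       # floor((n_iter - burn_in)/thin)
  # sign consistency of every retained state
  expect_true(all(ch1$Z[, ds$Y == 1L] > 0))
  expect_true(all(ch1$Z[, ds$Y == 0L] <= 0))
  expect_true(ch1$acceptance_rate_c > 0 && ch1$acceptance_rate_c < 1)
})

test_that("fixed-c mode holds the scale constant through the whole chain", {
  ds <- random_dataset(15, 5, seed = 7)
  cfg <- model_config(h = 10, pi = 0.2, fixed_c = 10)
  ch <- run_chain(ds, cfg, burn_in = 100, thin = 2, draws = 50, seed = 3)
  expect_true(all(ch$c == 10))
  expect_true(is.na(ch$acceptance_rate_c))
  # and a different fixed c gives a different chain (c matters)
  cfg2 <- model_config(h = 10, pi = 0.2, fixed_c = 500)
  ch2 <- run_chain(ds, cfg2, burn_in = 100, thin = 2, draws = 50, seed = 3)
  expect_false(identical(ch$gamma, ch2$gamma))
})

test_that("fixed-gamma mode never updates the selection", {
  ds <- random_dataset(15, 5, seed = 11)
  ch <- run_chain(ds, model_config(h = 10, pi = 0.2), burn_in = 100, thin = 2,
                  draws = 40, seed = 5, fixed_gamma = c(2L, 4L))
  expect_true(all(ch$gamma[, c(2, 4)]))
  expect_true(all(!ch$gamma[, c(1, 3, 5)]))
})

test_that("joint distribution is preserved by the transition kernels (Geweke-style)", {
  ds <- tiny_fixture()
  X <- ds$X; n <- 4; p <- 3
  h <- 1; pi0 <- 0.3
  cfg <- model_config(h = h, pi = pi0)
  rIG <- function(k) 1 / rgamma(k, shape = 0.5, rate = n / 2)
  draw_Z_given <- function(sel, cc) {
    Q <- gsgselect:::cpp_orth_basis(X[, sel, drop = FALSE], 1e-10)
    z <- rnorm(n) + sqrt(h) * rnorm(1)
    if (ncol(Q)) z <- z + sqrt(cc) * drop(Q %*% rnorm(ncol(Q)))
    z
  }
  R <- 20000
  # forward: (gamma, c, Z) straight from prior x likelihood
  set.seed(1)
  fw <- matrix(NA_real_, R, 3)
  for (r in seq_len(R)) {
    g <- which(runif(p) < pi0); cc <- rIG(1); z <- draw_Z_given(g, cc)
    fw[r, ] <- c(length(g), 1 / (1 + cc), log1p(sum(z^2)))
  }
  # successive-conditional: forward data block (Z, Y | gamma, c), then the
  # three MCMC blocks given Y; the stationary marginals must match forward
  set.seed(2)
  sel <- integer(0); cc <- n
  sc <- matrix(NA_real_, R, 3)
  for (r in seq_len(R)) {
    z <- draw_Z_given(sel, cc)
    Y <- as.integer(z > 0)
    op <- build_sigma(X, sel, cc, h)
    z <- update_Z(z, op, Y)
    sel <- update_gamma(z, sel, cc, X, cfg)$selected
    cc <- update_c(cc, z, sel, X, h)$c
    sc[r, ] <- c(length(sel), 1 / (1 + cc), log1p(sum(z^2)))
  }
  bm_se <- function(x, nb = 50) {
    b <- colMeans(matrix(x[seq_len(nb * (length(x) %/% nb))], ncol = nb))
    sd(b) / sqrt(nb)
  }
  for (j in 1:3) {
    zstat <- (mean(fw[, j]) - mean(sc[, j])) /
      sqrt(var(fw[, j]) / R + bm_se(sc[, j])^2)
    expect_lt(abs(zstat), 5)
  }
})
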