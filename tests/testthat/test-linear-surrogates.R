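test_that("AvgGP pools all surfaces and ignores labels", {
  d <- two_surface_data()
  fit <- fit_avggp(d, n_restarts = 1, seed = 1)
  Xs <- matrix(c(0.2, 0.7))
  p0 <- predict_surface(fit, Xs, "a")
  p7 <- predict_surface(fit, Xs, "never-seen-label")
  expect_equal(p0, p7)
  # P = 1 degenerates to a plain GP fit
  d1 <- toy_gp_data(15, seed = 5)
  single <- mo_dataset(d1$X, d1$y, rep("only", 15))
  av <- fit_avggp(single, n_restarts = 1, seed = 2)
  gp <- fit_gp(d1$X, d1$y, n_restarts = 1, seed = 2)
  expect_equal(predict_surface(av, Xs, "only")$mean, predict(gp, Xs)$mean,
               tolerance = 1e-6)
})

test_that("MOGP kernel is block-diagonal with shared SE blocks", {
  p <- toy_params()
  X <- matrix(runif(6))
  lab <- rep(c("a", "b"), each = 3)
  K <- mogp_kernel(X, lab, params = p)
  expect_equal(K[1:3, 4:6], matrix(0, 3, 3))
  expect_equal(K[1:3, 1:3], se_kernel(X[1:3, , drop = FALSE], params = p))
  expect_equal(K, t(K))
})

test_that("MOGP posterior equals an independent per-surface GP with tied hyperparameters", {
  d <- two_surface_data(n = 3, seed = 11)
  fit <- fit_mogp(d, n_restarts = 1, seed = 1)
  Xs <- matrix(c(0.1, 0.45, 0.8))
  po <- predict_surface(fit, Xs, "a")
  ia <- which(d$surface == "a")
  oracle <- gp_posterior(d$X[ia, , drop = FALSE], d$y[ia], Xs, fit$params)
  expect_equal(po$mean, oracle$mean, tolerance = 1e-10)
  expect_equal(po$var, oracle$var, tolerance = 1e-10)
})

test_that("MOGP returns the prior on a declared-but-empty surface and signals unknown labels", {
  d <- two_surface_data()
  d2 <- mo_dataset(d$X, d$y, d$surface, surface_labels = c("a", "b", "empty"))
  fit <- fit_mogp(d2, n_restarts = 1, seed = 1)
  po <- predict_surface(fit, matrix(0.5), "empty")
  expect_equal(po$mean, 0)
  expect_equal(po$var, fit$params$variance)
  expect_error(predict_surface(fit, matrix(0.5), "unknown"),
               class = "tldoe_no_posterior")
})

test_that("LMC with Q=1 and B=I reproduces the MOGP kernel and posterior", {
  d <- two_surface_data(n = 6, seed = 13)
  kp <- kernel_params(1, 0.35, 0.04)
  prm <- lmc_params(W = matrix(0, 2, 1), kappa = c(1, 1),
                    lengthscales = matrix(0.35, 1, 1),
                    noise_variance = 0.04, surface_labels = c("a", "b"))
  K_lmc <- lmc_kernel(d$X, d$surface, params = prm)
  K_mogp <- mogp_kernel(d$X, d$surface, params = kp)
  expect_equal(K_lmc, K_mogp, tolerance = 1e-12)
  # posteriors agree too (block-elimination oracle through gp_posterior)
  lmc_obj <- structure(list(data = d, params = prm,
                            chol = tldoe:::chol_jitter(K_lmc + diag(0.04, 12))),
                       class = c("lmc", "surrogate"))
  Xs <- matrix(c(0.25, 0.6))
  po <- predict_surface(lmc_obj, Xs, "b")
  ib <- which(d$surface == "b")
  oracle <- gp_posterior(d$X[ib, , drop = FALSE], d$y[ib], Xs, kp)
  expect_equal(po$mean, oracle$mean, tolerance = 1e-8)
  expect_equal(po$var, oracle$var, tolerance = 1e-8)
})

test_that("LMC kernel cross-covariance matches a sampling oracle", {
  # empirical covariance of function draws at two fixed points vs b_pp' k(x,x')
  prm <- lmc_params(W = matrix(c(1.2, 0.7), 2, 1), kappa = c(0.3, 0.1),
                    lengthscales = matrix(0.5, 1, 1),
                    noise_variance = 1e-8, surface_labels = c("a", "b"))
  X <- matrix(c(0.2, 0.6))
  lab <- c("a", "b")
  K <- lmc_kernel(rbind(X[1, , drop = FALSE], X[2, , drop = FALSE]), lab,
                  params = prm)
  draws <- withr::with_seed(99, {
    L <- t(chol(K + diag(1e-10, 2)))
    L %*% matrix(rnorm(2 * 10000), 2)
  })
  emp <- stats::cov(t(draws))
  b12 <- tcrossprod(prm$W)[1, 2]
  k_x <- exp(-0.5 * (0.4 / 0.5)^2)
  expect_equal(K[1, 2], b12 * k_x, tolerance = 1e-12)
  expect_equal(emp[1, 2], K[1, 2], tolerance = 0.05)
})

test_that("duplicated rows of W make one surface interpolate another's data", {
  d1 <- toy_gp_data(12, seed = 21, noise_sd = 0.02)
  d <- mo_dataset(d1$X, d1$y, rep("a", 12), surface_labels = c("a", "b"))
  prm <- lmc_params(W = matrix(c(1, 1), 2, 1), kappa = c(0, 0),
                    lengthscales = matrix(0.3, 1, 1),
                    noise_variance = 1e-6, surface_labels = c("a", "b"))
  K <- lmc_kernel(d$X, d$surface, params = prm) + diag(1e-6, 12)
  obj <- structure(list(data = d, params = prm, chol = tldoe:::chol_jitter(K)),
                   class = c("lmc", "surrogate"))
  # the rank-1 kernel matrix is numerically semi-definite, so a small jitter
  # enters the solve; interpolation holds to that resolution
  po_b <- predict_surface(obj, d$X[1:4, , drop = FALSE], "b")
  expect_equal(po_b$mean, d1$y[1:4], tolerance = 0.05)
  po_a <- predict_surface(obj, d$X[1:4, , drop = FALSE], "a")
  expect_equal(po_b$mean, po_a$mean, tolerance = 1e-9)
})

test_that("fitted LMC similarity matrix is PSD and fitting is deterministic", {
  d <- two_surface_data(n = 10, seed = 31)
  f1 <- fit_lmc(d, Q = 2, n_restarts = 1, seed = 5, maxit = 60)
  f2 <- fit_lmc(d, Q = 2, n_restarts = 1, seed = 5, maxit = 60)
  expect_identical(f1$params$W, f2$params$W)
  B <- tldoe:::lmc_B(f1$params)
  expect_true(all(eigen(B, symmetric = TRUE, only.values = TRUE)$values >= -1e-8))
  expect_error(fit_lmc(d, Q = 5), "rank")
})

test_that("LMC with a single surface reduces to a plain GP fit", {
  d1 <- toy_gp_data(18, seed = 41)
  d <- mo_dataset(d1$X, d1$y, rep("s", 18))
  lmc <- fit_lmc(d, Q = 1, n_restarts = 2, seed = 1, maxit = 150)
  gp <- fit_gp(d1$X, d1$y, n_restarts = 2, seed = 1)
  Xs <- matrix(c(0.2, 0.5, 0.9))
  expect_equal(predict_surface(lmc, Xs, "s")$mean, predict(gp, Xs)$mean,
               tolerance = 0.05)
})

test_that("assembled kernel matrices are symmetric with near-nonnegative spectra", {
  d <- two_surface_data(n = 8, seed = 51)
  fit <- fit_lmc(d, Q = 2, n_restarts = 1, seed = 3, maxit = 50)
  K <- lmc_kernel(d$X, d$surface, params = fit$params)
  expect_equal(K, t(K), tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-8)
})
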