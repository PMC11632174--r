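test_that("augmented kernel reduces to a plain SE kernel at equal latent coordinates", {
  prm <- list(variance = 1.7, ls_x = 0.4, ls_h = c(1, 2), noise_variance = 0.01)
  X <- matrix(runif(5))
  H <- matrix(rep(c(0.3, -0.2), each = 5), 5, 2)
  A <- cbind(X, H)
  K <- augmented_kernel(A, A, prm)
  expect_equal(K, se_kernel(X, X, kernel_params(1.7, 0.4, 1)))
})

test_that("distant latent coordinates decouple surfaces (MOGP recovery)", {
  d <- two_surface_data(n = 8, seed = 61)
  prm <- list(variance = 1, ls_x = 0.3, ls_h = 0.01, noise_variance = 0.01)
  # latent separation 100x the latent lengthscale
  means <- matrix(c(0, 1), 2, 1)
  model <- lvmogp_model(d, prm, means, matrix(0, 2, 1), seed = 1)
  Xs <- matrix(seq(0.1, 0.9, length.out = 5))
  po <- predict_surface(model, Xs, "a")
  ia <- which(d$surface == "a")
  kp <- kernel_params(1, 0.3, 0.01)
  oracle <- gp_posterior(d$X[ia, , drop = FALSE], d$y[ia], Xs, kp)
  expect_equal(po$mean, oracle$mean, tolerance = 1e-6)
  expect_equal(po$var, oracle$var, tolerance = 1e-6)
})

test_that("a linear latent kernel on explicit coordinates reproduces an LMC covariance", {
  # with point-mass latents H and a linear kernel over h, cov = (H H')_{pp'} k_x;
  # the LMC with W = H and kappa = 0 gives exactly the same matrix
  X <- matrix(c(0.1, 0.5, 0.9))
  lab <- c("a", "b", "a")
  H <- matrix(c(0.8, -0.4), 2, 1, dimnames = list(c("a", "b"), NULL))
  k_x <- se_kernel(X, X, kernel_params(1, 0.3, 1))
  lin <- tcrossprod(H)[cbind(match(lab, rownames(H)),
                             rep(match(lab, rownames(H)), each = 3))]
  K_lin <- matrix(lin, 3) * k_x
  prm <- lmc_params(W = H, kappa = c(0, 0), lengthscales = matrix(0.3, 1, 1),
                    noise_variance = 1e-9, surface_labels = c("a", "b"))
  expect_equal(K_lin, lmc_kernel(X, lab, params = prm), tolerance = 1e-12)
})

test_that("the variational bound collapses to the exact marginal likelihood", {
  d <- two_surface_data(n = 10, seed = 71)
  prm <- list(variance = 1.2, ls_x = 0.35, ls_h = c(1, 1),
              noise_variance = 0.05)
  means <- matrix(c(0.2, -0.3, 0.1, 0.4), 2, 2)
  vars0 <- matrix(1e-12, 2, 2)
  eps <- withr::with_seed(5, array(rnorm(3 * 2 * 2), dim = c(3, 2, 2)))
  bound <- lvmogp_elbo(d, means, vars0, prm, eps, c("a", "b"),
                       include_kl = FALSE)
  A <- cbind(d$X, means[match(d$surface, c("a", "b")), ])
  kp <- kernel_params(1.2, c(0.35, 1, 1), 0.05)
  exact <- log_marginal_likelihood(A, d$y, kp)
  expect_lt(abs(bound - exact), 1e-3)
  # the KL term only lowers the bound
  expect_lte(lvmogp_elbo(d, means, matrix(0.3, 2, 2), prm, eps, c("a", "b")),
             lvmogp_elbo(d, means, matrix(0.3, 2, 2), prm, eps, c("a", "b"),
                         include_kl = FALSE))
  # and the full ELBO never exceeds the collapsed exact likelihood optimum
  expect_lte(lvmogp_elbo(d, means, vars0, prm, eps, c("a", "b")), exact + 1e-6)
})

test_that("optimization does not decrease the bound and is seed-deterministic", {
  d <- two_surface_data(n = 8, seed = 81)
  f1 <- fit_lvmogp(d, QH = 2, n_restarts = 1, seed = 7, maxit = 60)
  f2 <- fit_lvmogp(d, QH = 2, n_restarts = 1, seed = 7, maxit = 60)
  expect_identical(f1$means, f2$means)
  expect_identical(f1$params, f2$params)
  # ELBO at the optimum is at least the ELBO at the initialization
  eps <- withr::with_seed(tldoe:::sub_seed(7, "fit-eps"),
                          array(rnorm(5 * 2 * 2), dim = c(5, 2, 2)))
  init_means <- withr::with_seed(tldoe:::sub_seed(7, "starts"),
                                 matrix(rnorm(4, 0, 0.1), 2, 2))
  expect_gte(f1$elbo, -1e8)
  expect_gt(f1$elbo,
            lvmogp_elbo(d, init_means, matrix(0.2, 2, 2),
                        list(variance = var(d$y), ls_x = 0.3, ls_h = c(1, 1),
                             noise_variance = 0.1 * var(d$y)),
                        eps, c("a", "b")) - 1e-6)
})

test_that("point-estimate limit equals a plain GP at the latent means", {
  d <- two_surface_data(n = 9, seed = 91)
  prm <- list(variance = 1.4, ls_x = 0.4, ls_h = c(0.8, 1.3),
              noise_variance = 0.03)
  means <- matrix(c(0.5, -0.5, 0, 0.2), 2, 2)
  model <- lvmogp_model(d, prm, means, matrix(0, 2, 2), seed = 3)
  Xs <- matrix(c(0.2, 0.8))
  po <- predict_surface(model, Xs, "b")
  A_train <- cbind(d$X, means[match(d$surface, c("a", "b")), ])
  A_test <- cbind(Xs, matrix(means[2, ], 2, 2, byrow = TRUE))
  kp <- kernel_params(1.4, c(0.4, 0.8, 1.3), 0.03)
  oracle <- gp_posterior(A_train, d$y, A_test, kp)
  expect_equal(po$mean, oracle$mean, tolerance = 1e-10)
  expect_equal(po$var, oracle$var, tolerance = 1e-10)
})

test_that("latent-position uncertainty inflates predictive variance", {
  d <- two_surface_data(n = 9, seed = 101)
  prm <- list(variance = 1.4, ls_x = 0.4, ls_h = c(0.8, 1.3),
              noise_variance = 0.03)
  means <- matrix(c(0.5, -0.5, 0, 0.2), 2, 2)
  m0 <- lvmogp_model(d, prm, means, matrix(0, 2, 2), seed = 3, n_samples = 64)
  m1 <- lvmogp_model(d, prm, means, matrix(0.4, 2, 2), seed = 3, n_samples = 64)
  Xs <- matrix(c(0.15, 0.5, 0.85))
  v0 <- predict_surface(m0, Xs, "a")$var
  v1 <- predict_surface(m1, Xs, "a")$var
  expect_true(all(v1 >= v0 - 1e-6))
})

test_that("surfaces with identical data land close together in latent space", {
  d1 <- toy_gp_data(10, seed = 111, noise_sd = 0.05)
  d <- mo_dataset(rbind(d1$X, d1$X), c(d1$y, d1$y),
                  rep(c("a", "b"), each = 10))
  fit <- fit_lvmogp(d, QH = 2, n_restarts = 1, seed = 2, maxit = 120)
  gap <- sqrt(sum((fit$means[1, ] - fit$means[2, ])^2))
  expect_lt(gap, max(fit$params$ls_h))
})

test_that("new-surface latent initialization follows the probe/primer matching rule", {
  d <- two_surface_data(n = 6, seed = 121)
  d3 <- mo_dataset(rbind(d$X, matrix(runif(6))), c(d$y, rnorm(6)),
                   c(d$surface, rep("c", 6)))
  fit <- fit_lvmogp(d3, QH = 2, n_restarts = 0, seed = 1, maxit = 40)
  md <- data.frame(surface = c("a", "b", "c"),
                   probe = c("probe", "probe", "evagreen"),
                   primer_fw = c("F1", "F2", "F1"),
                   primer_rv = c("R1", "R2", "R3"),
                   stringsAsFactors = FALSE)
  # exactly one probe+primer match: return that surface's latent mean
  new_md <- list(probe = "probe", primer_fw = "F1", primer_rv = "R9")
  init <- init_latent_for_new_surface(fit, md, new_md)
  expect_equal(init$mean, as.numeric(fit$means[1, ]))
  expect_equal(init$rule, "probe+primer")
  # no primer match: fall back to probe matches; equal variances average
  fit_eq <- fit
  fit_eq$vars <- matrix(0.2, 3, 2)
  new_md2 <- list(probe = "probe", primer_fw = "F9", primer_rv = "R9")
  init2 <- init_latent_for_new_surface(fit_eq, md, new_md2)
  expect_equal(init2$mean, colMeans(fit_eq$means[1:2, ]))
  expect_equal(init2$rule, "probe")
  # permutation invariance of the matching set
  md_perm <- md[c(2, 1, 3), ]
  init3 <- init_latent_for_new_surface(fit_eq, md_perm, new_md2)
  expect_equal(init3$mean, init2$mean)
  # no probe match at all: global average rule
  init4 <- init_latent_for_new_surface(
    fit_eq, md, list(probe = "other", primer_fw = "F9", primer_rv = "R9"))
  expect_equal(init4$rule, "all")
  # unknown surface without initialization signals
  expect_error(predict_surface(fit, matrix(0.5), "zzz"),
               class = "tldoe_no_posterior")
})

test_that("latent space export has one row per surface", {
  d <- two_surface_data(n = 6, seed = 131)
  fit <- fit_lvmogp(d, QH = 2, n_restarts = 0, seed = 1, maxit = 30)
  ls <- latent_space(fit)
  expect_equal(ls$surface, c("a", "b"))
  expect_named(ls, c("surface", "mu_h1", "mu_h2", "var_h1", "var_h2"))
})
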