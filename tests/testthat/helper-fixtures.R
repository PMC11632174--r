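# small deterministic fixtures shared across test files

toy_gp_data <- function(n = 20, seed = 1, noise_sd = 0.1) {
  withr::with_seed(seed, {
    X <- matrix(runif(n))
    f <- sin(6 * X[, 1])
    list(X = X, y = f + rnorm(n, 0, noise_sd), f = f)
  })
}

toy_params <- function(variance = 2, lengthscales = 0.3, noise = 0.05) {
  kernel_params(variance, lengthscales, noise)
}

two_surface_data <- function(n = 15, seed = 3) {
  withr::with_seed(seed, {
    X <- matrix(runif(2 * n))
    y <- c(sin(5 * X[1:n, 1]), cos(5 * X[n + 1:n, 1]))
    mo_dataset(X, y, rep(c("a", "b"), each = n))
  })
}
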