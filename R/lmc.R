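#' Coregionalization parameters for the LMC
#'
#' The linear model of coregionalization assumes each output surface is a
#' linear combination of Q shared latent GPs plus an independent term, so
#' the between-surface similarity matrix is `B = W W' + diag(kappa)` (PSD by
#' construction). Each latent function q carries its own SE kernel with unit
#' variance (the scale lives in B); the independent `diag(kappa)` term
#' shares the first latent kernel's lengthscales.
#'
#' @param W P x Q weight matrix.
#' @param kappa length-P non-negative vector of independent variances.
#' @param lengthscales Q x D matrix of per-latent-function lengthscales.
#' @param noise_variance shared observation noise variance.
#' @param surface_labels character vector naming the P rows of `W`.
#' @return object of class `lmc_params`.
#' @export
lmc_params <- function(W, kappa, lengthscales, noise_variance, surface_labels) {
  W <- as.matrix(W)
  lengthscales <- as.matrix(lengthscales)
  stopifnot(nrow(W) == length(kappa), length(surface_labels) == nrow(W),
            all(kappa >= 0), all(lengthscales > 0), noise_variance > 0)
  structure(list(W = W, kappa = as.numeric(kappa), Q = ncol(W),
                 lengthscales = lengthscales, noise_variance = noise_variance,
                 surface_labels = as.character(surface_labels)),
            class = "lmc_params")
}

# similarity matrix B = WW' + diag(kappa)
lmc_B <- function(params) tcrossprod(params$W) + diag(params$kappa, nrow(params$W))

#' LMC kernel matrix over stacked rows
#'
#' Entry (i, j) is \eqn{\sum_q b^{(q)}_{p_i p_j} k_q(x_i, x_j)} where
#' \eqn{b^{(q)}} is the rank-1 contribution of column q of W; the
#' `diag(kappa)` contribution rides on the first latent kernel.
#'
#' @param X,p,X2,p2 stacked inputs and their surface labels.
#' @param params [lmc_params()].
#' @return covariance matrix.
#' @export
lmc_kernel <- function(X, p, X2 = X, p2 = p, params) {
  pi2 <- match(as.character(p2), params$surface_labels)
  p <- match(as.character(p), params$surface_labels)
  p2 <- pi2
  if (anyNA(p) || anyNA(p2)) stop("unknown surface label in lmc_kernel", call. = FALSE)
  K <- 0
  for (q in seq_len(params$Q)) {
    kp <- kernel_params(1, params$lengthscales[q, ], 1)  # noise unused here
    bq <- tcrossprod(params$W[, q])
    if (q == 1) bq <- bq + diag(params$kappa, nrow(params$W))
    K <- K + bq[cbind(rep(p, length(p2)), rep(p2, each = length(p)))] *
      se_kernel(X, X2, kp)
  }
  matrix(K, nrow = length(p))
}

lmc_pack <- function(params) {
  c(as.numeric(params$W), inv_softplus(params$kappa),
    log(as.numeric(params$lengthscales)), log(params$noise_variance))
}
lmc_unpack <- function(theta, P, Q, D, surface_labels) {
  W <- matrix(theta[1:(P * Q)], P, Q)
  kappa <- softplus(theta[P * Q + 1:P])
  ls <- matrix(exp(theta[P * Q + P + 1:(Q * D)]), Q, D)
  nv <- exp(theta[P * Q + P + Q * D + 1])
  lmc_params(W, kappa, ls, nv, surface_labels)
}

#' Fit the linear model of coregionalization
#'
#' Maximizes the exact marginal likelihood over the weights W, independent
#' variances kappa, per-latent-function lengthscales and the shared noise
#' variance, with random restarts. Deterministic for a given seed.
#'
#' @param data a [mo_dataset()]; only surfaces with data are modeled.
#' @param Q number of shared latent functions (rank of W), Q <= P.
#' @param n_restarts,seed,maxit optimizer controls.
#' @return object of class `c("lmc", "surrogate")`.
#' @export
fit_lmc <- function(data, Q = 2, n_restarts = 3, seed = 1, maxit = 200) {
  observed <- data$surface_labels[data$surface_labels %in% data$surface]
  P <- length(observed)
  if (Q > P) stop("rank Q must not exceed the number of observed surfaces", call. = FALSE)
  D <- ncol(data$X)
  vy <- max(stats::var(data$y), 1e-6)
  base_ls <- gp_init(data$X, data$y)$lengthscales
  p_idx <- match(data$surface, observed)
  obj <- cache_vg(lmc_nll_vg(data$X, data$y, p_idx, P, Q, D, observed))
  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts + 1), function(i) {
      W0 <- matrix(rnorm(P * Q, 0, sqrt(vy / (2 * Q))), P, Q)
      ls0 <- base_ls * exp(rnorm(D, 0, if (i == 1) 0 else 0.5))
      lmc_pack(lmc_params(W0, rep(vy / 2, P),
                          matrix(rep(ls0, each = Q), Q, D) *
                            exp(matrix(rnorm(Q * D, 0, if (i == 1) 0.1 else 0.5), Q, D)),
                          0.1 * vy, observed))
    })
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj$fn, obj$gr, method = "L-BFGS-B", lower = -12, upper = 12,
            control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    warning("all LMC restarts failed; returning initialization")
    best <- list(par = starts[[1]], value = obj$fn(starts[[1]]))
  }
  params <- lmc_unpack(best$par, P, Q, D, observed)
  K <- lmc_kernel(data$X, data$surface, params = params) +
    diag(params$noise_variance, length(data$y))
  structure(list(data = data, params = params, loglik = -best$value,
                 chol = chol_jitter(K)),
            class = c("lmc", "surrogate"))
}

#' @export
predict_surface.lmc <- function(object, Xstar, surface, ...) {
  surface <- as.character(surface)
  prm <- object$params
  if (!surface %in% prm$surface_labels) no_posterior("LMC", surface)
  Xstar <- as_matrix_input(Xstar)
  ps <- rep(surface, nrow(Xstar))
  Ks <- lmc_kernel(Xstar, ps, object$data$X, object$data$surface, prm)
  L <- object$chol
  alpha <- backsolve(L, forwardsolve(t(L), object$data$y))
  mu <- drop(Ks %*% alpha)
  V <- forwardsolve(t(L), t(Ks))
  B <- lmc_B(prm)
  prior_var <- B[match(surface, prm$surface_labels), match(surface, prm$surface_labels)]
  v <- pmax(prior_var - colSums(V^2), 0)
  list(mean = mu, var = v, noise_variance = prm$noise_variance)
}
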