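#' Kernel hyperparameters for the squared-exponential covariance
#'
#' Bundles the kernel variance \eqn{\sigma_k^2}, one lengthscale per input
#' dimension, and the observation noise variance \eqn{\sigma_n^2}. All must
#' be strictly positive.
#'
#' @param variance kernel (signal) variance, > 0.
#' @param lengthscales numeric vector of per-dimension lengthscales, > 0.
#' @param noise_variance observation noise variance, > 0.
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(variance, lengthscales, noise_variance) {
  stopifnot(is.numeric(variance), length(variance) == 1,
            is.numeric(lengthscales), length(lengthscales) >= 1,
            is.numeric(noise_variance), length(noise_variance) == 1)
  if (!all(is.finite(c(variance, lengthscales, noise_variance))) ||
      variance <= 0 || any(lengthscales <= 0) || noise_variance <= 0) {
    stop("kernel hyperparameters must be finite and strictly positive", call. = FALSE)
  }
  structure(list(variance = variance,
                 lengthscales = as.numeric(lengthscales),
                 noise_variance = noise_variance),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat("SE kernel: variance =", signif(x$variance, 4),
      " lengthscales = [", paste(signif(x$lengthscales, 4), collapse = ", "),
      "] noise =", signif(x$noise_variance, 4), "\n")
  invisible(x)
}

#' Squared-exponential kernel matrix
#'
#' Computes \eqn{k(x, x') = \sigma_k^2 \exp(-\sum_d (x_d - x'_d)^2 / (2 \ell_d^2))}
#' between all rows of `X` and `X2`.
#'
#' @param X,X2 numeric matrices (N x D and M x D); vectors are treated as
#'   single-column matrices.
#' @param params a [kernel_params()] object whose lengthscale vector has
#'   length D.
#' @return N x M covariance matrix.
#' @export
se_kernel <- function(X, X2 = X, params) {
  X <- as_matrix_input(X); X2 <- as_matrix_input(X2)
  D <- length(params$lengthscales)
  if (ncol(X) != D || ncol(X2) != D) {
    stop("input dimension does not match lengthscale vector length", call. = FALSE)
  }
  Xs <- sweep(X, 2, params$lengthscales, "/")
  X2s <- sweep(X2, 2, params$lengthscales, "/")
  d2 <- outer(rowSums(Xs^2), rowSums(X2s^2), "+") - 2 * tcrossprod(Xs, X2s)
  d2[d2 < 0] <- 0
  params$variance * exp(-0.5 * d2)
}

#' Log marginal likelihood of a zero-mean GP
#'
#' Evaluates \eqn{\log N(y \mid 0, K(X,X) + \sigma_n^2 I)} in closed form.
#'
#' @param X N x D input matrix.
#' @param y numeric vector of N observations.
#' @param params [kernel_params()].
#' @return scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(X, y, params) {
  X <- as_matrix_input(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (length(y) < 1) stop("need at least one observation", call. = FALSE)
  K <- se_kernel(X, X, params) + diag(params$noise_variance, length(y))
  lmvn0(y, K)
}

#' GP posterior at test inputs
#'
#' Conditions the zero-mean GP prior on the training data and returns the
#' latent-function posterior. The returned variance excludes the noise
#' variance; add `params$noise_variance` to score noisy observations.
#'
#' @param X,y training inputs/observations (may be empty: prior returned).
#' @param Xstar test input matrix.
#' @param params [kernel_params()].
#' @param full_cov return the full posterior covariance as well?
#' @return list with `mean`, `var` (and `cov` if `full_cov`).
#' @export
gp_posterior <- function(X, y, Xstar, params, full_cov = FALSE) {
  Xstar <- as_matrix_input(Xstar)
  n_star <- nrow(Xstar)
  if (is.null(X) || length(y) == 0) {
    out <- list(mean = rep(0, n_star), var = rep(params$variance, n_star))
    if (full_cov) out$cov <- se_kernel(Xstar, Xstar, params)
    return(out)
  }
  X <- as_matrix_input(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  K <- se_kernel(X, X, params) + diag(params$noise_variance, length(y))
  Ks <- se_kernel(Xstar, X, params)
  L <- chol_jitter(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  mu <- drop(Ks %*% alpha)
  V <- forwardsolve(t(L), t(Ks))        # L^-T Ks^T ; cov reduction = V'V
  if (full_cov) {
    Sig <- se_kernel(Xstar, Xstar, params) - crossprod(V)
    Sig <- (Sig + t(Sig)) / 2
    v <- pmax(diag(Sig), 0)
    diag(Sig) <- v
    list(mean = mu, var = v, cov = Sig)
  } else {
    v <- pmax(params$variance - colSums(V^2), 0)
    list(mean = mu, var = v)
  }
}

# hyperparameter vector <-> log-space parameterization
gp_pack <- function(params) c(log(params$variance), log(params$lengthscales),
                              log(params$noise_variance))
gp_unpack <- function(theta, D) {
  kernel_params(variance = exp(theta[1]),
                lengthscales = exp(theta[2:(1 + D)]),
                noise_variance = exp(theta[D + 2]))
}

# data-driven initialization: signal variance from var(y), lengthscales from
# median pairwise distances, noise at 10% of var(y)
gp_init <- function(X, y) {
  X <- as_matrix_input(X)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  ls <- apply(X, 2, function(col) {
    u <- unique(col)
    if (length(u) < 2) return(1)
    m <- stats::median(stats::dist(matrix(col)))
    if (!is.finite(m) || m <= 0) m <- diff(range(col)) / 2
    if (m <= 0) 1 else m
  })
  kernel_params(variance = vy, lengthscales = ls, noise_variance = 0.1 * vy)
}

#' Fit GP hyperparameters by maximum marginal likelihood
#'
#' Optimizes \eqn{(\sigma_k^2, \ell_d, \sigma_n^2)} in log space with
#' L-BFGS-B from a data-driven initialization plus random restarts, keeping
#' the restart with the highest log marginal likelihood. Deterministic for a
#' given `seed`.
#'
#' @param X,y training data (N >= 2).
#' @param n_restarts number of randomly jittered restarts beyond the
#'   data-driven start.
#' @param seed integer seed controlling restart jitter.
#' @param init optional [kernel_params()] used as the first start.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @return object of class `gp` holding the data, fitted `params`, and the
#'   attained `loglik`.
#' @export
fit_gp <- function(X, y, n_restarts = 3, seed = 1, init = NULL, maxit = 200) {
  X <- as_matrix_input(X)
  if (nrow(X) < 2) stop("need at least two observations to fit hyperparameters", call. = FALSE)
  D <- ncol(X)
  base <- if (is.null(init)) gp_init(X, y) else init
  obj <- cache_vg(gp_nll_vg(X, y))
  starts <- with_seed(seed, {
    s0 <- gp_pack(base)
    c(list(s0), lapply(seq_len(n_restarts), function(i) s0 + rnorm(length(s0), 0, 0.7)))
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj$fn, obj$gr, method = "L-BFGS-B",
            lower = rep(-12, length(s)), upper = rep(12, length(s)),
            control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    warning("all hyperparameter restarts failed; returning initialization")
    best <- list(par = gp_pack(base), value = obj$fn(gp_pack(base)))
  }
  structure(list(X = X, y = y, params = gp_unpack(best$par, D),
                 loglik = -best$value),
            class = "gp")
}

#' Predict from a fitted single-output GP
#'
#' @param object a `gp` object from [fit_gp()].
#' @param Xstar test inputs.
#' @param full_cov return full covariance?
#' @param ... unused.
#' @return list with `mean`, `var` (latent scale) and `noise_variance`.
#' @export
predict.gp <- function(object, Xstar, full_cov = FALSE, ...) {
  out <- gp_posterior(object$X, object$y, Xstar, object$params, full_cov = full_cov)
  out$noise_variance <- object$params$noise_variance
  out
}

#' @export
print.gp <- function(x, ...) {
  cat("Gaussian process fit:", nrow(x$X), "points,", ncol(x$X), "dims, logML =",
      signif(x$loglik, 6), "\n")
  print(x$params)
  invisible(x)
}
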