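#' @importFrom stats dist kmeans median optim pchisq pnorm rnorm runif sd var
#' @importFrom utils head read.csv write.csv modifyList
NULL

# Cholesky with an escalating jitter ladder. Covariance matrices assembled
# from smooth kernels are often numerically semi-definite; we add the
# smallest jitter (1e-8 .. 1e-4 of mean diagonal) that makes chol() succeed.
chol_jitter <- function(K, ladder = 10^seq(-8, -4)) {
  d <- mean(diag(K))
  if (!is.finite(d) || d <= 0) d <- 1
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (!is.null(L)) return(L)
  for (j in ladder) {
    L <- tryCatch(chol(K + diag(j * d, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("covariance matrix is numerically singular even after jitter", call. = FALSE)
}

# log N(y | 0, K) via Cholesky
lmvn0 <- function(y, K) {
  L <- chol_jitter(K)
  a <- backsolve(L, forwardsolve(t(L), y))
  -0.5 * sum(y * a) - sum(log(diag(L))) - 0.5 * length(y) * log(2 * pi)
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# derive a reproducible 32-bit sub-seed from a base seed and stream labels
sub_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(z) {
    if (is.character(z)) sum(utf8ToInt(z)) else as.numeric(z)
  })))
  s <- 0
  for (p in parts) s <- (s * 1009 + (as.numeric(p) %% 65537)) %% 2147483629
  as.integer(s) + 1L
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))

as_matrix_input <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  X
}
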