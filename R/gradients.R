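# Analytic gradients of the marginal-likelihood objectives.
#
# All models share the identity dL/dtheta = 0.5 * tr((alpha alpha' - K^-1)
# dK/dtheta) with alpha = K^-1 y; the per-parameter dK/dtheta of the SE
# kernel reduces to elementwise products with squared-distance matrices.
# Each fitter exposes a cached value+gradient pair so optim() evaluates the
# expensive factorization once per parameter vector.

# squared-difference matrix per input dimension
sqdiff_list <- function(X, X2 = X) {
  X <- as_matrix_input(X); X2 <- as_matrix_input(X2)
  lapply(seq_len(ncol(X)), function(d) outer(X[, d], X2[, d], "-")^2)
}

# M = alpha alpha' - K^-1 and the data-fit value, from K (incl. noise)
mll_core <- function(y, K) {
  L <- chol_jitter(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  Kinv <- chol2inv(L)
  value <- -0.5 * sum(y * alpha) - sum(log(diag(L))) -
    0.5 * length(y) * log(2 * pi)
  list(value = value, M = tcrossprod(alpha) - Kinv)
}

# gradient of log N(y|0, Kf + noise I) wrt (log var, log ls_d, log noise)
# given M, the noise-free kernel Kf and squared-diff matrices
se_mll_grads <- function(M, Kf, D2, lengthscales, noise_variance) {
  g_var <- 0.5 * sum(M * Kf)
  g_ls <- vapply(seq_along(D2), function(d) {
    0.5 * sum(M * Kf * D2[[d]]) / lengthscales[d]^2
  }, 0)
  g_noise <- 0.5 * sum(diag(M)) * noise_variance
  c(g_var, g_ls, g_noise)
}

# wrap a function returning list(value, grad) with a one-slot cache so
# optim's fn and gr calls at the same theta share the computation
cache_vg <- function(vg) {
  last_theta <- NULL
  last <- NULL
  get <- function(theta) {
    if (is.null(last_theta) || length(theta) != length(last_theta) ||
        any(theta != last_theta)) {
      last <<- vg(theta)
      last_theta <<- theta
    }
    last
  }
  list(fn = function(theta) get(theta)$value,
       gr = function(theta) get(theta)$grad)
}

# negative log marginal likelihood + gradient for a single-output GP
gp_nll_vg <- function(X, y) {
  D <- ncol(as_matrix_input(X))
  D2 <- sqdiff_list(X)
  function(theta) {
    p <- tryCatch(gp_unpack(theta, D), error = function(e) NULL)
    if (is.null(p)) return(list(value = 1e10, grad = numeric(length(theta))))
    out <- tryCatch({
      Kf <- se_kernel(X, X, p)
      core <- mll_core(y, Kf + diag(p$noise_variance, length(y)))
      g <- se_mll_grads(core$M, Kf, D2, p$lengthscales, p$noise_variance)
      list(value = -core$value, grad = -g)
    }, error = function(e) NULL)
    if (is.null(out) || !is.finite(out$value)) {
      list(value = 1e10, grad = numeric(length(theta)))
    } else out
  }
}

# as above but summed over independent per-surface blocks (MOGP)
mogp_nll_vg <- function(blocks, D) {
  D2s <- lapply(blocks, function(b) sqdiff_list(b$X))
  function(theta) {
    p <- tryCatch(gp_unpack(theta, D), error = function(e) NULL)
    if (is.null(p)) return(list(value = 1e10, grad = numeric(length(theta))))
    out <- tryCatch({
      value <- 0
      grad <- numeric(length(theta))
      for (i in seq_along(blocks)) {
        b <- blocks[[i]]
        Kf <- se_kernel(b$X, b$X, p)
        core <- mll_core(b$y, Kf + diag(p$noise_variance, length(b$y)))
        value <- value - core$value
        grad <- grad - se_mll_grads(core$M, Kf, D2s[[i]], p$lengthscales,
                                    p$noise_variance)
      }
      list(value = value, grad = grad)
    }, error = function(e) NULL)
    if (is.null(out) || !is.finite(out$value)) {
      list(value = 1e10, grad = numeric(length(theta)))
    } else out
  }
}

# negative log marginal likelihood + gradient for the LMC
# theta = [vec(W), raw_kappa, log ls (Q x D), log noise]
lmc_nll_vg <- function(X, y, p_idx, P, Q, D, surface_labels) {
  D2 <- sqdiff_list(X)
  same <- outer(p_idx, p_idx, "==")
  ind <- lapply(seq_len(P), function(p) p_idx == p)
  function(theta) {
    prm <- tryCatch(lmc_unpack(theta, P, Q, D, surface_labels),
                    error = function(e) NULL)
    if (is.null(prm)) return(list(value = 1e10, grad = numeric(length(theta))))
    out <- tryCatch({
      Eq <- lapply(seq_len(Q), function(q) {
        se_kernel(X, X, kernel_params(1, prm$lengthscales[q, ], 1))
      })
      Bq_mat <- lapply(seq_len(Q), function(q) {
        bq <- tcrossprod(prm$W[, q])
        if (q == 1) bq <- bq + diag(prm$kappa, P)
        bq[cbind(rep(p_idx, length(p_idx)), rep(p_idx, each = length(p_idx)))]
      })
      N <- length(y)
      K <- diag(prm$noise_variance, N)
      for (q in seq_len(Q)) K <- K + matrix(Bq_mat[[q]], N) * Eq[[q]]
      core <- mll_core(y, K)
      M <- core$M
      gW <- matrix(0, P, Q)
      for (q in seq_len(Q)) {
        G <- M * Eq[[q]]
        w_rows <- prm$W[p_idx, q]
        v <- G %*% w_rows
        gW[, q] <- vapply(seq_len(P), function(p) sum(v[ind[[p]]]), 0)
      }
      gkraw <- vapply(seq_len(P), function(p) {
        blk <- ind[[p]]
        0.5 * sum((M * Eq[[1]])[blk, blk])
      }, 0) * stats::plogis(theta[P * Q + 1:P])  # softplus chain
      gls <- matrix(0, Q, D)
      for (q in seq_len(Q)) for (d in seq_len(D)) {
        gls[q, d] <- 0.5 * sum(M * matrix(Bq_mat[[q]], N) * Eq[[q]] * D2[[d]]) /
          prm$lengthscales[q, d]^2
      }
      gnoise <- 0.5 * sum(diag(M)) * prm$noise_variance
      list(value = -core$value,
           grad = -c(as.numeric(gW), gkraw, as.numeric(gls), gnoise))
    }, error = function(e) NULL)
    if (is.null(out) || !is.finite(out$value)) {
      list(value = 1e10, grad = numeric(length(theta)))
    } else out
  }
}

# negative ELBO + gradient for the LVMOGP
# theta = [log var, log ls_x, log ls_h, log noise, mu (P x QH), log s (P x QH)]
lvmogp_nelbo_vg <- function(data, eps, labels, D, QH) {
  P <- length(labels)
  S <- dim(eps)[1]
  p_idx <- match(data$surface, labels)
  ind <- lapply(seq_len(P), function(p) p_idx == p)
  D2x <- sqdiff_list(data$X)
  N <- length(data$y)
  function(theta) {
    st <- tryCatch(lvmogp_unpack(theta, D, QH, P), error = function(e) NULL)
    if (is.null(st)) return(list(value = 1e10, grad = numeric(length(theta))))
    out <- tryCatch({
      prm <- st$params
      kp <- kernel_params(prm$variance, c(prm$ls_x, prm$ls_h), prm$noise_variance)
      value <- 0
      g_kern <- numeric(D + QH + 2)           # logvar, log ls (x,h), lognoise
      g_mu <- matrix(0, P, QH)
      g_logs <- matrix(0, P, QH)
      sqrt_s <- sqrt(st$vars)
      for (s in seq_len(S)) {
        H <- lvmogp_H(st$means, st$vars, eps, s)
        A <- lvmogp_augment(data, H, labels)
        Kf <- se_kernel(A, A, kp)
        core <- mll_core(data$y, Kf + diag(prm$noise_variance, N))
        value <- value + core$value / S
        M <- core$M
        # kernel hyperparameter terms
        g_var <- 0.5 * sum(M * Kf)
        g_lsx <- vapply(seq_len(D), function(d) {
          0.5 * sum(M * Kf * D2x[[d]]) / prm$ls_x[d]^2
        }, 0)
        MKf <- M * Kf
        g_lsh <- numeric(QH)
        for (j in seq_len(QH)) {
          cvec <- A[, D + j]
          dif <- outer(cvec, cvec, "-")
          g_lsh[j] <- 0.5 * sum(MKf * dif^2) / prm$ls_h[j]^2
          # latent-coordinate gradient: dL/dH[p,j]
          rs <- rowSums(MKf * dif)
          gH <- -vapply(seq_len(P), function(p) sum(rs[ind[[p]]]), 0) /
            prm$ls_h[j]^2
          g_mu[, j] <- g_mu[, j] + gH / S
          g_logs[, j] <- g_logs[, j] +
            gH * 0.5 * sqrt_s[, j] * eps[s, , j] / S
        }
        g_noise <- 0.5 * sum(diag(M)) * prm$noise_variance
        g_kern <- g_kern + c(g_var, g_lsx, g_lsh, g_noise) / S
      }
      kl <- lvmogp_kl(st$means, st$vars)
      g_mu <- g_mu - st$means
      g_logs <- g_logs - 0.5 * (st$vars - 1)
      elbo <- value - kl
      grad <- c(g_kern[1], g_kern[1 + seq_len(D)], g_kern[1 + D + seq_len(QH)],
                g_kern[D + QH + 2], as.numeric(g_mu), as.numeric(g_logs))
      list(value = -elbo, grad = -grad)
    }, error = function(e) NULL)
    if (is.null(out) || !is.finite(out$value)) {
      list(value = 1e10, grad = numeric(length(theta)))
    } else out
  }
}

# stage-one LVMOGP objective: negative exact log marginal likelihood with
# point-estimate latent coordinates (no KL, no latent variances)
# theta = [log var, log ls_x, log ls_h, log noise, mu (P x QH)]
lvmogp_ml_vg <- function(data, labels, D, QH) {
  P <- length(labels)
  p_idx <- match(data$surface, labels)
  ind <- lapply(seq_len(P), function(p) p_idx == p)
  D2x <- sqdiff_list(data$X)
  N <- length(data$y)
  function(theta) {
    out <- tryCatch({
      i <- 0
      variance <- exp(theta[i + 1]); i <- i + 1
      ls_x <- exp(theta[i + 1:D]); i <- i + D
      ls_h <- exp(theta[i + 1:QH]); i <- i + QH
      nv <- exp(theta[i + 1]); i <- i + 1
      mu <- matrix(theta[i + 1:(P * QH)], P, QH)
      kp <- kernel_params(variance, c(ls_x, ls_h), nv)
      A <- cbind(data$X, mu[p_idx, , drop = FALSE])
      Kf <- se_kernel(A, A, kp)
      core <- mll_core(data$y, Kf + diag(nv, N))
      M <- core$M
      MKf <- M * Kf
      g_var <- 0.5 * sum(MKf)
      g_lsx <- vapply(seq_len(D), function(d) {
        0.5 * sum(MKf * D2x[[d]]) / ls_x[d]^2
      }, 0)
      g_lsh <- numeric(QH)
      g_mu <- matrix(0, P, QH)
      for (j in seq_len(QH)) {
        cvec <- A[, D + j]
        dif <- outer(cvec, cvec, "-")
        g_lsh[j] <- 0.5 * sum(MKf * dif^2) / ls_h[j]^2
        rs <- rowSums(MKf * dif)
        g_mu[, j] <- -vapply(seq_len(P), function(p) sum(rs[ind[[p]]]), 0) /
          ls_h[j]^2
      }
      g_noise <- 0.5 * sum(diag(M)) * nv
      list(value = -core$value,
           grad = -c(g_var, g_lsx, g_lsh, g_noise, as.numeric(g_mu)))
    }, error = function(e) NULL)
    if (is.null(out) || !is.finite(out$value)) {
      list(value = 1e10, grad = numeric(length(theta)))
    } else out
  }
}
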