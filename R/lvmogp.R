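#' Latent-variable multi-output Gaussian process
#'
#' The LVMOGP augments the input domain with a learned latent coordinate
#' per output surface: `y_p(x) = f(x, h_p) + eps`, with a product SE kernel
#' over the observed dimensions x and the latent dimensions h. Surfaces
#' whose latent coordinates are close (relative to the latent lengthscales)
#' share function values; surfaces placed far apart decouple, recovering
#' independent GPs. To carry uncertainty about the placement, each `h_p` is
#' a diagonal Gaussian `N(mu_p, diag(s_p))` rather than a point.
#'
#' Training maximizes a Jensen lower bound on the log marginal likelihood:
#' the average over reparameterized samples of H of the exact GP marginal
#' likelihood, minus `KL(q(H) || N(0, I))`. The sample draws are fixed per
#' fit, so the objective is deterministic and the bound collapses to the
#' exact likelihood as the latent variances shrink to zero.
#'
#' @name lvmogp
NULL

lvmogp_check_params <- function(params, D, QH) {
  stopifnot(params$variance > 0, params$noise_variance > 0,
            length(params$ls_x) == D, all(params$ls_x > 0),
            length(params$ls_h) == QH, all(params$ls_h > 0))
  params
}

#' SE kernel on the augmented (x, h) space
#'
#' Product of an SE kernel over the observed dimensions and an SE kernel
#' over the latent dimensions, with separate lengthscales; equivalently one
#' SE kernel on the concatenated coordinates.
#'
#' @param A,B matrices with D + QH columns (x then h).
#' @param params list with `variance`, `ls_x`, `ls_h`, `noise_variance`.
#' @return covariance matrix.
#' @export
augmented_kernel <- function(A, B = A, params) {
  kp <- kernel_params(params$variance, c(params$ls_x, params$ls_h),
                      params$noise_variance)
  se_kernel(A, B, kp)
}

# H: P_obs x QH matrix of latent coordinates, rows named by surface label
lvmogp_augment <- function(data, H, labels) {
  idx <- match(data$surface, labels)
  cbind(data$X, H[idx, , drop = FALSE])
}

lvmogp_kl <- function(means, vars) {
  0.5 * sum(vars + means^2 - 1 - log(pmax(vars, 1e-300)))
}

# latent sample s for all surfaces: mu + sqrt(var) * eps[s,,]
lvmogp_H <- function(means, vars, eps, s) {
  e <- array(eps[s, , ], dim = dim(means))
  means + sqrt(vars) * e
}

#' Evidence lower bound of the LVMOGP
#'
#' Average over fixed reparameterized latent samples of the exact GP log
#' marginal likelihood on the augmented inputs, optionally minus the KL
#' divergence from the latent prior N(0, I). Equals the exact log marginal
#' likelihood at fixed latent means in the limit of zero latent variance
#' (with `include_kl = FALSE`).
#'
#' @param data a [mo_dataset()] (only surfaces with rows contribute).
#' @param means,vars P_obs x QH latent means and variances (rows ordered as
#'   `labels`).
#' @param params kernel parameter list (`variance`, `ls_x`, `ls_h`,
#'   `noise_variance`).
#' @param eps S x P_obs x QH array of standard-normal draws.
#' @param labels surface labels indexing the rows of `means`.
#' @param include_kl subtract the KL term?
#' @return scalar lower bound.
#' @export
lvmogp_elbo <- function(data, means, vars, params, eps, labels,
                        include_kl = TRUE) {
  S <- dim(eps)[1]
  ll <- vapply(seq_len(S), function(s) {
    H <- lvmogp_H(means, vars, eps, s)
    A <- lvmogp_augment(data, H, labels)
    K <- augmented_kernel(A, A, params) + diag(params$noise_variance, nrow(A))
    lmvn0(data$y, K)
  }, 0)
  out <- mean(ll)
  if (!all(is.finite(ll))) stop("non-finite variational bound", call. = FALSE)
  if (include_kl) out <- out - lvmogp_kl(means, vars)
  out
}

lvmogp_pack <- function(params, means, vars) {
  c(log(params$variance), log(params$ls_x), log(params$ls_h),
    log(params$noise_variance), as.numeric(means), log(as.numeric(vars)))
}
lvmogp_unpack <- function(theta, D, QH, P) {
  i <- 0
  variance <- exp(theta[i + 1]); i <- i + 1
  ls_x <- exp(theta[i + 1:D]); i <- i + D
  ls_h <- exp(theta[i + 1:QH]); i <- i + QH
  nv <- exp(theta[i + 1]); i <- i + 1
  means <- matrix(theta[i + 1:(P * QH)], P, QH); i <- i + P * QH
  vars <- matrix(exp(theta[i + 1:(P * QH)]), P, QH)
  list(params = list(variance = variance, ls_x = ls_x, ls_h = ls_h,
                     noise_variance = nv),
       means = means, vars = vars)
}

#' Assemble an LVMOGP model from explicit parameters
#'
#' Used by [fit_lvmogp()] and by diagnostics/tests that need a model with
#' prescribed latent geometry (e.g. checking that widely separated latent
#' means decouple the surfaces).
#'
#' @param data a [mo_dataset()].
#' @param params kernel parameter list (`variance`, `ls_x`, `ls_h`,
#'   `noise_variance`).
#' @param means,vars latent means/variances, one row per observed surface.
#' @param seed seed fixing the prediction-time latent draws.
#' @param n_samples number of latent samples for prediction averaging.
#' @return object of class `c("lvmogp", "surrogate")`.
#' @export
lvmogp_model <- function(data, params, means, vars, seed = 1, n_samples = 20) {
  observed <- data$surface_labels[data$surface_labels %in% data$surface]
  QH <- ncol(as.matrix(means))
  lvmogp_check_params(params, ncol(data$X), QH)
  means <- as.matrix(means); vars <- as.matrix(vars)
  stopifnot(nrow(means) == length(observed), all(dim(means) == dim(vars)),
            all(vars >= 0))
  pred_eps <- with_seed(sub_seed(seed, "pred-eps"),
                        array(rnorm(n_samples * nrow(means) * QH),
                              dim = c(n_samples, nrow(means), QH)))
  structure(list(data = data, params = params, means = means, vars = vars,
                 labels = observed, QH = QH, pred_eps = pred_eps, seed = seed),
            class = c("lvmogp", "surrogate"))
}

# Data-driven initialization of the latent means: approximate each surface
# by ridge regression on shared RBF features, measure pairwise distances
# between the fitted surface values at the feature centres, and embed them
# in QH dimensions by classical MDS (scaled to roughly unit spread). Gives
# the optimizer a start in which similar surfaces are already neighbours.
lvmogp_init_means <- function(data, QH, labels) {
  P <- length(labels)
  if (P < 2) return(matrix(0, P, QH))
  M <- min(10, max(4, floor(length(data$y) / 4)))
  centers <- suppressWarnings(
    stats::kmeans(data$X, centers = M, nstart = 3, iter.max = 20)$centers)
  med <- stats::median(stats::dist(data$X))
  if (!is.finite(med) || med <= 0) med <- 1
  kp <- kernel_params(1, rep(med, ncol(data$X)), 1)
  Phi_c <- se_kernel(centers, centers, kp)
  fhat <- matrix(0, P, nrow(centers))
  for (i in seq_len(P)) {
    r <- mo_rows(data, labels[i])
    Phi <- se_kernel(data$X[r, , drop = FALSE], centers, kp)
    beta <- solve(crossprod(Phi) + diag(0.1, ncol(Phi)), crossprod(Phi, data$y[r]))
    fhat[i, ] <- drop(Phi_c %*% beta)
  }
  Dm <- as.matrix(stats::dist(fhat))
  H0 <- tryCatch(stats::cmdscale(Dm, k = QH), error = function(e) NULL)
  if (is.null(H0) || ncol(H0) < QH) {
    extra <- matrix(0, P, QH - if (is.null(H0)) 0 else ncol(H0))
    H0 <- cbind(if (is.null(H0)) NULL else H0, extra)
  }
  sds <- apply(H0, 2, stats::sd)
  sds[!is.finite(sds) | sds < 1e-8] <- 1
  sweep(H0, 2, sds, "/")
}

#' Fit the LVMOGP by maximizing the variational bound
#'
#' Jointly optimizes the kernel hyperparameters, the latent means and
#' variances of every observed surface, maximizing the sampled lower bound
#' with L-BFGS-B over several restarts (best bound kept). Deterministic for
#' a given seed.
#'
#' @param data a [mo_dataset()].
#' @param QH latent dimension count (10 for cross-validation runs, 2 for
#'   Bayesian-optimization runs by convention here).
#' @param n_restarts,seed,maxit optimizer controls.
#' @param n_samples reparameterized latent samples used in the bound.
#' @param init optional previous `lvmogp` fit used as a warm start.
#' @return object of class `c("lvmogp", "surrogate")` with `elbo` attained.
#' @export
fit_lvmogp <- function(data, QH = 2, n_restarts = 2, seed = 1, maxit = 150,
                       n_samples = 5, init = NULL) {
  observed <- data$surface_labels[data$surface_labels %in% data$surface]
  P <- length(observed)
  D <- ncol(data$X)
  if (QH < 1) stop("QH must be >= 1", call. = FALSE)
  eps <- with_seed(sub_seed(seed, "fit-eps"),
                   array(rnorm(n_samples * P * QH), dim = c(n_samples, P, QH)))
  obj <- cache_vg(lvmogp_nelbo_vg(data, eps, observed, D, QH))
  base_kp <- gp_init(data$X, data$y)
  mds_means <- lvmogp_init_means(data, QH, observed)
  starts <- with_seed(sub_seed(seed, "starts"), {
    lapply(seq_len(n_restarts + 1), function(i) {
      if (i == 1 && !is.null(init)) {
        lvmogp_pack(init$params, init$means, init$vars)
      } else {
        jit <- if (i == 1) 0 else 0.4
        params <- list(variance = base_kp$variance * exp(rnorm(1, 0, jit)),
                       ls_x = base_kp$lengthscales * exp(rnorm(D, 0, jit)),
                       ls_h = exp(rnorm(QH, 0, jit)),
                       noise_variance = base_kp$noise_variance)
        means <- mds_means + matrix(rnorm(P * QH, 0, if (i == 1) 0.01 else 0.3),
                                    P, QH)
        vars <- matrix(0.1, P, QH)
        lvmogp_pack(params, means, vars)
      }
    })
  })
  # stage-one objective: maximum likelihood over point-estimate latents
  # (latent variances pinned small, no KL) — a much smoother surface that
  # positions the latent means before the full bound refines them
  ml <- cache_vg(lvmogp_ml_vg(data, observed, D, QH))
  n_lat <- P * QH
  best <- NULL
  for (k in seq_along(starts)) {
    s <- starts[[k]]
    warm <- k == 1 && !is.null(init)
    s2 <- s
    if (!warm) {
      s_ml <- s[seq_len(length(s) - n_lat)]        # drop log-variance block
      stage1 <- tryCatch(
        optim(s_ml, ml$fn, ml$gr, method = "L-BFGS-B", lower = -12, upper = 12,
              control = list(maxit = maxit)),
        error = function(e) NULL)
      if (!is.null(stage1)) {
        s2 <- c(stage1$par, s[length(s) - n_lat + seq_len(n_lat)])
      }
    }
    fit <- tryCatch(
      optim(s2, obj$fn, obj$gr, method = "L-BFGS-B", lower = -12, upper = 12,
            control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    warning("all LVMOGP restarts failed; returning initialization")
    best <- list(par = starts[[1]], value = obj$fn(starts[[1]]))
  }
  st <- lvmogp_unpack(best$par, D, QH, P)
  obj <- lvmogp_model(data, st$params, st$means, st$vars, seed = seed)
  obj$elbo <- -best$value
  obj$fit_eps <- eps
  obj
}

# posterior at augmented test rows for one latent sample
lvmogp_cond <- function(object, Astar, H) {
  A <- lvmogp_augment(object$data, H, object$labels)
  K <- augmented_kernel(A, A, object$params) +
    diag(object$params$noise_variance, nrow(A))
  Ks <- augmented_kernel(Astar, A, object$params)
  L <- chol_jitter(K)
  alpha <- backsolve(L, forwardsolve(t(L), object$data$y))
  V <- forwardsolve(t(L), t(Ks))
  list(mean = drop(Ks %*% alpha),
       var = pmax(object$params$variance - colSums(V^2), 0))
}

#' @export
predict_surface.lvmogp <- function(object, Xstar, surface,
                                   latent_dist = NULL, ...) {
  surface <- as.character(surface)
  Xstar <- as_matrix_input(Xstar)
  S <- dim(object$pred_eps)[1]
  known <- surface %in% object$labels
  if (!known && is.null(latent_dist)) no_posterior("LVMOGP", surface)
  new_eps <- if (!known) {
    with_seed(sub_seed(object$seed, "new-surface", surface),
              matrix(rnorm(S * object$QH), S, object$QH))
  } else NULL
  mu_s <- matrix(0, S, nrow(Xstar))
  var_s <- matrix(0, S, nrow(Xstar))
  for (s in seq_len(S)) {
    H <- lvmogp_H(object$means, object$vars, object$pred_eps, s)
    h_star <- if (known) {
      H[match(surface, object$labels), ]
    } else {
      latent_dist$mean + sqrt(pmax(latent_dist$var, 0)) * new_eps[s, ]
    }
    Astar <- cbind(Xstar, matrix(h_star, nrow(Xstar), object$QH, byrow = TRUE))
    po <- lvmogp_cond(object, Astar, H)
    mu_s[s, ] <- po$mean
    var_s[s, ] <- po$var
  }
  mu <- colMeans(mu_s)
  v <- colMeans(var_s + mu_s^2) - mu^2
  list(mean = mu, var = pmax(v, 0),
       noise_variance = object$params$noise_variance)
}

#' Latent-space summary of a fitted LVMOGP
#'
#' @param object fitted `lvmogp`.
#' @return data.frame with one row per surface: label, latent means and
#'   variances. Suitable for delimited-text export and latent-map plots.
#' @export
latent_space <- function(object) {
  stopifnot(inherits(object, "lvmogp"))
  out <- data.frame(surface = object$labels, object$means, object$vars,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("surface", paste0("mu_h", seq_len(object$QH)),
                  paste0("var_h", seq_len(object$QH)))
  out
}

#' Initialize the latent distribution of a new, unobserved surface
#'
#' The new surface's latent mean is an inverse-variance weighted average of
#' the latent means of observed surfaces sharing its probe and at least one
#' primer; if none match on primers, surfaces with the same probe are used;
#' failing that, all observed surfaces. The returned variance moment-matches
#' the weighted mixture of the matching surfaces' latent Gaussians.
#'
#' @param object fitted `lvmogp`.
#' @param metadata data.frame with columns `surface`, `probe`, `primer_fw`,
#'   `primer_rv` covering all observed surfaces.
#' @param new_metadata one-row data.frame (or list) with the same fields for
#'   the new surface.
#' @return list with `mean` and `var` (length-QH vectors) plus the matching
#'   rule used (`rule`).
#' @export
init_latent_for_new_surface <- function(object, metadata, new_metadata) {
  stopifnot(inherits(object, "lvmogp"))
  md <- metadata[match(object$labels, metadata$surface), , drop = FALSE]
  if (anyNA(md$surface)) stop("metadata missing for some observed surfaces", call. = FALSE)
  if (nrow(md) == 0) stop("no observed surfaces to average over", call. = FALSE)
  probe_match <- md$probe == new_metadata$probe
  primer_match <- md$primer_fw == new_metadata$primer_fw |
    md$primer_rv == new_metadata$primer_rv
  sel <- which(probe_match & primer_match); rule <- "probe+primer"
  if (!length(sel)) { sel <- which(probe_match); rule <- "probe" }
  if (!length(sel)) { sel <- seq_len(nrow(md)); rule <- "all" }
  w <- 1 / pmax(rowSums(object$vars[sel, , drop = FALSE]), 1e-12)
  w <- w / sum(w)
  mu <- colSums(object$means[sel, , drop = FALSE] * w)
  second <- colSums((object$vars[sel, , drop = FALSE] +
                       object$means[sel, , drop = FALSE]^2) * w)
  list(mean = mu, var = pmax(second - mu^2, 0), rule = rule)
}
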