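#' Predict on a named output surface
#'
#' Shared surrogate interface: every fitted surrogate (AvgGP, MOGP, LMC,
#' LVMOGP) returns a per-surface Gaussian posterior at the test inputs. The
#' returned `var` is on the latent-function scale; `noise_variance` is
#' supplied separately so callers can score observations (e.g. NLPD, the
#' drift feasibility check) on the observation scale.
#'
#' Models without any information about a surface signal a classed error
#' (`tldoe_no_posterior`): the LMC and MOGP have no posterior on a surface
#' that was never declared, which is what drives the random first point in
#' the Bayesian-optimization harness.
#'
#' @param object fitted surrogate.
#' @param Xstar test inputs.
#' @param surface surface label.
#' @param ... model-specific arguments.
#' @return list with `mean`, `var`, `noise_variance`.
#' @export
predict_surface <- function(object, Xstar, surface, ...) {
  UseMethod("predict_surface")
}

no_posterior <- function(model, surface) {
  stop(structure(class = c("tldoe_no_posterior", "error", "condition"),
                 list(message = sprintf("%s has no posterior on unseen surface '%s'",
                                        model, surface),
                      call = NULL)))
}

#' Fit the pooled "average GP" surrogate
#'
#' Treats all the data as if it came from a single response surface: a plain
#' GP on the pooled rows, ignoring the surface index. Predictions are
#' identical for every surface label, including unseen ones.
#'
#' @param data a [mo_dataset()].
#' @param n_restarts,seed,maxit passed to [fit_gp()].
#' @return object of class `c("avggp", "surrogate")`.
#' @export
fit_avggp <- function(data, n_restarts = 3, seed = 1, maxit = 200) {
  if (length(data$y) < 2) stop("empty or degenerate dataset", call. = FALSE)
  gp <- fit_gp(data$X, data$y, n_restarts = n_restarts, seed = seed, maxit = maxit)
  structure(list(gp = gp, data = data, params = gp$params, loglik = gp$loglik),
            class = c("avggp", "surrogate"))
}

#' @export
predict_surface.avggp <- function(object, Xstar, surface = NULL, ...) {
  out <- predict(object$gp, Xstar)
  out
}

#' Block-diagonal MOGP kernel
#'
#' Covariance between stacked rows `(x, p)`: the shared SE kernel when the
#' two rows lie on the same surface, exactly zero across surfaces.
#'
#' @param X,X2 input matrices.
#' @param p,p2 per-row surface labels.
#' @param params shared [kernel_params()].
#' @return covariance matrix.
#' @export
mogp_kernel <- function(X, p, X2 = X, p2 = p, params) {
  K <- se_kernel(X, X2, params)
  same <- outer(as.character(p), as.character(p2), "==")
  K * same
}

#' Fit the independent-output MOGP surrogate
#'
#' All surfaces share one set of SE hyperparameters (including a single
#' noise variance) but function values on different surfaces are
#' uncorrelated, so the marginal likelihood factorizes over surfaces and is
#' maximized as a sum of per-surface GP likelihoods.
#'
#' @inheritParams fit_avggp
#' @return object of class `c("mogp", "surrogate")`.
#' @export
fit_mogp <- function(data, n_restarts = 3, seed = 1, maxit = 200) {
  if (length(data$y) < 2) stop("empty or degenerate dataset", call. = FALSE)
  D <- ncol(data$X)
  observed <- data$surface_labels[data$surface_labels %in% data$surface]
  blocks <- lapply(observed, function(lb) {
    i <- mo_rows(data, lb)
    list(X = data$X[i, , drop = FALSE], y = data$y[i])
  })
  obj <- cache_vg(mogp_nll_vg(blocks, D))
  base <- gp_init(data$X, data$y)
  starts <- with_seed(seed, {
    s0 <- gp_pack(base)
    c(list(s0), lapply(seq_len(n_restarts), function(i) s0 + rnorm(length(s0), 0, 0.7)))
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
    warning("all hyperparameter restarts failed; returning initialization")
    best <- list(par = gp_pack(base), value = obj$fn(gp_pack(base)))
  }
  structure(list(data = data, params = gp_unpack(best$par, D),
                 loglik = -best$value),
            class = c("mogp", "surrogate"))
}

#' @export
predict_surface.mogp <- function(object, Xstar, surface, ...) {
  surface <- as.character(surface)
  if (!surface %in% object$data$surface_labels) no_posterior("MOGP", surface)
  i <- mo_rows(object$data, surface)
  out <- if (length(i) == 0) {
    gp_posterior(NULL, numeric(0), Xstar, object$params)
  } else {
    gp_posterior(object$data$X[i, , drop = FALSE], object$data$y[i], Xstar,
                 object$params)
  }
  out$noise_variance <- object$params$noise_variance
  out
}

#' @export
print.surrogate <- function(x, ...) {
  cat(toupper(class(x)[1]), "surrogate:", length(x$data$y), "rows,",
      x$data$P, "surfaces\n")
  invisible(x)
}
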