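#' Random-point-addition benchmark on synthetic surfaces
#'
#' Implements the synthetic-benchmark protocol: starting from the fully
#' observed surfaces, add one random pool point per new surface per
#' iteration, refit each surrogate, and score its predictions on the new
#' surfaces against the noiseless truth on a dense grid (RMSE, and NLPD at
#' observation-scale variance).
#'
#' @param gen a `synthetic_mo` object from one of the generators.
#' @param checkpoints iterations (points per new surface) at which to fit
#'   and score; use `1:30` for a full trace or a few checkpoints for a
#'   cheaper summary.
#' @param models subset of `c("avggp", "mogp", "lmc", "lvmogp")`.
#' @param Q,QH LMC rank / LVMOGP latent dimensions.
#' @param seed integer seed (model restarts).
#' @param n_restarts,maxit optimizer controls.
#' @return data.frame with columns model, checkpoint, surface, rmse, nlpd.
#' @export
benchmark_models <- function(gen, checkpoints = c(2, 5, 10),
                             models = c("avggp", "mogp", "lmc", "lvmogp"),
                             Q = 2, QH = 2, seed = 1, n_restarts = 1,
                             maxit = 150) {
  stopifnot(inherits(gen, "synthetic_mo"))
  out <- list()
  for (k in checkpoints) {
    data <- with_pool_points(gen, k)
    st <- fit_standardizer(data$y)
    data_std <- data
    data_std$y <- standardize(data$y, st)
    for (model in models) {
      fit <- fit_surrogate(model, data_std, seed = sub_seed(seed, model, k),
                           Q = Q, QH = QH, n_restarts = n_restarts,
                           maxit = maxit)
      for (lb in gen$new_surfaces) {
        po <- predict_surface(fit, gen$grid_X, lb)
        mu <- unstandardize_mean(po$mean, st)
        vv <- unstandardize_var(po$var + po$noise_variance, st)
        truth <- gen$grid_F[, lb]
        out[[length(out) + 1]] <- data.frame(
          model = model, checkpoint = k, surface = lb,
          rmse = rmse(mu, truth), nlpd = nlpd(mu, vv, truth),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
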