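#' Root mean squared error of predictive means
#'
#' @param mean predictive means.
#' @param truth held-out values.
#' @return scalar RMSE.
#' @export
rmse <- function(mean, truth) {
  stopifnot(length(mean) == length(truth), length(mean) > 0)
  sqrt(mean((mean - truth)^2))
}

#' Negative log predictive density
#'
#' Average negative log density of the held-out observations under the
#' predictive Gaussians. Observations are noisy, so the variance passed in
#' must be on the observation scale (latent variance plus noise variance).
#'
#' @param mean,variance predictive means and observation-scale variances.
#' @param truth held-out observations.
#' @return scalar NLPD (lower is better).
#' @export
nlpd <- function(mean, variance, truth) {
  stopifnot(length(mean) == length(truth), length(mean) > 0,
            all(variance > 0))
  variance <- rep_len(variance, length(mean))
  mean(0.5 * log(2 * pi * variance) + (truth - mean)^2 / (2 * variance))
}

#' Best-so-far regret trace of a Bayesian-optimization run
#'
#' At iteration n the regret is the minimum over selections i <= n of
#' `(y_rate_i - y_best)^2 + max(0, y_drift_i - T_drift)`: squared distance
#' of the selected rate from the best attainable rate, plus a penalty for
#' exceeding the drift threshold. The cumulative trace is the running sum
#' of the best-so-far regret, which plateaus exactly when the best point is
#' found (regret 0).
#'
#' @param y_rate,y_drift rate and drift observations of the selected points
#'   in selection order.
#' @param y_best rate of the point closest to the target among the
#'   training-plus-candidate pool for this surface.
#' @param drift_threshold T_drift; `Inf` disables the penalty.
#' @return list with `per_selection` (the Eq-style term of each selection),
#'   `regret` (best-so-far, non-increasing) and `cumulative`.
#' @export
regret_trace <- function(y_rate, y_drift = rep(0, length(y_rate)), y_best,
                         drift_threshold = Inf) {
  stopifnot(length(y_rate) >= 1, length(y_rate) == length(y_drift),
            is.finite(y_best))
  term <- (y_rate - y_best)^2 + pmax(0, y_drift - drift_threshold)
  best <- cummin(term)
  list(per_selection = term, regret = best, cumulative = cumsum(best))
}
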