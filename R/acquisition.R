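#' Squared distance to the target rate
#'
#' `delta = ||y - T||^2`; for the scalar rate objective this is `(y - T)^2`.
#'
#' @param y observed or predicted rate(s); may be a vector (elementwise
#'   squared distances are summed).
#' @param target target rate (same length as `y` or scalar).
#' @return scalar squared distance.
#' @export
delta_sq <- function(y, target) {
  stopifnot(all(is.finite(y)), all(is.finite(target)))
  sum((y - target)^2)
}

#' Acquisition context for target-vector expected improvement
#'
#' Collects everything the acquisition needs: the target rate, the drift
#' threshold, the incumbent squared distance `delta_min` over the surface
#' being optimized, and the calibration scale `gamma_sq` (mean predictive
#' variance of the rate model at the training points, recorded for
#' diagnostics).
#'
#' @param target_rate target rate T_rate.
#' @param drift_threshold drift threshold T_drift (`Inf` disables the
#'   penalty).
#' @param delta_min best (smallest) squared rate-distance observed so far on
#'   this surface; >= 0.
#' @param gamma_sq mean predictive variance at the training points; > 0.
#' @return list of class `acq_context`.
#' @export
acq_context <- function(target_rate, drift_threshold = Inf, delta_min,
                        gamma_sq = 1) {
  stopifnot(is.finite(target_rate), delta_min >= 0, gamma_sq > 0)
  structure(list(target_rate = target_rate, drift_threshold = drift_threshold,
                 delta_min = delta_min, gamma_sq = gamma_sq),
            class = "acq_context")
}

#' Target-vector expected improvement
#'
#' Expected improvement on the squared distance to the target rate,
#' `E[max(0, delta_min - delta)]` with `delta = (y - T)^2` and
#' `y ~ N(mean, variance)`. Normalizing the residual by the predictive
#' standard deviation makes `delta / variance` noncentral chi-square with
#' one degree of freedom and noncentrality `(mean - T)^2 / variance`, so
#' the improvement is available in closed form from the distribution
#' function `G_lambda` and the truncated first moment:
#' `alpha_EI = delta_min G(u) - variance * E[t 1(t < u)]` with
#' `u = delta_min / variance`. The truncated moment uses the identity
#' `E[t 1(t<u)] = F(u; k+2, lambda) + lambda F(u; k+4, lambda)` for k = 1.
#'
#' @param mean,variance predictive mean and variance of the rate at the
#'   candidate (variance > 0; a zero-variance limit is handled
#'   analytically).
#' @param delta_min incumbent squared distance (>= 0).
#' @param target_rate target rate.
#' @return non-negative expected improvement (vectorized over candidates).
#' @export
target_ei <- function(mean, variance, delta_min, target_rate) {
  stopifnot(all(variance >= 0), delta_min >= 0)
  n <- max(length(mean), length(variance))
  mean <- rep_len(mean, n); variance <- rep_len(variance, n)
  out <- numeric(n)
  tiny <- variance < 1e-300
  if (any(tiny)) {
    out[tiny] <- pmax(0, delta_min - (mean[tiny] - target_rate)^2)
  }
  i <- which(!tiny)
  if (length(i)) {
    v <- variance[i]
    lambda <- (mean[i] - target_rate)^2 / v
    u <- delta_min / v
    G1 <- pchisq(u, df = 1, ncp = lambda)
    part1 <- pchisq(u, df = 3, ncp = lambda) + lambda * pchisq(u, df = 5, ncp = lambda)
    out[i] <- pmax(0, delta_min * G1 - v * part1)
  }
  out
}

#' Probability of feasibility for the drift constraint
#'
#' `PF(x) = p(f_drift(x) <= T_drift)` under the drift surrogate's Gaussian
#' predictive distribution; at zero variance this is the indicator
#' `mean <= T_drift`.
#'
#' @param mean,variance predictive mean and variance of the drift
#'   (observation scale; variance >= 0).
#' @param threshold drift threshold T_drift.
#' @return probability in \[0, 1\] (vectorized).
#' @export
prob_feasible <- function(mean, variance, threshold) {
  stopifnot(all(variance >= 0))
  n <- max(length(mean), length(variance))
  mean <- rep_len(mean, n); variance <- rep_len(variance, n)
  sdv <- sqrt(variance)
  out <- ifelse(sdv > 0, pnorm((threshold - mean) / sdv),
                as.numeric(mean <= threshold))
  out
}

#' Penalized acquisition
#'
#' Product of the expected improvement and the probability of feasibility.
#'
#' @param ei non-negative expected improvement.
#' @param pf probability of feasibility in \[0, 1\].
#' @return penalized acquisition value(s).
#' @export
penalized_acquisition <- function(ei, pf) {
  stopifnot(all(ei >= 0), all(pf >= -1e-12), all(pf <= 1 + 1e-12))
  ei * pmin(pmax(pf, 0), 1)
}

#' Select the next candidate by acquisition argmax
#'
#' Computes the (optionally drift-penalized) target-EI for every candidate
#' and returns the id of the maximizer; ties within a relative tolerance of
#' 1e-12 are broken uniformly at random with the given seed.
#'
#' @param candidates data.frame with columns `id`, `rate_mean`, `rate_var`,
#'   and (if `penalized`) `drift_mean`, `drift_var` — drift on the
#'   observation scale.
#' @param ctx an [acq_context()].
#' @param penalized multiply by the probability of feasibility?
#' @param seed integer seed for tie-breaking.
#' @return the selected candidate's `id` (attributes: `acq`, the full
#'   acquisition vector).
#' @export
select_next <- function(candidates, ctx, penalized = FALSE, seed = 1) {
  if (!nrow(candidates)) stop("empty candidate list", call. = FALSE)
  acq <- target_ei(candidates$rate_mean, candidates$rate_var,
                   ctx$delta_min, ctx$target_rate)
  if (penalized) {
    pf <- prob_feasible(candidates$drift_mean, candidates$drift_var,
                        ctx$drift_threshold)
    acq <- penalized_acquisition(acq, pf)
  }
  top <- max(acq)
  tol <- 1e-12 * max(top, 1e-300)
  ties <- which(acq >= top - tol)
  pick <- if (length(ties) == 1) ties else {
    with_seed(seed, ties[sample.int(length(ties), 1)])
  }
  structure(candidates$id[pick], acq = acq)
}
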