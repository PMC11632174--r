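#' Logistic amplification curve
#'
#' End-point fluorescence after `tau` cycles of amplification:
#' `F_T = nu / (1 + ((nu - F0)/F0) * exp(-r * tau))` — a logistic growth
#' curve starting at the initial fluorescence `F0` and saturating at the
#' carrying capacity `nu`, with growth rate `r`. The reading of the model is
#' pinned by the boundary behavior `F(0) = F0` and `F(Inf) = nu`.
#'
#' @param tau cycle number(s), >= 0.
#' @param F0 starting fluorescence, > 0.
#' @param nu carrying capacity, > F0.
#' @param r amplification rate, > 0.
#' @return fluorescence value(s).
#' @export
amp_logistic <- function(tau, F0, nu, r) {
  if (F0 <= 0 || nu <= F0 || r <= 0) {
    stop("require 0 < F0 < nu and r > 0", call. = FALSE)
  }
  nu / (1 + ((nu - F0) / F0) * exp(-r * tau))
}

#' Drift-modulated amplification signal
#'
#' The measured signal is the logistic curve modulated linearly by the
#' drift `m`: `signal = F_T * (1 + (F_T / nu) * m * (log(F0) / r))`. With
#' `m = 0` the signal is exactly the logistic curve.
#'
#' @inheritParams amp_logistic
#' @param m drift (unconstrained sign).
#' @return signal value(s).
#' @export
amp_signal <- function(tau, F0, nu, r, m) {
  FT <- amp_logistic(tau, F0, nu, r)
  FT * (1 + (FT / nu) * m * (log(F0) / r))
}

# residuals in transformed parameter space: theta = (log F0, log nu, log r, m)
amp_resid <- function(theta, tau, fluor) {
  F0 <- exp(theta[1]); nu <- exp(theta[2]); r <- exp(theta[3]); m <- theta[4]
  if (!is.finite(F0) || !is.finite(nu) || nu <= F0 || F0 <= 0 || r <= 0) {
    return(rep(1e6, length(tau)))
  }
  res <- amp_signal(tau, F0, nu, r, m) - fluor
  res[!is.finite(res)] <- 1e6
  res
}

#' Fit the amplification-curve model to a fluorescence trace
#'
#' Least-squares estimation of `(F0, nu, r, m)` from (cycle, fluorescence)
#' pairs by Levenberg-Marquardt in log space for the positive parameters,
#' with a deterministic multistart over rate and drift initializations.
#' Initialization: `nu` at the trace maximum, `F0` at the first positive
#' reading, `r` from the slope of the logit-transformed trace, `m = 0`.
#'
#' A trace whose dynamic range is negligible relative to its level raises a
#' classed `tldoe_no_amplification` error.
#'
#' @param tau cycle numbers (>= 8 points spanning the rise).
#' @param fluor fluorescence readings.
#' @param seed integer seed (jitters the multistart grid deterministically).
#' @return list with `F0`, `nu`, `r`, `m`, `residual` (residual norm),
#'   `converged`.
#' @export
fit_amplification <- function(tau, fluor, seed = 1) {
  stopifnot(length(tau) == length(fluor), length(tau) >= 8,
            all(is.finite(tau)), all(is.finite(fluor)))
  rng <- diff(range(fluor))
  if (rng < 1e-6 * max(abs(fluor), 1) || rng == 0) {
    stop(structure(class = c("tldoe_no_amplification", "error", "condition"),
                   list(message = "flat trace: no amplification detected",
                        call = NULL)))
  }
  o <- order(tau)
  tau <- tau[o]; fluor <- fluor[o]
  nu0 <- max(fluor) * 1.02
  F00 <- max(fluor[fluor > 0][1], 1e-6, na.rm = TRUE)
  if (!is.finite(F00) || F00 >= nu0) F00 <- nu0 / 100
  # slope of logit-transformed trace estimates r
  fr <- pmin(pmax(fluor / nu0, 1e-4), 1 - 1e-4)
  lg <- log(fr / (1 - fr))
  mid <- fluor > 0.15 * nu0 & fluor < 0.9 * nu0
  r0 <- if (sum(mid) >= 2) {
    max(stats::coef(stats::lm(lg[mid] ~ tau[mid]))[2], 1e-3)
  } else 0.3
  r_grid <- r0 * c(1, 0.3, 3)
  m_grid <- c(0, 0.05, -0.05)
  jit <- with_seed(seed, exp(rnorm(length(r_grid), 0, 0.05)))
  best <- NULL
  for (i in seq_along(r_grid)) for (m0 in m_grid) {
    start <- c(log(F00), log(nu0), log(r_grid[i] * jit[i]), m0)
    fit <- tryCatch(
      minpack.lm::nls.lm(start, fn = amp_resid, tau = tau, fluor = fluor,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(theta = fit$par, rss = rss,
                   converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best)) stop("amplification-curve fit failed from every start", call. = FALSE)
  if (!best$converged) {
    warning("amplification-curve fit did not fully converge; returning best found")
  }
  th <- best$theta
  list(F0 = exp(th[1]), nu = exp(th[2]), r = exp(th[3]), m = th[4],
       residual = sqrt(best$rss), converged = best$converged)
}

#' Fit amplification curves for a table of traces
#'
#' @param traces data.frame with columns `well_id`, `cycle`, `fluorescence`.
#' @param seed integer seed.
#' @return data.frame with one row per well: `well_id`, `F0`, `nu`, `rate`,
#'   `drift`, `residual`; wells with no detectable amplification get NA
#'   parameters and a note.
#' @export
fit_curve_table <- function(traces, seed = 1) {
  stopifnot(all(c("well_id", "cycle", "fluorescence") %in% names(traces)))
  wells <- unique(traces$well_id)
  rows <- lapply(wells, function(w) {
    d <- traces[traces$well_id == w, ]
    fit <- tryCatch(fit_amplification(d$cycle, d$fluorescence,
                                      seed = sub_seed(seed, w)),
                    tldoe_no_amplification = function(e) NULL)
    if (is.null(fit)) {
      data.frame(well_id = w, F0 = NA_real_, nu = NA_real_, rate = NA_real_,
                 drift = NA_real_, residual = NA_real_,
                 note = "no_amplification", stringsAsFactors = FALSE)
    } else {
      data.frame(well_id = w, F0 = fit$F0, nu = fit$nu, rate = fit$r,
                 drift = fit$m, residual = fit$residual, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
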