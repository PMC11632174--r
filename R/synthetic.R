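#' Synthetic benchmark generators
#'
#' Three one-dimensional benchmark settings exercise the surrogates under
#' known ground truth: `gen_uncorrelated` (independent GP draws, a probe
#' for negative transfer), `gen_linear_correlated` (surfaces are linear
#' combinations of two shared latent GP draws, the LMC's home turf) and
#' `gen_offset_sigmoid` (a fixed sigmoid shifted horizontally per surface,
#' a nonlinear family the LMC cannot represent but the LVMOGP can). Each
#' returns observed surfaces, initially-empty "new" surfaces, a per-surface
#' pool of pre-drawn random points to add one per iteration, and noiseless
#' truth on a dense grid for scoring.
#'
#' @name synthetic
NULL

label_seq <- function(prefix, n) {
  if (n > 0) paste0(prefix, seq_len(n)) else character(0)
}

# draw a joint GP sample at rows of X (exact, via Cholesky)
gp_draw <- function(X, lengthscale, variance) {
  K <- se_kernel(X, X, kernel_params(variance, rep(lengthscale, ncol(as_matrix_input(X))),
                                     1)) + diag(1e-9, nrow(as_matrix_input(X)))
  drop(t(chol(K)) %*% rnorm(nrow(as_matrix_input(X))))
}

synthetic_result <- function(case, observed, new_surfaces, X_obs, y_obs, s_obs,
                             pool, grid_X, grid_F, spec) {
  labels <- c(observed, new_surfaces)
  data <- mo_dataset(X_obs, y_obs, s_obs, surface_labels = labels)
  structure(list(case = case, data = data, pool = pool,
                 grid_X = grid_X, grid_F = grid_F,
                 observed_surfaces = observed, new_surfaces = new_surfaces,
                 spec = spec),
            class = "synthetic_mo")
}

#' @export
print.synthetic_mo <- function(x, ...) {
  cat("Synthetic benchmark (", x$case, "): ", length(x$observed_surfaces),
      " observed + ", length(x$new_surfaces), " new surfaces, ",
      length(x$data$y), " observed rows, pool of ",
      nrow(x$pool[[1]]), " points per new surface\n", sep = "")
  invisible(x)
}

#' Uncorrelated response surfaces
#'
#' Every surface is an independent draw from a GP prior (SE kernel,
#' lengthscale 0.3, variance 2 by default) on \[0, 1\]; sharing function
#' values between surfaces can only hurt, so this setting measures negative
#' transfer.
#'
#' @param n_observed surfaces fully observed at the start (30 points each).
#' @param n_new initially-empty surfaces.
#' @param n_points observed points per observed surface.
#' @param pool_size pre-drawn random points available per new surface.
#' @param lengthscale,variance GP prior hyperparameters of the generator.
#' @param noise_sd observation noise standard deviation.
#' @param grid_size dense-grid resolution for truth.
#' @param seed integer seed; fixed seed gives identical datasets.
#' @return object of class `synthetic_mo`.
#' @export
gen_uncorrelated <- function(n_observed = 2, n_new = 10, n_points = 30,
                             pool_size = 30, lengthscale = 0.3, variance = 2,
                             noise_sd = 0.1, grid_size = 101, seed = 1) {
  with_seed(seed, {
    observed <- label_seq("obs", n_observed)
    new_s <- label_seq("new", n_new)
    grid <- matrix(seq(0, 1, length.out = grid_size))
    draw_surface <- function(n_extra) {
      x <- matrix(runif(n_extra))
      f <- gp_draw(rbind(grid, x), lengthscale, variance)
      list(x = x, f_x = f[grid_size + seq_len(n_extra)], f_grid = f[seq_len(grid_size)])
    }
    X_obs <- NULL; y_obs <- NULL; s_obs <- NULL
    grid_F <- matrix(0, grid_size, n_observed + n_new,
                     dimnames = list(NULL, c(observed, new_s)))
    pool <- list()
    for (lb in observed) {
      d <- draw_surface(n_points)
      X_obs <- rbind(X_obs, d$x)
      y_obs <- c(y_obs, d$f_x + rnorm(n_points, 0, noise_sd))
      s_obs <- c(s_obs, rep(lb, n_points))
      grid_F[, lb] <- d$f_grid
    }
    for (lb in new_s) {
      d <- draw_surface(pool_size)
      pool[[lb]] <- data.frame(x = d$x[, 1], f = d$f_x,
                               y = d$f_x + rnorm(pool_size, 0, noise_sd))
      grid_F[, lb] <- d$f_grid
    }
    synthetic_result("uncorrelated", observed, new_s, X_obs, y_obs, s_obs,
                     pool, grid, grid_F,
                     list(lengthscale = lengthscale, variance = variance,
                          noise_sd = noise_sd, seed = seed))
  })
}

#' Linearly correlated response surfaces
#'
#' Surfaces are random linear combinations of two shared latent GP draws
#' (SE kernel, lengthscale 0.3, variance 2 by default) plus observation
#' noise; the stacked function-value matrix has rank <= 2 before noise, the
#' structure the linear model of coregionalization assumes.
#'
#' @inheritParams gen_uncorrelated
#' @return object of class `synthetic_mo`.
#' @export
gen_linear_correlated <- function(n_observed = 2, n_new = 10, n_points = 30,
                                  pool_size = 30, lengthscale = 0.3,
                                  variance = 2, noise_sd = 0.1,
                                  grid_size = 101, seed = 1) {
  with_seed(seed, {
    observed <- label_seq("obs", n_observed)
    new_s <- label_seq("new", n_new)
    P <- n_observed + n_new
    labels <- c(observed, new_s)
    grid <- matrix(seq(0, 1, length.out = grid_size))
    x_all <- lapply(labels, function(lb) {
      matrix(runif(if (lb %in% observed) n_points else pool_size))
    })
    names(x_all) <- labels
    X_union <- rbind(grid, do.call(rbind, x_all))
    g1 <- gp_draw(X_union, lengthscale, variance)
    g2 <- gp_draw(X_union, lengthscale, variance)
    W <- matrix(rnorm(P * 2, 0, sqrt(0.5)), P, 2, dimnames = list(labels, NULL))
    offsets <- c(0, cumsum(vapply(x_all, nrow, 0)))
    surf_vals <- function(lb, on_grid = FALSE) {
      i <- match(lb, labels)
      idx <- if (on_grid) seq_len(grid_size) else
        grid_size + offsets[i] + seq_len(nrow(x_all[[lb]]))
      W[lb, 1] * g1[idx] + W[lb, 2] * g2[idx]
    }
    X_obs <- NULL; y_obs <- NULL; s_obs <- NULL
    grid_F <- matrix(0, grid_size, P, dimnames = list(NULL, labels))
    pool <- list()
    for (lb in labels) {
      f <- surf_vals(lb)
      grid_F[, lb] <- surf_vals(lb, on_grid = TRUE)
      if (lb %in% observed) {
        X_obs <- rbind(X_obs, x_all[[lb]])
        y_obs <- c(y_obs, f + rnorm(length(f), 0, noise_sd))
        s_obs <- c(s_obs, rep(lb, length(f)))
      } else {
        pool[[lb]] <- data.frame(x = x_all[[lb]][, 1], f = f,
                                 y = f + rnorm(length(f), 0, noise_sd))
      }
    }
    out <- synthetic_result("linear", observed, new_s, X_obs, y_obs, s_obs,
                            pool, grid, grid_F,
                            list(lengthscale = lengthscale, variance = variance,
                                 noise_sd = noise_sd, seed = seed))
    out$weights <- W
    out
  })
}

#' Horizontally offset sigmoid surfaces
#'
#' Every surface is the same sigmoid shifted horizontally by a per-surface
#' offset drawn uniformly from \[-2, 2\], on the domain \[-3, 3\]. The
#' offset family is nonlinear in its latent structure: no linear
#' combination of a fixed set of latent functions reproduces a horizontal
#' shift, which is what separates the LVMOGP from the LMC here.
#'
#' @inheritParams gen_uncorrelated
#' @param offset_range half-width of the uniform offset distribution.
#' @param amplitude sigmoid amplitude (curve spans -amplitude..amplitude).
#' @param steepness sigmoid steepness.
#' @return object of class `synthetic_mo` (with per-surface `offsets`).
#' @export
gen_offset_sigmoid <- function(n_observed = 2, n_new = 10, n_points = 30,
                               pool_size = 30, offset_range = 2,
                               amplitude = 1, steepness = 2, noise_sd = 0.1,
                               grid_size = 101, seed = 1) {
  sig <- function(x, c) amplitude * (2 / (1 + exp(-steepness * (x - c))) - 1)
  with_seed(seed, {
    observed <- label_seq("obs", n_observed)
    new_s <- label_seq("new", n_new)
    labels <- c(observed, new_s)
    P <- length(labels)
    offsets <- runif(P, -offset_range, offset_range)
    names(offsets) <- labels
    grid <- matrix(seq(-3, 3, length.out = grid_size))
    grid_F <- vapply(labels, function(lb) sig(grid[, 1], offsets[lb]),
                     numeric(grid_size))
    X_obs <- NULL; y_obs <- NULL; s_obs <- NULL
    pool <- list()
    for (lb in labels) {
      n <- if (lb %in% observed) n_points else pool_size
      x <- runif(n, -3, 3)
      f <- sig(x, offsets[lb])
      if (lb %in% observed) {
        X_obs <- rbind(X_obs, matrix(x))
        y_obs <- c(y_obs, f + rnorm(n, 0, noise_sd))
        s_obs <- c(s_obs, rep(lb, n))
      } else {
        pool[[lb]] <- data.frame(x = x, f = f, y = f + rnorm(n, 0, noise_sd))
      }
    }
    out <- synthetic_result("offset", observed, new_s, X_obs, y_obs, s_obs,
                            pool, grid, grid_F,
                            list(offset_range = offset_range,
                                 noise_sd = noise_sd, seed = seed))
    out$offsets <- offsets
    out
  })
}

#' Random-point-addition protocol
#'
#' Returns the dataset after `k` iterations of adding one random pool point
#' per new surface (pool order is the iteration order fixed at generation
#' time), implementing the benchmark protocol used to trace RMSE/NLPD
#' against points per new surface.
#'
#' @param gen a `synthetic_mo` object.
#' @param k number of pool points per new surface to include (0 = only the
#'   observed surfaces).
#' @return a [mo_dataset()].
#' @export
with_pool_points <- function(gen, k) {
  stopifnot(inherits(gen, "synthetic_mo"), k >= 0)
  data <- gen$data
  if (k == 0) return(data)
  for (lb in gen$new_surfaces) {
    pk <- head(gen$pool[[lb]], k)
    data <- mo_append(data, matrix(pk$x), pk$y, rep(lb, nrow(pk)))
  }
  data
}

#' Competitor-like synthetic dataset
#'
#' Emulates the structure of the real competitor-amplification data: P
#' competitor surfaces over a (BP, GC) design space (BP on a log-spaced
#' grid, GC a fraction), 1-6 replicates per location, smooth rate surfaces
#' whose optimum shifts with the competitor (clustered by probe and forward
#' primer, so transfer across related competitors helps), and drift split
#' into two magnitude regimes by reporter chemistry (EvaGreen competitors'
#' drift scaled by `drift_factor`).
#'
#' @param n_surfaces competitor count (34 matches the application).
#' @param n_locations unique design locations per competitor.
#' @param drift_factor drift magnitude ratio between the EvaGreen and probe
#'   regimes.
#' @param rate_noise_sd,drift_noise_sd measurement noise (drift noise is
#'   scaled by the regime factor).
#' @param seed integer seed.
#' @return object of class `competitor_data`: `table` (one row per
#'   measurement), `metadata` (per-competitor probe/primers), `truth`
#'   (noiseless rate/drift functions), `target_surfaces`.
#' @export
gen_competitor_like <- function(n_surfaces = 34, n_locations = 10,
                                drift_factor = 10, rate_noise_sd = 0.05,
                                drift_noise_sd = 0.01, seed = 1) {
  with_seed(seed, {
    ids <- sprintf("C%02d", seq_len(n_surfaces))
    probes <- rep(c("probe", "evagreen"), length.out = n_surfaces)
    fw_pool <- sprintf("FW%d", 1:4)
    rv_pool <- sprintf("RV%d", 1:4)
    primer_fw <- sample(fw_pool, n_surfaces, replace = TRUE)
    primer_rv <- sample(rv_pool, n_surfaces, replace = TRUE)
    bp_grid <- round(exp(seq(log(20), log(220), length.out = 12)))
    gc_grid <- seq(0.25, 0.75, length.out = 11)
    # transformed, roughly centered coordinates
    u1 <- function(bp) (log(bp) - log(66)) / 0.8
    u2 <- function(gc) log(gc / (1 - gc)) / 0.7
    # per-group bump centres: competitors sharing probe+forward primer have
    # nearby rate optima; groups are spread apart
    groups <- paste(probes, primer_fw)
    centers <- list()
    for (g in unique(groups)) centers[[g]] <- rnorm(2, 0, 0.8)
    a <- numeric(n_surfaces); b <- numeric(n_surfaces)
    for (i in seq_len(n_surfaces)) {
      a[i] <- centers[[groups[i]]][1] + rnorm(1, 0, 0.15)
      b[i] <- centers[[groups[i]]][2] + rnorm(1, 0, 0.15)
    }
    drift_scale <- ifelse(probes == "evagreen", drift_factor, 1)
    rate_fn <- function(bp, gc, id) {
      i <- match(id, ids)
      1.2 + 1.8 * exp(-((u1(bp) - a[i])^2 + (u2(gc) - b[i])^2) / (2 * 0.8^2))
    }
    drift_fn <- function(bp, gc, id) {
      i <- match(id, ids)
      drift_scale[i] * (0.05 + 0.03 * tanh(u1(bp)) + 0.02 * u2(gc))
    }
    rep_probs <- c(0.55, 0.2, 0.1, 0.07, 0.05, 0.03)
    rows <- list()
    for (i in seq_len(n_surfaces)) {
      loc <- data.frame(bp = sample(bp_grid, n_locations, replace = TRUE),
                        gc = sample(gc_grid, n_locations, replace = TRUE))
      loc <- unique(loc)
      reps <- sample(1:6, nrow(loc), replace = TRUE, prob = rep_probs)
      loc <- loc[rep(seq_len(nrow(loc)), reps), ]
      n <- nrow(loc)
      rows[[i]] <- data.frame(
        competitor_id = ids[i], probe = probes[i],
        primer_fw = primer_fw[i], primer_rv = primer_rv[i],
        bp = loc$bp, gc = loc$gc,
        rate = rate_fn(loc$bp, loc$gc, ids[i]) + rnorm(n, 0, rate_noise_sd),
        drift = drift_fn(loc$bp, loc$gc, ids[i]) +
          rnorm(n, 0, drift_noise_sd * drift_scale[i]),
        replicate = unlist(lapply(reps, seq_len)),
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    metadata <- data.frame(surface = ids, probe = probes,
                           primer_fw = primer_fw, primer_rv = primer_rv,
                           stringsAsFactors = FALSE)
    n_targets <- min(16, max(1, floor(n_surfaces / 2)))
    obs_counts <- table(factor(tab$competitor_id, levels = ids))
    anchors <- names(sort(obs_counts, decreasing = TRUE))[1:2]
    targets <- setdiff(ids, anchors)
    targets <- targets[seq_len(min(n_targets, length(targets)))]
    structure(list(table = tab, metadata = metadata,
                   truth = list(rate = rate_fn, drift = drift_fn),
                   drift_scale = stats::setNames(drift_scale, ids),
                   target_surfaces = targets, anchor_surfaces = anchors,
                   spec = list(n_surfaces = n_surfaces,
                               drift_factor = drift_factor, seed = seed)),
              class = "competitor_data")
  })
}

#' @export
print.competitor_data <- function(x, ...) {
  cat("Competitor dataset:", nrow(x$table), "measurements on",
      nrow(x$metadata), "competitors (",
      length(unique(paste(x$table$competitor_id, x$table$bp, x$table$gc))),
      "unique locations )\n")
  invisible(x)
}

#' Simulate amplification traces
#'
#' Draws per-well logistic-curve parameters, evaluates the drift-modulated
#' signal over the cycle range and adds Gaussian readout noise.
#'
#' @param n_wells number of traces.
#' @param cycles cycle numbers.
#' @param noise_sd readout noise relative to carrying capacity.
#' @param seed integer seed.
#' @return list with `traces` (well_id, cycle, fluorescence) and `params`
#'   (true per-well parameters).
#' @export
gen_traces <- function(n_wells = 8, cycles = 0:40, noise_sd = 0.01, seed = 1) {
  with_seed(seed, {
    params <- data.frame(
      well_id = sprintf("W%02d", seq_len(n_wells)),
      F0 = runif(n_wells, 0.02, 0.1),
      nu = runif(n_wells, 0.8, 1.2),
      r = runif(n_wells, 0.2, 0.8),
      m = runif(n_wells, -0.05, 0.05),
      stringsAsFactors = FALSE)
    traces <- do.call(rbind, lapply(seq_len(n_wells), function(i) {
      p <- params[i, ]
      sig <- amp_signal(cycles, p$F0, p$nu, p$r, p$m)
      data.frame(well_id = p$well_id, cycle = cycles,
                 fluorescence = sig + rnorm(length(cycles), 0, noise_sd * p$nu),
                 stringsAsFactors = FALSE)
    }))
    list(traces = traces, params = params)
  })
}
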