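#' Configuration for a retrospective Bayesian-optimization experiment
#'
#' @param model one of `"avggp"`, `"mogp"`, `"lmc"`, `"lvmogp"`.
#' @param scenario `"one_at_a_time"` (each target competitor optimized
#'   alone, all other competitors fully in training) or `"learning_many"`
#'   (only the two most-observed competitors in training, all targets
#'   optimized in parallel, one selection per target per sweep).
#' @param start_strategy `"center"` (most central candidate first) or
#'   `"models_choice"` (acquisition argmax where a new-surface posterior
#'   exists; uniform random for MOGP/LMC, which have none).
#' @param target_rate target rate T_rate.
#' @param penalized multiply the expected improvement by the probability of
#'   feasibility for the drift threshold?
#' @param drift_threshold T_drift (required when `penalized`).
#' @param max_iterations selection budget per surface; defaults to 15 for
#'   rate-only optimization, and for the penalized case 20 (learning_many)
#'   or 10 (one_at_a_time).
#' @param seeds integer seeds; each seed is an independent replicate
#'   driving restarts, tie-breaks and random first points (24 in the full
#'   protocol).
#' @param target_surfaces competitor ids to optimize (default: the
#'   dataset's target list).
#' @param Q,QH LMC rank / LVMOGP latent dimensions (2 by convention in the
#'   optimization experiments).
#' @param tolerance closeness to the best point (in rate units) used by
#'   [bo_report()]; 0.05 matches the experimental measurement uncertainty.
#' @param n_restarts,maxit,refit_maxit surrogate optimizer controls (fresh
#'   fit vs warm refits).
#' @return list of class `bo_config`.
#' @export
bo_config <- function(model, scenario = c("one_at_a_time", "learning_many"),
                      start_strategy = c("center", "models_choice"),
                      target_rate, penalized = FALSE, drift_threshold = Inf,
                      max_iterations = NULL, seeds = 1:24,
                      target_surfaces = NULL, Q = 2, QH = 2,
                      tolerance = 0.05, n_restarts = 1, maxit = 100,
                      refit_maxit = 40) {
  scenario <- match.arg(scenario)
  start_strategy <- match.arg(start_strategy)
  stopifnot(model %in% c("avggp", "mogp", "lmc", "lvmogp"))
  if (penalized && is.na(drift_threshold)) {
    stop("penalized optimization needs a drift_threshold", call. = FALSE)
  }
  if (is.null(max_iterations)) {
    max_iterations <- if (!penalized) 15 else if (scenario == "learning_many") 20 else 10
  }
  stopifnot(max_iterations >= 1)
  structure(list(model = model, scenario = scenario,
                 start_strategy = start_strategy, target_rate = target_rate,
                 penalized = penalized, drift_threshold = drift_threshold,
                 max_iterations = max_iterations, seeds = seeds,
                 target_surfaces = target_surfaces, Q = Q, QH = QH,
                 tolerance = tolerance, n_restarts = n_restarts,
                 maxit = maxit, refit_maxit = refit_maxit),
            class = "bo_config")
}

#' First experiment for a surface with no observations
#'
#' `center` picks the candidate closest to the candidate centroid in the
#' transformed input space. `models_choice` maximizes the acquisition under
#' the surrogate's new-surface posterior where one exists (AvgGP: pooled
#' posterior; LVMOGP: latent position from
#' [init_latent_for_new_surface()]); the MOGP and LMC have no posterior on
#' an unseen surface, so the pick is uniform random.
#'
#' @param surrogate fitted surrogate (may be `NULL` for `center`).
#' @param candidates data.frame with `id` and input columns (`u1`, `u2`,
#'   ... matching the model's input space).
#' @param strategy `"center"` or `"models_choice"`.
#' @param ctx an [acq_context()] (models_choice only).
#' @param penalized,drift_model penalize by feasibility of the drift?
#' @param latent_dist new-surface latent Gaussian for the LVMOGP.
#' @param standardizers list with `rate` (and `drift`) standardizers used
#'   to map model outputs back to original units.
#' @param surface label of the new surface (prediction bookkeeping).
#' @param seed integer seed (random picks, tie-breaks).
#' @return selected candidate `id`.
#' @export
choose_first_point <- function(surrogate, candidates, strategy, ctx = NULL,
                               penalized = FALSE, drift_model = NULL,
                               latent_dist = NULL, standardizers = NULL,
                               surface = NULL, seed = 1) {
  if (!nrow(candidates)) stop("empty candidate set", call. = FALSE)
  U <- as.matrix(candidates[, setdiff(names(candidates), "id"), drop = FALSE])
  if (strategy == "center") {
    ctr <- colMeans(U)
    d <- rowSums(sweep(U, 2, ctr)^2)
    return(candidates$id[which.min(d)])
  }
  model_class <- class(surrogate)[1]
  if (model_class %in% c("mogp", "lmc")) {
    return(with_seed(seed, candidates$id[sample.int(nrow(candidates), 1)]))
  }
  po <- if (model_class == "lvmogp") {
    predict_surface(surrogate, U, surface, latent_dist = latent_dist)
  } else {
    predict_surface(surrogate, U, surface)
  }
  rate_mean <- unstandardize_mean(po$mean, standardizers$rate)
  rate_var <- unstandardize_var(po$var, standardizers$rate)
  cand <- data.frame(id = candidates$id, rate_mean = rate_mean,
                     rate_var = pmax(rate_var, 1e-12))
  if (penalized) {
    pd <- if (model_class == "lvmogp") {
      predict_surface(drift_model, U, surface, latent_dist = latent_dist)
    } else {
      predict_surface(drift_model, U, surface)
    }
    cand$drift_mean <- unstandardize_mean(pd$mean, standardizers$drift)
    cand$drift_var <- unstandardize_var(pd$var + pd$noise_variance,
                                        standardizers$drift)
  }
  as.vector(select_next(cand, ctx, penalized = penalized, seed = seed))
}

# fit (or warm-refit) the rate / drift surrogates on the given training rows
bo_fit_models <- function(cdata, config, train_rows, seed, warm = NULL,
                          maxit = NULL) {
  maxit <- if (is.null(maxit)) config$maxit else maxit
  st <- list(rate = fit_standardizer(cdata$table$rate[train_rows]))
  data_rate <- competitor_mo(cdata, "rate", train_rows)
  data_rate$y <- standardize(data_rate$y, st$rate)
  rate_model <- fit_surrogate(config$model, data_rate, seed = seed,
                              Q = config$Q, QH = config$QH,
                              n_restarts = config$n_restarts, maxit = maxit,
                              init = warm$rate_model)
  drift_model <- NULL
  if (config$penalized) {
    st$drift <- fit_standardizer(cdata$table$drift[train_rows])
    data_drift <- competitor_mo(cdata, "drift", train_rows)
    data_drift$y <- standardize(data_drift$y, st$drift)
    drift_model <- fit_surrogate(config$model, data_drift,
                                 seed = sub_seed(seed, "drift"),
                                 Q = config$Q, QH = config$QH,
                                 n_restarts = config$n_restarts, maxit = maxit,
                                 init = warm$drift_model)
  }
  list(rate_model = rate_model, drift_model = drift_model, standardizers = st)
}

# best attainable rate for a surface over its full row pool, with the
# drift penalty folded into "closest to target" for the penalized case
bo_y_best <- function(cdata, surface, config) {
  rows <- which(cdata$table$competitor_id == surface)
  term <- (cdata$table$rate[rows] - config$target_rate)^2
  if (config$penalized) {
    term <- term + pmax(0, cdata$table$drift[rows] - config$drift_threshold)
  }
  cdata$table$rate[rows[which.min(term)]]
}

# acquisition-based selection for one target surface at one iteration
bo_select_for_surface <- function(cdata, config, models, surface, cand_rows,
                                  train_rows, seed, iter) {
  tab <- cdata$table
  U_cand <- transform_inputs(tab$bp[cand_rows], tab$gc[cand_rows])
  obs_rows <- intersect(train_rows, which(tab$competitor_id == surface))
  sel_seed <- sub_seed(seed, "select", surface, iter)
  st <- models$standardizers
  if (!length(obs_rows)) {
    # empty surface: incumbent taken over the whole training pool
    delta0 <- min((tab$rate[train_rows] - config$target_rate)^2)
    ctx <- acq_context(config$target_rate, config$drift_threshold,
                       delta_min = delta0)
    latent_dist <- NULL
    if (config$model == "lvmogp" && config$start_strategy == "models_choice") {
      latent_dist <- init_latent_for_new_surface(
        models$rate_model, cdata$metadata,
        cdata$metadata[cdata$metadata$surface == surface, ])
    }
    cands <- data.frame(id = cand_rows, U_cand)
    return(choose_first_point(models$rate_model, cands,
                              config$start_strategy, ctx = ctx,
                              penalized = config$penalized,
                              drift_model = models$drift_model,
                              latent_dist = latent_dist,
                              standardizers = st, surface = surface,
                              seed = sel_seed))
  }
  po <- predict_surface(models$rate_model, U_cand, surface)
  cand <- data.frame(id = cand_rows,
                     rate_mean = unstandardize_mean(po$mean, st$rate),
                     rate_var = pmax(unstandardize_var(po$var, st$rate), 1e-12))
  if (config$penalized) {
    pd <- predict_surface(models$drift_model, U_cand, surface)
    cand$drift_mean <- unstandardize_mean(pd$mean, st$drift)
    cand$drift_var <- unstandardize_var(pd$var + pd$noise_variance, st$drift)
  }
  delta_min <- min((tab$rate[obs_rows] - config$target_rate)^2)
  gamma_sq <- mean(cand$rate_var)
  ctx <- acq_context(config$target_rate, config$drift_threshold,
                     delta_min = delta_min, gamma_sq = gamma_sq)
  as.vector(select_next(cand, ctx, penalized = config$penalized,
                        seed = sel_seed))
}

#' Retrospective Bayesian optimization on a fixed candidate pool
#'
#' Replays the optimization against pre-collected data: at each iteration
#' the surrogates are refit on the current training rows (warm-started
#' after the first fit), the acquisition is evaluated over the target
#' surface's remaining candidate rows, and the selected measurement moves
#' from the candidate pool into training. In `learning_many` every target
#' surface receives one selection per sweep from models refit once per
#' sweep.
#'
#' @param cdata a `competitor_data` object.
#' @param config a [bo_config()].
#' @return data.frame with one row per (seed, surface, iteration):
#'   selection, observed rate/drift, per-selection regret term, best-so-far
#'   regret and cumulative regret.
#' @export
run_bo <- function(cdata, config) {
  stopifnot(inherits(cdata, "competitor_data"), inherits(config, "bo_config"))
  tab <- cdata$table
  ids <- unique(tab$competitor_id)
  targets <- config$target_surfaces
  if (is.null(targets)) targets <- cdata$target_surfaces
  if (is.null(targets)) stop("no target surfaces specified", call. = FALSE)
  missing <- setdiff(targets, ids)
  if (length(missing)) stop("surfaces absent from data: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  counts <- table(factor(tab$competitor_id, levels = ids))
  anchors <- names(sort(counts[setdiff(ids, targets)], decreasing = TRUE))
  if (config$scenario == "learning_many" && length(anchors) < 2) {
    stop("learning_many needs at least two non-target anchor surfaces", call. = FALSE)
  }
  records <- list()
  for (seed in config$seeds) {
    if (config$scenario == "one_at_a_time") {
      for (srf in targets) {
        run <- bo_single_surface(cdata, config, srf,
                                 train_rows = which(tab$competitor_id != srf),
                                 seed = seed)
        records[[length(records) + 1]] <- run
      }
    } else {
      records[[length(records) + 1]] <-
        bo_learning_many(cdata, config, targets, anchors[1:2], seed)
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

bo_finalize_records <- function(recs, cdata, config, seed) {
  out <- list()
  for (srf in unique(recs$surface)) {
    r <- recs[recs$surface == srf, , drop = FALSE]
    r <- r[order(r$iteration), , drop = FALSE]
    y_best <- bo_y_best(cdata, srf, config)
    tr <- regret_trace(r$y_rate, r$y_drift, y_best, config$drift_threshold)
    r$y_best <- y_best
    r$sel_term <- tr$per_selection
    r$regret <- tr$regret
    r$cum_regret <- tr$cumulative
    out[[srf]] <- r
  }
  res <- do.call(rbind, out)
  res$model <- config$model
  res$scenario <- config$scenario
  res$strategy <- config$start_strategy
  res$penalized <- config$penalized
  res$seed <- seed
  res[, c("model", "scenario", "strategy", "penalized", "seed", "surface",
          "iteration", "candidate_id", "y_rate", "y_drift", "y_best",
          "sel_term", "regret", "cum_regret")]
}

bo_single_surface <- function(cdata, config, surface, train_rows, seed) {
  tab <- cdata$table
  cand_rows <- which(tab$competitor_id == surface)
  recs <- NULL
  warm <- NULL
  for (iter in seq_len(config$max_iterations)) {
    if (!length(cand_rows)) break
    models <- bo_fit_models(cdata, config, train_rows,
                            seed = sub_seed(seed, "fit", surface, iter),
                            warm = warm,
                            maxit = if (iter == 1) config$maxit else config$refit_maxit)
    warm <- models
    pick <- bo_select_for_surface(cdata, config, models, surface, cand_rows,
                                  train_rows, seed, iter)
    recs <- rbind(recs, data.frame(surface = surface, iteration = iter,
                                   candidate_id = pick,
                                   y_rate = tab$rate[pick],
                                   y_drift = tab$drift[pick],
                                   stringsAsFactors = FALSE))
    train_rows <- c(train_rows, pick)
    cand_rows <- setdiff(cand_rows, pick)
  }
  bo_finalize_records(recs, cdata, config, seed)
}

bo_learning_many <- function(cdata, config, targets, anchors, seed) {
  tab <- cdata$table
  train_rows <- which(tab$competitor_id %in% anchors)
  cand <- lapply(targets, function(s) which(tab$competitor_id == s))
  names(cand) <- targets
  recs <- NULL
  warm <- NULL
  for (iter in seq_len(config$max_iterations)) {
    if (!any(lengths(cand) > 0)) break
    models <- bo_fit_models(cdata, config, train_rows,
                            seed = sub_seed(seed, "fit", iter),
                            warm = warm,
                            maxit = if (iter == 1) config$maxit else config$refit_maxit)
    warm <- models
    picks <- integer(0)
    for (srf in targets) {
      if (!length(cand[[srf]])) next
      pick <- bo_select_for_surface(cdata, config, models, srf, cand[[srf]],
                                    train_rows, seed, iter)
      picks <- c(picks, pick)
      recs <- rbind(recs, data.frame(surface = srf, iteration = iter,
                                     candidate_id = pick,
                                     y_rate = tab$rate[pick],
                                     y_drift = tab$drift[pick],
                                     stringsAsFactors = FALSE))
      cand[[srf]] <- setdiff(cand[[srf]], pick)
    }
    train_rows <- c(train_rows, picks)
  }
  bo_finalize_records(recs, cdata, config, seed)
}

#' Summary statistics of Bayesian-optimization runs
#'
#' Per (model, scenario, strategy): mean iterations to get within the
#' tolerance of the best point's rate, the fraction of runs whose first
#' selection is already within tolerance, the fraction of runs that reach
#' the best point at all, and the mean final cumulative regret.
#'
#' @param results output of [run_bo()] (possibly several configs row-bound).
#' @param tolerance closeness in rate units (default 0.05).
#' @return data.frame of summary rows.
#' @export
bo_report <- function(results, tolerance = 0.05) {
  key <- interaction(results$model, results$scenario, results$strategy,
                     results$penalized, drop = TRUE)
  out <- lapply(split(results, key), function(g) {
    runs <- split(g, interaction(g$seed, g$surface, drop = TRUE))
    iters <- vapply(runs, function(r) {
      r <- r[order(r$iteration), ]
      hit <- which(abs(r$y_rate - r$y_best) <= tolerance)
      if (length(hit)) r$iteration[hit[1]] else NA_real_
    }, 0)
    final_cum <- vapply(runs, function(r) max(r$cum_regret), 0)
    first_best <- vapply(runs, function(r) {
      r <- r[order(r$iteration), ]
      abs(r$y_rate[1] - r$y_best[1]) <= tolerance
    }, TRUE)
    data.frame(model = g$model[1], scenario = g$scenario[1],
               strategy = g$strategy[1], penalized = g$penalized[1],
               n_runs = length(runs),
               mean_iters_to_tol = mean(iters, na.rm = TRUE),
               frac_reaching_tol = mean(!is.na(iters)),
               frac_first_to_best = mean(first_best),
               mean_final_cum_regret = mean(final_cum),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
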