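test_that("RMSE and NLPD match their closed forms", {
  y <- withr::with_seed(7, rnorm(10))
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y + 0.3, y), 0.3)
  mu <- withr::with_seed(8, rnorm(10))
  expect_equal(rmse(mu, y), sqrt(mean((mu - y)^2)))
  # unit-density point: y = mu, variance 1/(2*pi)
  expect_equal(nlpd(1, 1 / (2 * pi), 1), 0)
  # overdispersion penalty when predictions are exact
  expect_gt(nlpd(y, 4, y), nlpd(y, 1 / (2 * pi), y))
  # Gaussian log-density oracle
  v <- withr::with_seed(9, runif(10, 0.1, 2))
  expect_equal(nlpd(mu, v, y),
               -mean(dnorm(y, mu, sqrt(v), log = TRUE)))
  expect_error(nlpd(mu, c(-1, v[-1]), y), "variance")
})

test_that("regret traces plateau at the best point and accumulate the drift penalty", {
  # first selection is the best point with feasible drift: flat afterwards
  tr <- regret_trace(y_rate = c(2.5, 3, 1), y_drift = c(0.1, 0.1, 0.1),
                     y_best = 2.5, drift_threshold = 0.2)
  expect_equal(tr$regret, c(0, 0, 0))
  expect_equal(tr$cumulative, c(0, 0, 0))
  # exceeding the drift threshold by 0.1 adds exactly 0.1
  tr2 <- regret_trace(y_rate = 2.5, y_drift = 0.3, y_best = 2.5,
                      drift_threshold = 0.2)
  expect_equal(tr2$per_selection, 0.1)
  # best-so-far regret is non-increasing
  tr3 <- regret_trace(y_rate = c(4, 3, 3.5, 2.6), y_best = 2.5)
  expect_true(all(diff(tr3$regret) <= 0))
  expect_equal(tr3$cumulative, cumsum(tr3$regret))
})

test_that("cross-validation anchors the two largest competitors and errors on empty test sets", {
  cdata <- gen_competitor_like(n_surfaces = 5, n_locations = 5, seed = 2)
  res <- cross_validate(cdata, fractions = 0.3, repeats = 2,
                        models = c("avggp", "mogp"), outputs = "rate",
                        seed = 1, maxit = 40)
  expect_equal(nrow(res), 2 * 2)
  expect_true(all(res$rmse > 0))
  expect_true(all(is.finite(res$nlpd)))
  counts <- table(cdata$table$competitor_id)
  anchors <- names(sort(counts, decreasing = TRUE))[1:2]
  # anchors fully in training: n_train at least their row count plus one per rest
  expect_true(all(res$n_train >= sum(counts[anchors]) + (5 - 2)))
  expect_error(cross_validate(cdata, fractions = 1, repeats = 1,
                              models = "avggp", outputs = "rate"),
               "no test rows")
})

test_that("cross-validation is reproducible for a fixed seed", {
  cdata <- gen_competitor_like(n_surfaces = 4, n_locations = 4, seed = 5)
  r1 <- cross_validate(cdata, fractions = 0.4, repeats = 2, models = "mogp",
                       outputs = "rate", seed = 11, maxit = 40)
  r2 <- cross_validate(cdata, fractions = 0.4, repeats = 2, models = "mogp",
                       outputs = "rate", seed = 11, maxit = 40)
  expect_identical(r1, r2)
})

test_that("the center strategy picks the middle of a symmetric grid", {
  gr <- expand.grid(u1 = c(-1, 0, 1), u2 = c(-1, 0, 1))
  cands <- data.frame(id = 1:9, gr)
  pick <- choose_first_point(NULL, cands, "center")
  expect_equal(pick, which(gr$u1 == 0 & gr$u2 == 0))
})

test_that("models_choice first points are random for MOGP and reproducible", {
  d <- two_surface_data()
  fit <- fit_mogp(d, n_restarts = 1, seed = 1)
  cands <- data.frame(id = 1:6, u1 = runif(6))
  p1 <- choose_first_point(fit, cands, "models_choice", seed = 21)
  p2 <- choose_first_point(fit, cands, "models_choice", seed = 21)
  expect_equal(p1, p2)
  picks <- vapply(1:30, function(s) {
    choose_first_point(fit, cands, "models_choice", seed = s)
  }, 0)
  expect_gt(length(unique(picks)), 1)
})

test_that("retrospective BO respects the candidate pool and is reproducible", {
  cdata <- gen_competitor_like(n_surfaces = 5, n_locations = 4, seed = 7)
  targets <- cdata$target_surfaces[1]
  config <- bo_config(model = "mogp", scenario = "one_at_a_time",
                      start_strategy = "center", target_rate = 2.5,
                      seeds = c(1, 2), target_surfaces = targets,
                      max_iterations = 4, maxit = 40, refit_maxit = 20)
  res <- run_bo(cdata, config)
  res2 <- run_bo(cdata, config)
  expect_identical(res, res2)
  rows_target <- which(cdata$table$competitor_id == targets)
  for (s in unique(res$seed)) {
    sel <- res$candidate_id[res$seed == s]
    expect_true(all(sel %in% rows_target))
    expect_equal(anyDuplicated(sel), 0)
  }
  expect_true(all(diff(res$iteration[res$seed == 1]) == 1))
  expect_true(all(res$regret >= 0))
})

test_that("a single-candidate pool terminates after one selection", {
  cdata <- gen_competitor_like(n_surfaces = 4, n_locations = 4, seed = 9)
  tgt <- cdata$target_surfaces[1]
  keep <- c(which(cdata$table$competitor_id != tgt),
            which(cdata$table$competitor_id == tgt)[1])
  cdata$table <- cdata$table[sort(keep), ]
  config <- bo_config(model = "avggp", scenario = "one_at_a_time",
                      start_strategy = "center", target_rate = 2.5,
                      seeds = 1, target_surfaces = tgt, max_iterations = 5,
                      maxit = 30)
  res <- run_bo(cdata, config)
  expect_equal(nrow(res), 1)
})

test_that("penalized and single-objective runs coincide when the threshold is infinite", {
  cdata <- gen_competitor_like(n_surfaces = 4, n_locations = 4, seed = 13)
  tgt <- cdata$target_surfaces[1]
  base <- bo_config(model = "mogp", scenario = "one_at_a_time",
                    start_strategy = "center", target_rate = 2.5, seeds = 1,
                    target_surfaces = tgt, max_iterations = 3, maxit = 30,
                    refit_maxit = 20)
  pen <- bo_config(model = "mogp", scenario = "one_at_a_time",
                   start_strategy = "center", target_rate = 2.5,
                   penalized = TRUE, drift_threshold = Inf, seeds = 1,
                   target_surfaces = tgt, max_iterations = 3, maxit = 30,
                   refit_maxit = 20)
  r1 <- run_bo(cdata, base)
  r2 <- run_bo(cdata, pen)
  expect_equal(r1$candidate_id, r2$candidate_id)
  expect_equal(r1$regret, r2$regret)
})

test_that("learning_many selects one point per target per sweep", {
  cdata <- gen_competitor_like(n_surfaces = 6, n_locations = 4, seed = 15)
  targets <- cdata$target_surfaces[1:2]
  config <- bo_config(model = "avggp", scenario = "learning_many",
                      start_strategy = "center", target_rate = 2.5,
                      seeds = 1, target_surfaces = targets,
                      max_iterations = 3, maxit = 30, refit_maxit = 20)
  res <- run_bo(cdata, config)
  per_iter <- table(res$iteration)
  expect_true(all(per_iter == length(targets)))
})

test_that("bo_report summarizes iterations-to-tolerance and plateaus", {
  fake <- data.frame(model = "mogp", scenario = "one_at_a_time",
                     strategy = "center", penalized = FALSE, seed = 1,
                     surface = "s", iteration = 1:3,
                     candidate_id = 1:3,
                     y_rate = c(3.0, 2.52, 2.5), y_drift = 0,
                     y_best = 2.5, sel_term = c(0.25, 4e-4, 0),
                     regret = c(0.25, 4e-4, 0),
                     cum_regret = cumsum(c(0.25, 4e-4, 0)))
  rep <- bo_report(fake, tolerance = 0.05)
  expect_equal(rep$mean_iters_to_tol, 2)
  expect_equal(rep$frac_first_to_best, 0)
  expect_equal(rep$mean_final_cum_regret, sum(c(0.25, 4e-4, 0)))
})

test_that("bo_config validates its inputs and applies iteration defaults", {
  expect_error(bo_config(model = "mogp", target_rate = 2, penalized = TRUE,
                         drift_threshold = NA), "drift_threshold")
  c1 <- bo_config(model = "mogp", target_rate = 2)
  expect_equal(c1$max_iterations, 15)
  c2 <- bo_config(model = "mogp", target_rate = 2, penalized = TRUE,
                  drift_threshold = 0.2, scenario = "learning_many")
  expect_equal(c2$max_iterations, 20)
  c3 <- bo_config(model = "mogp", target_rate = 2, penalized = TRUE,
                  drift_threshold = 0.2, scenario = "one_at_a_time")
  expect_equal(c3$max_iterations, 10)
})

test_that("AvgGP barely improves with more training data on distinct surfaces", {
  # on mutually independent surfaces the pooled model's error is dominated
  # by between-surface dispersion it cannot represent
  vals <- NULL
  for (ds in 1:3) {
    gen <- gen_uncorrelated(seed = 700 + ds)
    res <- benchmark_models(gen, checkpoints = c(2, 30), models = "avggp",
                            seed = ds)
    vals <- rbind(vals, tapply(res$rmse, res$checkpoint, mean))
  }
  m <- colMeans(vals)
  rel_change <- abs(m[2] - m[1]) / m[1]
  expect_lt(rel_change, 0.10)
})
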