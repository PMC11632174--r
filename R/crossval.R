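# fit any of the four surrogates behind one face
fit_surrogate <- function(model, data, seed = 1, Q = 2, QH = 2,
                          n_restarts = 2, maxit = 150, init = NULL) {
  switch(model,
         avggp = fit_avggp(data, n_restarts = n_restarts, seed = seed,
                           maxit = maxit),
         mogp = fit_mogp(data, n_restarts = n_restarts, seed = seed,
                         maxit = maxit),
         lmc = fit_lmc(data, Q = min(Q, sum(data$surface_labels %in% data$surface)),
                       n_restarts = n_restarts, seed = seed, maxit = maxit),
         lvmogp = fit_lvmogp(data, QH = QH, n_restarts = n_restarts,
                             seed = seed, maxit = maxit, init = init),
         stop("unknown model: ", model, call. = FALSE))
}

#' Cross-validation of the surrogate models on competitor data
#'
#' Replicates the transfer-learning cross-validation protocol: for each
#' repeat, the training set contains all rows of the two competitors with
#' the most observations (the anchors) plus a random fraction of the
#' remaining rows, forced to keep at least one row per competitor; the four
#' surrogates are fitted per output on standardized observations and scored
#' on the held-out rows by RMSE and NLPD (observation scale, original
#' units).
#'
#' @param cdata a `competitor_data` object.
#' @param fractions fractions of the non-anchor rows placed in training
#'   (1.0 would leave no test rows and is an error).
#' @param repeats random resamplings per fraction (70 in the full
#'   protocol).
#' @param models subset of `c("avggp", "mogp", "lmc", "lvmogp")`.
#' @param outputs subset of `c("rate", "drift")`.
#' @param Q,QH LMC rank / LVMOGP latent dimensions (10 in the full
#'   protocol).
#' @param seed integer seed.
#' @param n_restarts,maxit optimizer controls passed to the fitters.
#' @return data.frame with columns model, fraction, repeat_id, output,
#'   rmse, nlpd, n_train, n_test.
#' @export
cross_validate <- function(cdata, fractions = c(0.2, 0.35, 0.5),
                           repeats = 10,
                           models = c("avggp", "mogp", "lmc", "lvmogp"),
                           outputs = c("rate", "drift"),
                           Q = 10, QH = 10, seed = 1,
                           n_restarts = 1, maxit = 120) {
  stopifnot(inherits(cdata, "competitor_data"))
  tab <- cdata$table
  ids <- unique(tab$competitor_id)
  if (length(ids) < 3) stop("need at least three competitors", call. = FALSE)
  counts <- table(factor(tab$competitor_id, levels = ids))
  anchors <- names(sort(counts, decreasing = TRUE))[1:2]
  rest_rows <- which(!tab$competitor_id %in% anchors)
  out <- list()
  for (fr in fractions) {
    for (rep_i in seq_len(repeats)) {
      split_seed <- sub_seed(seed, "cv", round(fr * 1000), rep_i)
      train_rest <- with_seed(split_seed, {
        k <- floor(fr * length(rest_rows))
        sel <- if (k > 0) sample(rest_rows, k) else integer(0)
        # force at least one row per competitor
        for (id in setdiff(ids, anchors)) {
          rows_id <- which(tab$competitor_id == id)
          if (!any(sel %in% rows_id)) sel <- c(sel, sample(rows_id, 1))
        }
        sel
      })
      train_rows <- sort(c(which(tab$competitor_id %in% anchors), train_rest))
      test_rows <- setdiff(seq_len(nrow(tab)), train_rows)
      if (!length(test_rows)) {
        stop("fraction leaves no test rows", call. = FALSE)
      }
      for (output in outputs) {
        st <- fit_standardizer(tab[[output]][train_rows])
        data_tr <- competitor_mo(cdata, output, train_rows)
        data_tr$y <- standardize(data_tr$y, st)
        U_te <- transform_inputs(tab$bp[test_rows], tab$gc[test_rows])
        y_te <- tab[[output]][test_rows]
        s_te <- tab$competitor_id[test_rows]
        for (model in models) {
          fit <- fit_surrogate(model, data_tr,
                               seed = sub_seed(split_seed, model, output),
                               Q = Q, QH = QH, n_restarts = n_restarts,
                               maxit = maxit)
          mu <- numeric(length(test_rows)); vv <- numeric(length(test_rows))
          for (lb in unique(s_te)) {
            j <- which(s_te == lb)
            po <- predict_surface(fit, U_te[j, , drop = FALSE], lb)
            mu[j] <- unstandardize_mean(po$mean, st)
            vv[j] <- unstandardize_var(po$var + po$noise_variance, st)
          }
          out[[length(out) + 1]] <- data.frame(
            model = model, fraction = fr, repeat_id = rep_i, output = output,
            rmse = rmse(mu, y_te), nlpd = nlpd(mu, vv, y_te),
            n_train = length(train_rows), n_test = length(test_rows),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}
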