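#' Coefficient of determination
#'
#' R-squared computed exactly as 1 - sum((yhat - y)^2) / sum((y - ybar)^2);
#' can be negative when predictions are worse than the observed mean.
#'
#' @param observed numeric vector of observed outcomes.
#' @param predicted numeric vector of predictions, same length.
#' @return a single real number.
#' @export
evaluate_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 2)
    stop("need at least two observations", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("zero variance in observed outcomes; R-squared undefined",
         call. = FALSE)
  1 - sum((predicted - observed)^2) / ss_tot
}

#' Fit the baseline regression suite
#'
#' Fits an ordinary linear regression plus four classical non-linear
#' families (polynomial regression, random forest, support vector
#' regression, gradient boosting) of contact frequency on the two GReX
#' features, selecting each family's hyperparameter on an internal
#' train-validation split by validation R-squared.
#'
#' Default grids: polynomial degree 1-10; random forest 10-100 trees;
#' SVR epsilon 0.1-1; gradient boosting 10-300 boosting stages.
#'
#' @param train a `pair_dataset`.
#' @param val_fraction validation fraction of the internal split.
#' @param grids named list overriding the default hyperparameter grids
#'   (names: polynomial, random_forest, svr, gradient_boosting).
#' @param families character vector of families to fit (default all five).
#' @param seed integer seed for the split and the stochastic learners.
#' @return list with `table` (data.frame: model, best_hyperparameter,
#'   val_r2) and `models` (the refitted best predictor per family, each a
#'   function over a pair dataset).
#' @export
fit_baseline_suite <- function(train, val_fraction = 0.2, grids = list(),
                               families = c("linear", "polynomial",
                                            "random_forest", "svr",
                                            "gradient_boosting"),
                               seed = 1L) {
  stopifnot(nrow(train) > 10)
  families <- match.arg(families, several.ok = TRUE)
  defaults <- list(polynomial = 1:10,
                   random_forest = seq(10L, 100L, by = 10L),
                   svr = seq(0.1, 1, by = 0.1),
                   gradient_boosting = c(10L, 50L, 100L, 150L, 200L, 250L,
                                         300L))
  grids <- utils::modifyList(defaults, grids)
  for (fam in setdiff(names(grids), "linear"))
    if (length(grids[[fam]]) == 0)
      stop("empty hyperparameter grid for ", fam, call. = FALSE)
  sp <- split_train_test(train, fraction = 1 - val_fraction, seed = seed)
  tr <- sp$train; va <- sp$test
  Xtr <- cbind(u = tr$grex_up, v = tr$grex_down)
  Xva <- cbind(u = va$grex_up, v = va$grex_down)
  ytr <- tr$contact; yva <- va$contact
  rows <- list(); models <- list()
  score <- function(pred) evaluate_r2(yva, pred)
  if ("linear" %in% families) {
    lin_fit <- stats::lm(y ~ u + v, data = data.frame(Xtr, y = ytr))
    r2 <- score(stats::predict(lin_fit, data.frame(Xva)))
    rows[["linear"]] <- data.frame(model = "linear",
                                   best_hyperparameter = NA_real_,
                                   val_r2 = r2)
    models[["linear"]] <- local({
      fit <- lin_fit
      function(pairs) stats::predict(fit, data.frame(u = pairs$grex_up,
                                                     v = pairs$grex_down))
    })
  }
  if ("polynomial" %in% families) {
    best <- NULL
    for (d in grids$polynomial) {
      fit <- stats::lm(y ~ stats::poly(u, v, degree = d),
                       data = data.frame(Xtr, y = ytr))
      r2 <- score(stats::predict(fit, data.frame(Xva)))
      if (is.null(best) || r2 > best$r2) best <- list(d = d, r2 = r2,
                                                      fit = fit)
    }
    rows[["polynomial"]] <- data.frame(model = "polynomial",
                                       best_hyperparameter = best$d,
                                       val_r2 = best$r2)
    models[["polynomial"]] <- local({
      fit <- best$fit
      function(pairs) stats::predict(fit, data.frame(u = pairs$grex_up,
                                                     v = pairs$grex_down))
    })
  }
  if ("random_forest" %in% families) {
    best <- NULL
    for (nt in grids$random_forest) {
      set.seed(seed)
      fit <- randomForest::randomForest(Xtr, ytr, ntree = nt)
      r2 <- score(stats::predict(fit, Xva))
      if (is.null(best) || r2 > best$r2) best <- list(nt = nt, r2 = r2,
                                                      fit = fit)
    }
    rows[["random_forest"]] <- data.frame(model = "random_forest",
                                          best_hyperparameter = best$nt,
                                          val_r2 = best$r2)
    models[["random_forest"]] <- local({
      fit <- best$fit
      function(pairs) stats::predict(fit, cbind(u = pairs$grex_up,
                                                v = pairs$grex_down))
    })
  }
  if ("svr" %in% families) {
    best <- NULL
    for (ep in grids$svr) {
      fit <- e1071::svm(Xtr, ytr, epsilon = ep)
      r2 <- score(stats::predict(fit, Xva))
      if (is.null(best) || r2 > best$r2) best <- list(ep = ep, r2 = r2,
                                                      fit = fit)
    }
    rows[["svr"]] <- data.frame(model = "svr",
                                best_hyperparameter = best$ep,
                                val_r2 = best$r2)
    models[["svr"]] <- local({
      fit <- best$fit
      function(pairs) stats::predict(fit, cbind(u = pairs$grex_up,
                                                v = pairs$grex_down))
    })
  }
  if ("gradient_boosting" %in% families) {
    best <- NULL
    for (nr in grids$gradient_boosting) {
      set.seed(seed)
      fit <- xgboost::xgboost(Xtr, ytr, nrounds = nr,
                              objective = "reg:squarederror",
                              nthreads = 1, seed = seed)
      r2 <- score(stats::predict(fit, Xva))
      if (is.null(best) || r2 > best$r2) best <- list(nr = nr, r2 = r2,
                                                      fit = fit)
    }
    rows[["gradient_boosting"]] <- data.frame(model = "gradient_boosting",
                                              best_hyperparameter = best$nr,
                                              val_r2 = best$r2)
    models[["gradient_boosting"]] <- local({
      fit <- best$fit
      function(pairs) stats::predict(fit, cbind(u = pairs$grex_up,
                                                v = pairs$grex_down))
    })
  }
  list(table = do.call(rbind, unname(rows)), models = models)
}

#' Grid search over network candidates with k-fold cross-validation
#'
#' Evaluates each (architecture, training configuration) candidate by
#' k-fold cross-validation on the training data, recording the mean
#' validation score, and ranks candidates by the selection metric
#' (R-squared maximized or RMSE minimized). Ties break toward fewer
#' learnable parameters, then earlier candidate order. Candidates whose
#' training produces a non-finite loss are marked failed and excluded from
#' the ranking.
#'
#' @param train a `pair_dataset`.
#' @param space list of candidates, each a list with elements
#'   `architecture` and `config` (e.g. from [nn_preset()]).
#' @param folds cross-validation folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return list with `results` (data.frame: candidate, mean_r2, mean_rmse,
#'   n_parameters, failed) ordered by rank, and `best` (the winning
#'   candidate).
#' @export
nn_grid_search <- function(train, space, folds = 5L, seed = 1L) {
  if (length(space) == 0)
    stop("empty candidate space", call. = FALSE)
  n <- nrow(train)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  res <- lapply(seq_along(space), function(k) {
    cand <- space[[k]]
    metric <- cand$config$selection_metric
    r2s <- rmses <- numeric(folds)
    failed <- FALSE
    for (f in seq_len(folds)) {
      tr <- train[fold_id != f, , drop = FALSE]
      va <- train[fold_id == f, , drop = FALSE]
      fit <- tryCatch(train_nn(tr, cand$architecture, cand$config),
                      error = function(e) NULL)
      if (is.null(fit)) { failed <- TRUE; break }
      pred <- predict(fit, va)
      r2s[f] <- evaluate_r2(va$contact, pred)
      rmses[f] <- sqrt(mean((pred - va$contact)^2))
    }
    data.frame(candidate = k,
               mean_r2 = if (failed) NA_real_ else mean(r2s),
               mean_rmse = if (failed) NA_real_ else mean(rmses),
               n_parameters = nn_n_parameters(cand$architecture),
               metric = metric,
               failed = failed)
  })
  res <- do.call(rbind, res)
  ok <- res[!res$failed, , drop = FALSE]
  if (nrow(ok) == 0)
    stop("all candidates failed during training", call. = FALSE)
  key <- ifelse(ok$metric == "rmse", ok$mean_rmse, -ok$mean_r2)
  ord <- order(key, ok$n_parameters, ok$candidate)
  ranked <- ok[ord, , drop = FALSE]
  results <- rbind(ranked, res[res$failed, , drop = FALSE])
  rownames(results) <- NULL
  list(results = results, best = space[[ranked$candidate[1]]])
}
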