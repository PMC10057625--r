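#' Fit a bagged ensemble of regression trees
#'
#' Bootstrap-aggregated CART trees with per-split predictor sampling
#' (`n_predictors`), squared-error impurity, exact greedy splits.
#'
#' @param x numeric feature matrix (rows = cycles).
#' @param y numeric target (mg/dL).
#' @param n_learners number of trees.
#' @param min_leaf_size minimum observations per leaf.
#' @param n_predictors predictors sampled per split (capped at `ncol(x)`).
#' @return object of class `ppg_ensemble`.
#' @export
fit_bag <- function(x, y, n_learners, min_leaf_size = 1,
                    n_predictors = ncol(x)) {
  x <- as.matrix(x)
  n <- nrow(x)
  trees <- lapply(seq_len(n_learners), function(b) {
    rows <- sample.int(n, n, replace = TRUE) - 1L
    fit_tree_cpp(x, y, rows, as.integer(min_leaf_size),
                 as.integer(min(n_predictors, ncol(x))))
  })
  structure(list(method = "bag", trees = trees,
                 weights = rep(1 / n_learners, n_learners), base = 0,
                 feature_names = colnames(x)), class = "ppg_ensemble")
}

#' Fit a least-squares boosted ensemble of regression trees
#'
#' Gradient boosting with squared-error loss (LSBoost): each tree fits
#' the current residuals on the full sample with all predictors, and is
#' added with step `learning_rate`.
#'
#' @inheritParams fit_bag
#' @param learning_rate shrinkage in (0, 1].
#' @export
fit_lsboost <- function(x, y, n_learners, min_leaf_size = 1,
                        learning_rate = 0.1) {
  x <- as.matrix(x)
  n <- nrow(x)
  base <- mean(y)
  fit <- rep(base, n)
  rows <- seq_len(n) - 1L
  trees <- vector("list", n_learners)
  for (b in seq_len(n_learners)) {
    tr <- fit_tree_cpp(x, y - fit, rows, as.integer(min_leaf_size),
                       ncol(x))
    trees[[b]] <- tr
    fit <- fit + learning_rate *
      predict_ensemble_cpp(list(tr), x, 1.0, 0.0)
  }
  structure(list(method = "lsboost", trees = trees,
                 weights = rep(learning_rate, n_learners), base = base,
                 feature_names = colnames(x)), class = "ppg_ensemble")
}

#' @export
predict.ppg_ensemble <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  predict_ensemble_cpp(object$trees, x, object$weights, object$base)
}

#' Day-wise train/test split of a feature table
#'
#' Routes cycle rows by recording day so no recording contributes to
#' both sets. The default mirrors a 7-train / 2-test day protocol.
#'
#' @param feature_table table with a `day` column (one row per cycle).
#' @param train_days,test_days disjoint day-index vectors.
#' @return list with `train` and `test` tables.
#' @export
split_by_day <- function(feature_table, train_days = 1:7,
                         test_days = 8:9) {
  if (length(intersect(train_days, test_days)) > 0)
    stop("train_days and test_days must be disjoint")
  train <- feature_table[feature_table$day %in% train_days, , drop = FALSE]
  test <- feature_table[feature_table$day %in% test_days, , drop = FALSE]
  if (nrow(train) == 0) stop("empty training set for the requested days")
  if (nrow(test) == 0) stop("empty test set for the requested days")
  list(train = train, test = test)
}

#' The hyperparameter search space of the ensemble models
#'
#' Number of learners 10-500, minimum leaf size 1-18, predictors
#' sampled per split 1-19 (bagging only; capped at the 18 features at
#' fit time), and - for LSBoost, whose learning rate the original
#' search space does not list - a log-uniform learning rate in
#' `[0.01, 1]`.
#'
#' @export
hyperparameter_space <- function() {
  list(n_learners = c(10L, 500L), min_leaf_size = c(1L, 18L),
       n_predictors = c(1L, 19L), learning_rate = c(0.01, 1))
}

draw_params <- function(method, space) {
  p <- list(
    method = method,
    n_learners = sample(space$n_learners[1]:space$n_learners[2], 1),
    min_leaf_size = sample(space$min_leaf_size[1]:space$min_leaf_size[2], 1)
  )
  if (method == "bag") {
    p$n_predictors <- sample(space$n_predictors[1]:space$n_predictors[2], 1)
  } else {
    lr <- exp(runif(1, log(space$learning_rate[1]),
                    log(space$learning_rate[2])))
    p$learning_rate <- lr
  }
  p
}

fit_with_params <- function(x, y, p) {
  if (p$method == "bag")
    fit_bag(x, y, p$n_learners, p$min_leaf_size, p$n_predictors)
  else
    fit_lsboost(x, y, p$n_learners, p$min_leaf_size, p$learning_rate)
}

#' Randomised hyperparameter search with grouped cross-validation
#'
#' Both ensemble methods (bagging and least-squares boosting) are
#' searched with `n_draws` random draws each from
#' [hyperparameter_space()]. Each draw is scored by the mean RMSE over
#' `folds`-fold cross-validation in which folds are formed at the
#' recording level, so near-duplicate cycles from one recording never
#' straddle a train/validation boundary. The best draw is refit on all
#' training rows.
#'
#' For tractability the CV search may run on a row subsample
#' (`search_max_rows`, sampled fold-proportionally); the final refit
#' always uses every training row.
#'
#' @param train feature table (one row per cycle) with columns
#'   [feature_names()], `bgl_label` and `recording_id`.
#' @param methods which ensemble methods to search.
#' @param n_draws random draws per method.
#' @param folds number of CV folds.
#' @param seed integer seed; fixes folds, draws and fits.
#' @param search_max_rows row cap for the CV search (`Inf` to disable).
#' @param space search ranges, see [hyperparameter_space()].
#' @return object of class `ppg_model`: `method`, `params`, `cv_rmse`,
#'   `ensemble`, `feature_names`, `subject_id`.
#' @export
tune_and_train <- function(train, methods = c("bag", "lsboost"),
                           n_draws = 50, folds = 5, seed = 1,
                           search_max_rows = 1000,
                           space = hyperparameter_space()) {
  feats <- feature_names()
  y_all <- train$bgl_label
  if (length(unique(y_all)) < 2)
    stop("degenerate target: all training BGLs identical")
  if (nrow(train) < 2 * folds)
    stop("too few training rows for the requested folds")
  x_all <- as.matrix(as.data.frame(train)[, feats, drop = FALSE])
  with_seed(seed, {
    rec <- as.character(train$recording_id)
    urec <- unique(rec)
    fold_of_rec <- sample(rep_len(seq_len(folds), length(urec)))
    names(fold_of_rec) <- urec
    fold <- fold_of_rec[rec]

    keep <- seq_along(y_all)
    if (is.finite(search_max_rows) && length(keep) > search_max_rows) {
      frac <- search_max_rows / length(keep)
      keep <- unlist(lapply(seq_len(folds), function(f) {
        i <- which(fold == f)
        sample(i, min(length(i), max(2, round(length(i) * frac))))
      }))
    }
    xs <- x_all[keep, , drop = FALSE]
    ys <- y_all[keep]
    fs <- fold[keep]

    best <- NULL
    for (method in methods) {
      for (d in seq_len(n_draws)) {
        p <- draw_params(method, space)
        errs <- vapply(seq_len(folds), function(f) {
          tr <- fs != f
          if (sum(tr) < 2 || sum(!tr) < 1) return(NA_real_)
          m <- fit_with_params(xs[tr, , drop = FALSE], ys[tr], p)
          pred <- predict_ensemble_cpp(m$trees, xs[!tr, , drop = FALSE],
                                       m$weights, m$base)
          sqrt(mean((pred - ys[!tr])^2))
        }, numeric(1))
        score <- mean(errs, na.rm = TRUE)
        if (is.null(best) || score < best$cv_rmse)
          best <- list(params = p, cv_rmse = score)
      }
    }
    ensemble <- fit_with_params(x_all, y_all, best$params)
    structure(list(subject_id = train$subject_id[1],
                   method = best$params$method, params = best$params,
                   cv_rmse = best$cv_rmse, ensemble = ensemble,
                   feature_names = feats, seed = seed),
              class = "ppg_model")
  })
}

#' @export
print.ppg_model <- function(x, ...) {
  cat(sprintf("<ppg_model> %s: %s, %d learners, min leaf %d, CV RMSE %.2f mg/dL\n",
              x$subject_id %||% "?", x$method, x$params$n_learners,
              x$params$min_leaf_size, x$cv_rmse))
  invisible(x)
}

#' Predict per-cycle blood glucose
#'
#' Finite predictions clipped to the glucometer measuring interval
#' 10-600 mg/dL.
#'
#' @param model a `ppg_model` from [tune_and_train()].
#' @param feature_table rows to predict (must contain all 18 features).
#' @return numeric vector of predicted BGLs, mg/dL.
#' @export
predict_bgl <- function(model, feature_table) {
  missing <- setdiff(model$feature_names, names(feature_table))
  if (length(missing) > 0)
    stop("missing features: ", paste(missing, collapse = ", "))
  clip(predict(model$ensemble, feature_table), 10, 600)
}

#' Aggregate per-cycle predictions to per-measurement predictions
#'
#' One (reference, predicted) pair per recording, using the mean
#' (default) or median of that recording's cycle-level predictions.
#'
#' @param feature_table table with `recording_id`, `bgl_label` and any
#'   of `day`, `timepoint`, `subject_id` to carry through.
#' @param predictions per-cycle predictions aligned with the rows.
#' @param stat `"mean"` or `"median"`.
#' @return `data.table` with one row per recording: `recording_id`,
#'   carried metadata, `reference_bgl`, `predicted_bgl`, `n_cycles`.
#' @export
aggregate_predictions <- function(feature_table, predictions,
                                  stat = c("mean", "median")) {
  stat <- match.arg(stat)
  fun <- if (stat == "mean") mean else median
  dt <- copy(as.data.table(feature_table))
  dt[, .pred := predictions]
  carry <- intersect(c("subject_id", "day", "timepoint"), names(dt))
  out <- dt[, c(lapply(.SD, data.table::first),
                list(reference_bgl = bgl_label[1],
                     predicted_bgl = fun(.pred),
                     n_cycles = .N)),
            by = recording_id, .SDcols = carry]
  out[]
}
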