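# Day-wise splitting, hyperparameter search, ensembles, prediction and
# aggregation.

# A small feature table whose target is an exact linear function of
# delta_ac: the ensembles must drive the CV RMSE far below the target SD.
# One cycle per recording, so the recording-grouped CV reduces to plain
# row-level CV and the tree-granularity floor stays well below the bound.
linear_fixture <- function(n_rec = 400, cycles_per_rec = 1, noise = 0) {
  set.seed(99)
  rows <- lapply(seq_len(n_rec), function(r) {
    base <- runif(1, 0.5, 1.5)
    f <- matrix(rnorm(cycles_per_rec * 18, 1, 0.05), cycles_per_rec, 18)
    colnames(f) <- feature_names()
    f[, "delta_ac"] <- base + rnorm(cycles_per_rec, 0, 0.005)
    dt <- as.data.frame(f)
    dt$bgl_label <- 100 + 80 * base + rnorm(cycles_per_rec, 0, noise)
    dt$recording_id <- sprintf("rec%03d", r)
    dt$day <- ((r - 1) %% 9) + 1
    dt$subject_id <- "FIX"
    dt
  })
  do.call(rbind, rows)
}

test_that("split_by_day routes and partitions", {
  tab <- linear_fixture()
  ds <- split_by_day(tab, 1:7, 8:9)
  expect_setequal(unique(ds$test$day), 8:9)
  expect_setequal(unique(ds$train$day), 1:7)
  expect_equal(nrow(ds$train) + nrow(ds$test), nrow(tab))
  expect_error(split_by_day(tab, 1:7, 7:9), "disjoint")
  expect_error(split_by_day(tab, 1:9, 10), "empty test")
})

test_that("search recovers a noise-free linear target", {
  tab <- linear_fixture()
  ds <- split_by_day(tab)
  model <- tune_and_train(ds$train, n_draws = 10, seed = 4)
  expect_lt(model$cv_rmse, 0.05 * sd(ds$train$bgl_label))
  pred <- predict_bgl(model, ds$train)
  expect_lt(sqrt(mean((pred - ds$train$bgl_label)^2)),
            0.05 * sd(ds$train$bgl_label))
})

test_that("search is seed-deterministic and stays inside the ranges", {
  tab <- linear_fixture()
  ds <- split_by_day(tab)
  m1 <- tune_and_train(ds$train, n_draws = 3, seed = 11)
  m2 <- tune_and_train(ds$train, n_draws = 3, seed = 11)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$cv_rmse, m2$cv_rmse)

  space <- hyperparameter_space()
  for (s in 1:6) {
    m <- tune_and_train(ds$train, n_draws = 2, seed = s)
    p <- m$params
    expect_true(p$n_learners >= space$n_learners[1] &&
                p$n_learners <= space$n_learners[2])
    expect_true(p$min_leaf_size >= space$min_leaf_size[1] &&
                p$min_leaf_size <= space$min_leaf_size[2])
    if (p$method == "bag") {
      expect_true(p$n_predictors >= 1 && p$n_predictors <= 19)
    } else {
      expect_true(p$learning_rate >= 0.01 && p$learning_rate <= 1)
    }
  }

  # degenerate target rejected
  bad <- linear_fixture()
  bad$bgl_label <- 120
  expect_error(tune_and_train(bad), "degenerate")
})

test_that("training never sees the test days (no leakage)", {
  tab <- linear_fixture()
  ds <- split_by_day(tab)
  m_full <- tune_and_train(ds$train, n_draws = 2, seed = 8)
  # retrain after deleting the test rows entirely: bit-identical outcome
  tab2 <- tab[tab$day %in% 1:7, ]
  m_cut <- tune_and_train(tab2, n_draws = 2, seed = 8)
  expect_identical(m_full$params, m_cut$params)
  expect_identical(m_full$cv_rmse, m_cut$cv_rmse)
  expect_identical(predict_bgl(m_full, ds$test), predict_bgl(m_cut, ds$test))
})

test_that("tree ensembles reproduce constants and clip to 10-600", {
  x <- matrix(rnorm(60 * 18), 60, 18)
  colnames(x) <- feature_names()
  # constant target -> constant prediction
  set.seed(2)
  m <- fit_bag(x, rep(140, 60), n_learners = 20)
  expect_equal(predict(m, as.data.frame(x)), rep(140, 60))
  # target below the glucometer interval -> clipped to 10
  mlow <- structure(list(subject_id = "Z", method = "bag",
                         params = list(), cv_rmse = 0,
                         ensemble = fit_bag(x, rep(5, 60), 10),
                         feature_names = feature_names()),
                    class = "ppg_model")
  expect_true(all(predict_bgl(mlow, as.data.frame(x)) == 10))
  expect_error(predict_bgl(mlow, as.data.frame(x)[, 1:5]), "missing features")
})

test_that("aggregation reduces cycles to one pair per recording", {
  tab <- data.frame(recording_id = c("a", "a", "a", "b", "b"),
                    subject_id = "s", day = 8, timepoint = 30,
                    bgl_label = c(100, 100, 100, 120, 120))
  agg <- aggregate_predictions(tab, c(100, 110, 120, 100, 300))
  expect_equal(nrow(agg), 2)
  expect_equal(agg$predicted_bgl[agg$recording_id == "a"], 110)
  agg_med <- aggregate_predictions(tab, c(100, 110, 300, 100, 300),
                                   stat = "median")
  expect_equal(agg_med$predicted_bgl[agg_med$recording_id == "a"], 110)
  expect_equal(agg$reference_bgl, c(100, 120))
  expect_equal(agg$n_cycles, c(3, 2))
})
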