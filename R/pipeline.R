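#' Pipeline configuration
#'
#' All tunables of every stage with their default values: 10th-order
#' 0.01 Hz low-pass for the DC component, 8th-order 0.3-10 Hz band-pass
#' for the AC component, upsampling factor 4, matched-filter threshold
#' r >= 0.90, template length 100, train days 1-7 vs test days 8-9,
#' 5-fold recording-grouped cross-validation.
#'
#' @param profiles cohort subject profiles (simulation only).
#' @param schedule a [simulation_schedule()].
#' @param seed master seed for simulation and model search.
#' @param upsample_factor integer upsampling factor.
#' @param dc_order,dc_cutoff,ac_order,ac_band Butterworth settings (Hz).
#' @param min_separation,prominence_frac peak-detector settings.
#' @param r_min matched-filter rejection threshold.
#' @param template_length matched-filter template length, samples.
#' @param train_days,test_days day-wise split.
#' @param cv_folds cross-validation folds.
#' @param n_draws random hyperparameter draws per ensemble method.
#' @param search_max_rows row cap for the CV search (refit uses all rows).
#' @param eval_level `"recording"` (aggregate cycles per measurement
#'   before evaluating) or `"cycle"`.
#' @param aggregate `"mean"` or `"median"` cycle aggregation.
#' @param glucometer_cv reference-meter noise (fraction of reading).
#' @return object of class `ppg_config` (a named list).
#' @export
pipeline_config <- function(profiles = default_cohort_profiles(),
                            schedule = simulation_schedule(),
                            seed = 1L,
                            upsample_factor = 4,
                            dc_order = 10, dc_cutoff = 0.01,
                            ac_order = 8, ac_band = c(0.3, 10),
                            min_separation = 0.3, prominence_frac = 0.3,
                            r_min = 0.90, template_length = 100,
                            train_days = 1:7, test_days = 8:9,
                            cv_folds = 5, n_draws = 50,
                            search_max_rows = 1000,
                            eval_level = c("recording", "cycle"),
                            aggregate = c("mean", "median"),
                            glucometer_cv = 0.05) {
  if (length(intersect(train_days, test_days)) > 0)
    stop("train_days and test_days must be disjoint")
  structure(list(
    profiles = profiles, schedule = schedule, seed = as.integer(seed),
    upsample_factor = upsample_factor,
    dc_order = dc_order, dc_cutoff = dc_cutoff,
    ac_order = ac_order, ac_band = ac_band,
    min_separation = min_separation, prominence_frac = prominence_frac,
    r_min = r_min, template_length = template_length,
    train_days = train_days, test_days = test_days,
    cv_folds = cv_folds, n_draws = n_draws,
    search_max_rows = search_max_rows,
    eval_level = match.arg(eval_level),
    aggregate = match.arg(aggregate),
    glucometer_cv = glucometer_cv
  ), class = "ppg_config")
}

#' Pre-process one recording and extract its per-cycle feature rows
#'
#' Runs conditioning, segmentation, matched-filter QC and feature
#' extraction for a single recording.
#'
#' @param recording a `ppg_recording`.
#' @param config a [pipeline_config()].
#' @return list with `features` (a `data.table`, one row per valid
#'   cycle: metadata, correlation `r`, and the 18 features) and `qc`
#'   (total/valid cycle counts).
#' @export
process_recording <- function(recording, config = pipeline_config()) {
  proc <- preprocess_recording(
    recording, upsample_factor = config$upsample_factor,
    dc_order = config$dc_order, dc_cutoff = config$dc_cutoff,
    ac_order = config$ac_order, ac_band = config$ac_band,
    min_separation = config$min_separation,
    prominence_frac = config$prominence_frac)
  cycles <- segment_cycles(proc)
  template <- build_template(cycles, config$template_length)
  qc <- filter_cycles(cycles, template, config$r_min)
  rows <- list()
  rs <- qc$correlations[qc$correlations >= config$r_min]
  for (i in seq_along(qc$valid)) {
    fv <- extract_features(qc$valid[[i]])
    if (is.null(fv)) next
    rows[[length(rows) + 1L]] <- c(
      list(subject_id = recording$subject_id, day = recording$day,
           timepoint = recording$timepoint,
           repeat_index = recording$repeat_index,
           recording_id = recording$recording_id,
           bgl_label = recording$reference_bgl,
           true_bgl = recording$true_bgl %||% NA_real_,
           cycle_index = i, r = rs[i]),
      as.list(fv))
  }
  features <- if (length(rows) > 0) rbindlist(rows) else data.table()
  list(features = features,
       qc = data.table(recording_id = recording$recording_id,
                       subject_id = recording$subject_id,
                       n_cycles = length(cycles),
                       n_valid = length(qc$valid),
                       retained_fraction =
                         if (length(cycles) > 0)
                           length(qc$valid) / length(cycles) else NA_real_))
}

#' Build the cohort-wide feature table
#'
#' @param cohort a `ppg_cohort`.
#' @param config a [pipeline_config()].
#' @param verbose print per-recording progress counts.
#' @return list with `features` (all valid cycles of all recordings)
#'   and `qc` (per-recording retention bookkeeping).
#' @export
extract_cohort_features <- function(cohort, config = pipeline_config(),
                                    verbose = FALSE) {
  feats <- list(); qcs <- list()
  for (rec in cohort$recordings) {
    res <- process_recording(rec, config)
    feats[[rec$recording_id]] <- res$features
    qcs[[rec$recording_id]] <- res$qc
    if (verbose)
      message(sprintf("%s: %d/%d cycles retained", rec$recording_id,
                      res$qc$n_valid, res$qc$n_cycles))
  }
  list(features = rbindlist(feats), qc = rbindlist(qcs))
}

#' Run the full estimation pipeline
#'
#' Simulate (unless a cohort is supplied) -> pre-process -> segment and
#' QC -> features -> per-subject fasting-mean split and feature ranking
#' -> day-wise split -> hyperparameter search and training -> held-out
#' prediction -> aggregation -> clinical evaluation.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built or on-disk cohort (a `ppg_cohort`);
#'   when `NULL` one is simulated from the config's profiles, schedule
#'   and seed.
#' @param verbose log per-stage bookkeeping.
#' @return object of class `ppg_pipeline_result`: `feature_table`,
#'   `qc`, and per-subject entries each holding `threshold`,
#'   `feature_ranking`, `model`, `predictions` (per-recording pairs)
#'   and `report` (a `bgl_evaluation`).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(cohort)) {
    say("simulating cohort (%d subjects, %d days, seed %d)",
        length(config$profiles), config$schedule$n_days, config$seed)
    cohort <- gen_cohort(config$profiles, config$schedule,
                         seed = config$seed,
                         glucometer_cv = config$glucometer_cv)
  }
  say("pre-processing %d recordings", length(cohort$recordings))
  fx <- extract_cohort_features(cohort, config)
  say("cycles: %d total, %d valid (mean retention %.2f)",
      sum(fx$qc$n_cycles), sum(fx$qc$n_valid),
      mean(fx$qc$retained_fraction, na.rm = TRUE))

  meta <- cohort$metadata
  subjects <- unique(fx$features$subject_id)
  results <- list()
  for (sid in subjects) {
    sub <- fx$features[fx$features$subject_id == sid, ]
    fasting <- unique(meta[meta$subject_id == sid & meta$timepoint_min < 0,
                           .(day, reference_bgl_mgdl)])$reference_bgl_mgdl
    split <- suppressWarnings(split_by_fasting_mean(sub, fasting))
    ranking <- if (nrow(split$low) > 1 && nrow(split$high) > 1)
      rank_features(split) else NULL
    ds <- split_by_day(sub, config$train_days, config$test_days)
    say("%s: threshold %.1f mg/dL, %d train / %d test cycles",
        sid, split$threshold, nrow(ds$train), nrow(ds$test))
    model <- tune_and_train(ds$train, n_draws = config$n_draws,
                            folds = config$cv_folds, seed = config$seed,
                            search_max_rows = config$search_max_rows)
    say("%s: chose %s (%d learners, leaf %d), CV RMSE %.2f",
        sid, model$method, model$params$n_learners,
        model$params$min_leaf_size, model$cv_rmse)
    pred <- predict_bgl(model, ds$test)
    pairs <- if (config$eval_level == "recording") {
      agg <- aggregate_predictions(ds$test, pred, config$aggregate)
      data.table(recording_id = agg$recording_id, day = agg$day,
                 reference_bgl = agg$reference_bgl,
                 predicted_bgl = agg$predicted_bgl)
    } else {
      data.table(recording_id = ds$test$recording_id, day = ds$test$day,
                 reference_bgl = ds$test$bgl_label, predicted_bgl = pred)
    }
    report <- evaluate_predictions(pairs$reference_bgl, pairs$predicted_bgl)
    say("%s: CEG A %.1f%%, RMSE %.2f, MARD %.2f%%, r %.2f", sid,
        report$ceg$percentages[report$ceg$regions == "A"], report$rmse,
        report$mard, report$pearson_r)
    results[[sid]] <- list(subject_id = sid, threshold = split$threshold,
                           feature_ranking = ranking, model = model,
                           predictions = pairs, report = report)
  }
  structure(list(feature_table = fx$features, qc = fx$qc,
                 subjects = results, config = config),
            class = "ppg_pipeline_result")
}

#' @export
print.ppg_pipeline_result <- function(x, ...) {
  cat(sprintf("<ppg_pipeline_result> %d subjects, %d valid cycles\n",
              length(x$subjects), nrow(x$feature_table)))
  for (s in x$subjects) {
    rep <- s$report
    cat(sprintf("  %s: CEG A %.1f%% (A+B %.1f%%), RMSE %.2f mg/dL, MARD %.2f%%, r %.2f\n",
                s$subject_id,
                rep$ceg$percentages[rep$ceg$regions == "A"],
                sum(rep$ceg$percentages[rep$ceg$regions %in% c("A", "B")]),
                rep$rmse, rep$mard, rep$pearson_r))
  }
  invisible(x)
}
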