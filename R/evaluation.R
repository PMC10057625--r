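#' Clarke error grid classification
#'
#' Classifies (reference, predicted) glucose pairs into the canonical
#' Clarke (1987) regions:
#' * **A** - prediction within 20% of the reference, or both values in
#'   the hypoglycemic range (< 70 mg/dL): clinically accurate.
#' * **B** - benign errors outside A that would not lead to
#'   inappropriate treatment.
#' * **C** - overcorrection errors (e.g. prediction >= reference + 110
#'   for references in 70-290, or below `7/5 * ref - 182` for
#'   references in 130-180).
#' * **D** - dangerous failure to detect (prediction in the 70-180
#'   euglycemic band while the reference is hypo- or hyperglycemic).
#' * **E** - erroneous treatment (opposite-corner misclassification:
#'   hypoglycemia read as hyperglycemia or vice versa).
#'
#' Regions are evaluated in the priority order A, E, C, D, B; the
#' inequalities below are the full canonical set used by the standard
#' reference implementations.
#'
#' @param reference reference glucometer BGLs, mg/dL, in (0, 600].
#' @param predicted predicted BGLs, same length.
#' @return character vector of region labels `"A"`..`"E"`.
#' @export
ceg_classify <- function(reference, predicted) {
  if (length(reference) != length(predicted))
    stop("reference and predicted must have equal length")
  if (any(reference <= 0 | predicted <= 0 |
          reference > 600 | predicted > 600))
    stop("glucose values must lie in (0, 600] mg/dL")
  r <- reference; p <- predicted
  out <- rep("B", length(r))
  a <- (p <= 70 & r <= 70) | (p <= 1.2 * r & p >= 0.8 * r)
  e <- !a & ((r >= 180 & p <= 70) | (r <= 70 & p >= 180))
  cc <- !a & !e &
    ((r >= 70 & r <= 290 & p >= r + 110) |
     (r >= 130 & r <= 180 & p <= (7 / 5) * r - 182))
  d <- !a & !e & !cc &
    ((r >= 240 & p <= 180 & p >= 70) |
     (r <= 175 / 3 & p <= 180 & p >= 70) |
     (r >= 175 / 3 & r <= 70 & p >= (6 / 5) * r))
  out[d] <- "D"; out[cc] <- "C"; out[e] <- "E"; out[a] <- "A"
  out
}

#' Clarke error grid summary
#'
#' @param reference,predicted glucose pairs, mg/dL.
#' @return object of class `ceg_result`: per-region counts and
#'   percentages (summing to 100) plus the point labels.
#' @export
ceg_summary <- function(reference, predicted) {
  if (length(reference) < 1) stop("need at least one pair")
  labels <- ceg_classify(reference, predicted)
  counts <- table(factor(labels, levels = c("A", "B", "C", "D", "E")))
  structure(list(labels = labels, counts = as.integer(counts),
                 regions = names(counts),
                 percentages = 100 * as.numeric(counts) / length(labels),
                 n_points = length(labels)), class = "ceg_result")
}

#' @export
print.ceg_result <- function(x, ...) {
  cat("Clarke error grid:", x$n_points, "points\n")
  for (i in seq_along(x$regions))
    cat(sprintf("  region %s: %5.1f%% (%d)\n", x$regions[i],
                x$percentages[i], x$counts[i]))
  invisible(x)
}

#' Mean absolute relative difference (MARD)
#'
#' `100 * mean(|predicted - reference| / reference)`, the standard CGM
#' accuracy metric, in percent.
#' @param reference,predicted glucose pairs, mg/dL; references must be
#'   positive.
#' @export
mard <- function(reference, predicted) {
  if (any(reference <= 0)) stop("reference values must be positive")
  100 * mean(abs(predicted - reference) / reference)
}

#' Root mean squared error
#' @param reference,predicted paired values.
#' @export
rmse <- function(reference, predicted) {
  sqrt(mean((predicted - reference)^2))
}

#' Least-squares regression report of predicted on reference glucose
#'
#' Ordinary least squares of `predicted ~ reference`: slope and
#' intercept with 95% t-based confidence intervals, the residual
#' standard error, R-squared (equal to the squared Pearson correlation
#' for a simple regression), and the Pearson correlation itself.
#'
#' @param reference,predicted glucose pairs (>= 3, reference variance
#'   positive).
#' @return list with `slope`, `intercept`, `slope_ci`, `intercept_ci`,
#'   `standard_error`, `r_squared`, `pearson_r`, `n`.
#' @export
regression_report <- function(reference, predicted) {
  if (length(reference) < 3) stop("need at least 3 pairs")
  if (var(reference) == 0) stop("reference variance is zero")
  fit <- lm(predicted ~ reference)
  ci <- suppressWarnings(confint(fit, level = 0.95))
  # summary.lm warns on degenerate (perfect or constant) fits; the report
  # is still well defined for them
  s <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       slope_ci = unname(ci[2, ]), intercept_ci = unname(ci[1, ]),
       standard_error = s$sigma, r_squared = s$r.squared,
       pearson_r = suppressWarnings(cor(reference, predicted)),
       n = length(reference))
}

#' ISO 15197 tolerance rate
#'
#' A pair is compliant when the absolute error is within `low_band`
#' mg/dL for references below `cutoff` and within `high_band` mg/dL at
#' or above it (the +/-15 / +/-20 mg/dL bands around a 100 mg/dL
#' cutoff). Returns the percentage of compliant pairs.
#'
#' @param reference,predicted glucose pairs, mg/dL.
#' @param low_band,high_band tolerance bands, mg/dL.
#' @param cutoff reference cutoff between the two bands, mg/dL.
#' @export
iso_tolerance_rate <- function(reference, predicted, low_band = 15,
                               high_band = 20, cutoff = 100) {
  if (length(reference) < 1) stop("need at least one pair")
  band <- ifelse(reference < cutoff, low_band, high_band)
  100 * mean(abs(predicted - reference) <= band)
}

#' Full clinical evaluation report
#'
#' Bundles the Clarke error grid summary, RMSE, MARD, Pearson r, the
#' least-squares regression report and the ISO tolerance rate for one
#' set of (reference, predicted) pairs.
#'
#' @param reference,predicted glucose pairs, mg/dL.
#' @return object of class `bgl_evaluation`.
#' @export
evaluate_predictions <- function(reference, predicted) {
  structure(list(
    n = length(reference),
    rmse = rmse(reference, predicted),
    mard = mard(reference, predicted),
    pearson_r = suppressWarnings(cor(reference, predicted)),
    regression = if (length(reference) >= 3 && var(reference) > 0)
      regression_report(reference, predicted) else NULL,
    iso_within_tolerance = iso_tolerance_rate(reference, predicted),
    ceg = ceg_summary(reference, predicted)
  ), class = "bgl_evaluation")
}

#' @export
print.bgl_evaluation <- function(x, ...) {
  cat(sprintf("BGL evaluation on %d measurements\n", x$n))
  cat(sprintf("  RMSE  %.2f mg/dL | MARD %.2f%% | r %.3f | ISO within tolerance %.1f%%\n",
              x$rmse, x$mard, x$pearson_r, x$iso_within_tolerance))
  ab <- sum(x$ceg$percentages[x$ceg$regions %in% c("A", "B")])
  cat(sprintf("  CEG: A %.1f%%, A+B %.1f%%\n",
              x$ceg$percentages[x$ceg$regions == "A"], ab))
  if (!is.null(x$regression))
    cat(sprintf("  OLS: slope %.3f (%.3f, %.3f), intercept %.1f (%.1f, %.1f), SE %.2f, R^2 %.2f\n",
                x$regression$slope, x$regression$slope_ci[1],
                x$regression$slope_ci[2], x$regression$intercept,
                x$regression$intercept_ci[1], x$regression$intercept_ci[2],
                x$regression$standard_error, x$regression$r_squared))
  invisible(x)
}
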