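#' Split cycles into low- and high-glucose groups
#'
#' The per-subject threshold is the arithmetic mean of the fasting
#' reference glucometer readings. Cycles whose recording BGL is below
#' the threshold go to the low group; cycles at or above it (including
#' the boundary) go to the high group.
#'
#' Works on either a list of `ppg_cycle` objects or a feature table
#' (`data.frame`/`data.table` with a `bgl_label` column).
#'
#' @param cycles cycle list or feature table.
#' @param fasting_bgls numeric vector of fasting reference BGLs.
#' @return object of class `glucose_split`: list with `threshold`,
#'   `low`, `high` (same container type as the input).
#' @export
split_by_fasting_mean <- function(cycles, fasting_bgls) {
  if (length(fasting_bgls) < 1) stop("need at least one fasting measurement")
  threshold <- mean(fasting_bgls)
  labels <- if (is.data.frame(cycles)) cycles$bgl_label
            else vapply(cycles, `[[`, numeric(1), "bgl_label")
  is_low <- labels < threshold
  if (all(is_low) || !any(is_low))
    warning("all cycles fall on one side of the fasting threshold; the high/low comparison will be skipped")
  low <- if (is.data.frame(cycles)) cycles[is_low, , drop = FALSE] else cycles[is_low]
  high <- if (is.data.frame(cycles)) cycles[!is_low, , drop = FALSE] else cycles[!is_low]
  structure(list(threshold = threshold, low = low, high = high),
            class = "glucose_split")
}

#' Pointwise comparison of low- vs high-glucose ensemble cycles
#'
#' All cycles are resampled to a common length; the two groups are
#' compared pointwise with a Welch two-sample t-test (no
#' multiple-testing correction, by design). Confidence half-widths are
#' per-group pointwise 95% t-intervals of the mean.
#'
#' @param split a `glucose_split` whose `low`/`high` entries are lists
#'   of `ppg_cycle` objects.
#' @param alpha significance level for the pointwise rejection mask.
#' @param length_out common resampling length.
#' @param pooled use the pooled-variance (classical) two-sample test
#'   instead of Welch.
#' @return object of class `cycle_comparison`: `mean_low`, `mean_high`,
#'   `ci_low`, `ci_high`, `p_values`, `reject_mask`.
#' @export
compare_cycles <- function(split, alpha = 0.05, length_out = 100,
                           pooled = FALSE) {
  n1 <- length(split$low); n2 <- length(split$high)
  if (n1 < 2 || n2 < 2)
    stop("each glucose group needs at least 2 cycles for the pointwise t-test")
  mat <- function(cycles) t(vapply(cycles, function(cy)
    resample_linear(cy$samples, length_out), numeric(length_out)))
  a <- mat(split$low); b <- mat(split$high)
  if (pooled) {
    m1 <- colMeans(a); m2 <- colMeans(b)
    v1 <- apply(a, 2, var); v2 <- apply(b, 2, var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    t_stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
    df <- n1 + n2 - 2
    p <- ifelse(se2 > 0, 2 * pt(-abs(t_stat), df), ifelse(m1 == m2, 1, 0))
    w <- list(p = p, mean1 = m1, mean2 = m2, var1 = v1, var2 = v2,
              n1 = n1, n2 = n2)
  } else {
    w <- welch_t_cols(a, b)
  }
  structure(list(
    mean_low = w$mean1, mean_high = w$mean2,
    ci_low = qt(0.975, n1 - 1) * sqrt(w$var1 / n1),
    ci_high = qt(0.975, n2 - 1) * sqrt(w$var2 / n2),
    p_values = w$p,
    reject_mask = !is.na(w$p) & w$p < alpha,
    alpha = alpha
  ), class = "cycle_comparison")
}

#' Rank features by their high/low-glucose percentage difference
#'
#' For each of the 18 features: `100 * |mean_high - mean_low| /
#' |mean_low|`, with a Welch two-sample p-value on the per-cycle feature
#' values. Features whose low-group mean is zero have an undefined
#' percentage difference; they are flagged (`NA`) and placed last.
#'
#' @param split a `glucose_split` whose `low`/`high` entries are feature
#'   tables (rows = cycles, columns include [feature_names()]).
#' @param top_k how many features to mark as leading (attribute only;
#'   the full ranking is returned).
#' @return `data.table` with `feature`, `percent_difference`, `p_value`,
#'   sorted by decreasing percentage difference.
#' @export
rank_features <- function(split, top_k = 10) {
  feats <- feature_names()
  low <- as.data.frame(split$low)[, feats, drop = FALSE]
  high <- as.data.frame(split$high)[, feats, drop = FALSE]
  if (nrow(low) == 0 || nrow(high) == 0)
    stop("both glucose groups must be non-empty")
  w <- welch_t_cols(as.matrix(low), as.matrix(high))
  pct <- ifelse(w$mean1 != 0,
                100 * abs(w$mean2 - w$mean1) / abs(w$mean1), NA_real_)
  out <- data.table(feature = feats, percent_difference = pct,
                    p_value = w$p)
  setorder(out, -percent_difference, na.last = TRUE)
  setattr(out, "top_k", min(top_k, sum(!is.na(pct))))
  out[]
}
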