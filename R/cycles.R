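#' Segment a processed recording into single-cycle windows
#'
#' One window per interior systolic peak, spanning from the trough on
#' its left to the trough on its right (inclusive); adjacent cycles
#' share their boundary trough. Each cycle inherits the recording's DC
#' value and reference glucometer BGL.
#'
#' @param processed a `ppg_processed` from [preprocess_recording()].
#' @return list of `ppg_cycle` objects (possibly empty, with a warning).
#' @export
segment_cycles <- function(processed) {
  pk <- processed$peaks
  tr <- processed$troughs
  if (length(pk) == 0 || length(tr) < 2) {
    warning("no valid interior peak; returning zero cycles")
    return(list())
  }
  x <- processed$ac_series
  rate <- processed$upsampled_rate
  cycles <- vector("list", length(pk))
  for (i in seq_along(pk)) {
    l <- tr[i]; r <- tr[i + 1]
    seg <- x[l:r]
    cycles[[i]] <- structure(list(
      samples = seg,
      peak_offset = pk[i] - l + 1L,
      left_trough_value = x[l], peak_value = x[pk[i]],
      right_trough_value = x[r],
      dc_value = processed$dc_value,
      sampling_rate = rate,
      duration = (r - l) / rate,
      recording_ref = processed$recording_id,
      bgl_label = processed$reference_bgl
    ), class = "ppg_cycle")
  }
  cycles
}

#' Build the matched-filter template of a recording
#'
#' The template is the pointwise mean of the middle ten cycles (all
#' cycles when fewer than ten exist), each first resampled to a fixed
#' length by linear interpolation.
#'
#' @param cycles list of `ppg_cycle`.
#' @param template_length fixed template length in samples.
#' @return object of class `cycle_template` with `waveform` and
#'   `n_source_cycles`.
#' @export
build_template <- function(cycles, template_length = 100) {
  n <- length(cycles)
  if (n < 1) stop("cannot build a template from zero cycles")
  idx <- middle_ten(n)
  mat <- vapply(cycles[idx],
                function(cy) resample_linear(cy$samples, template_length),
                numeric(template_length))
  structure(list(waveform = rowMeans(mat), n_source_cycles = length(idx)),
            class = "cycle_template")
}

# Indices of the ten cycles centred at floor(n/2) (0-based centre), i.e.
# 0-based floor(n/2)-5 .. floor(n/2)+4; all cycles when n < 10.
middle_ten <- function(n) {
  if (n < 10) return(seq_len(n))
  c0 <- n %/% 2
  (c0 - 5):(c0 + 4) + 1L
}

#' Matched-filter quality control of PPG cycles
#'
#' Each cycle is resampled to the template length and correlated
#' (Pearson) with the template; cycles whose correlation falls below
#' `r_min` are deemed too noisy and removed. The boundary case equal to
#' `r_min` is kept. A
#' zero-variance cycle has `r` defined as 0 and is rejected.
#'
#' @param cycles list of `ppg_cycle`.
#' @param template a `cycle_template` from [build_template()].
#' @param r_min rejection threshold (default 0.90).
#' @return list with `valid`, `rejected` (lists of cycles) and
#'   `correlations` (numeric, one per input cycle, for audit).
#' @export
filter_cycles <- function(cycles, template, r_min = 0.90) {
  if (!inherits(template, "cycle_template")) stop("template must be built first")
  L <- length(template$waveform)
  r <- vapply(cycles, function(cy) {
    y <- resample_linear(cy$samples, L)
    if (sd(y) == 0 || sd(template$waveform) == 0) return(0)
    cor(y, template$waveform)
  }, numeric(1))
  keep <- r >= r_min
  list(valid = cycles[keep], rejected = cycles[!keep], correlations = r)
}

#' Teager-Kaiser energy operator
#'
#' `psi[n] = x[n]^2 - x[n+1] * x[n-1]`, evaluated at interior points, so
#' the output is two samples shorter than the input. For a sinusoid
#' `A * sin(w * n)` the operator returns the constant `A^2 * sin(w)^2`.
#'
#' @param x numeric vector of length >= 3.
#' @return numeric vector of length `length(x) - 2`.
#' @export
tkeo <- function(x) {
  n <- length(x)
  if (n < 3) stop("tkeo needs at least 3 samples")
  x[2:(n - 1)]^2 - x[3:n] * x[1:(n - 2)]
}

#' Names of the 18 per-cycle features
#' @export
feature_names <- function() {
  c("dc_value", "peak_value", "delta_ac", "rise_slope", "rise_time",
    "fall_level", "fall_slope", "fall_time", "width_quarter",
    "width_three_quarter", "base_width", "area", "optical_density",
    "tkeo_mean", "tkeo_variance", "tkeo_std", "tkeo_skewness",
    "tkeo_kurtosis")
}

# Time span for which the cycle exceeds left_trough + h * delta_ac, with
# linear interpolation at the two crossings.
width_at_height <- function(y, rate, v_left, delta_ac, h) {
  if (delta_ac <= 0) return(0)
  level <- v_left + h * delta_ac
  above <- y > level
  if (!any(above)) return(0)
  first <- which(above)[1]
  last <- rev(which(above))[1]
  t_first <- if (first == 1) 0 else
    (first - 2 + (level - y[first - 1]) / (y[first] - y[first - 1])) / rate
  t_last <- if (last == length(y)) (length(y) - 1) / rate else
    (last - 1 + (level - y[last]) / (y[last + 1] - y[last])) / rate
  t_last - t_first
}

#' Extract the 18-feature vector of one PPG cycle
#'
#' Morphological timings and amplitudes are anchored at the left trough:
#' `delta_ac` is peak minus left trough, widths at 1/4 and 3/4 height
#' are the durations for which the cycle exceeds the corresponding
#' level above the left trough, the area is the trapezoidal integral of
#' the cycle above the left-trough level, and the optical density is
#' `log10(1 + delta_ac / dc_value)`. The fall slope is stored negative
#' (downhill). TKEO statistics use population moments with raw kurtosis
#' (normal = 3).
#'
#' @param cycle a `ppg_cycle`.
#' @param sampling_rate optional rate override (defaults to the cycle's
#'   own rate).
#' @return named numeric vector with exactly 18 entries
#'   (see [feature_names()]), or `NULL` with a warning when
#'   `dc_value <= 0` makes the optical density undefined.
#' @export
extract_features <- function(cycle, sampling_rate = NULL) {
  rate <- sampling_rate %||% cycle$sampling_rate
  y <- cycle$samples
  n <- length(y)
  k <- cycle$peak_offset
  v_l <- cycle$left_trough_value
  v_r <- cycle$right_trough_value
  v_p <- cycle$peak_value
  if (cycle$dc_value <= 0) {
    warning("dc_value <= 0: optical density undefined, cycle dropped")
    return(NULL)
  }
  delta_ac <- v_p - v_l
  fall_level <- v_p - v_r
  rise_time <- (k - 1) / rate
  fall_time <- (n - k) / rate
  dt <- 1 / rate
  area <- dt * (sum(y - v_l) - (y[1] - v_l) / 2 - (y[n] - v_l) / 2)
  e <- tkeo(y)
  mo <- population_moments(e)
  out <- c(
    dc_value = cycle$dc_value,
    peak_value = v_p,
    delta_ac = delta_ac,
    rise_slope = if (rise_time > 0) delta_ac / rise_time else 0,
    rise_time = rise_time,
    fall_level = fall_level,
    fall_slope = if (fall_time > 0) -fall_level / fall_time else 0,
    fall_time = fall_time,
    width_quarter = width_at_height(y, rate, v_l, delta_ac, 0.25),
    width_three_quarter = width_at_height(y, rate, v_l, delta_ac, 0.75),
    base_width = rise_time + fall_time,
    area = area,
    optical_density = log10(1 + delta_ac / cycle$dc_value),
    tkeo_mean = mo$mean,
    tkeo_variance = mo$variance,
    tkeo_std = mo$sd,
    tkeo_skewness = mo$skewness,
    tkeo_kurtosis = mo$kurtosis
  )
  stopifnot(identical(names(out), feature_names()))
  out
}
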