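#' Extract the DC component of a PPG signal
#'
#' Zero-phase 10th-order Butterworth low-pass with a 0.01 Hz cutoff.
#' On a 2-minute recording this cutoff barely resolves any trend, so the
#' output is essentially the local mean level of the signal; warm-up is
#' handled by steady-state initialisation plus odd-reflection padding
#' (30 s or the signal length, whichever is shorter).
#'
#' @param samples raw PPG samples.
#' @param sampling_rate sampling rate in Hz.
#' @param order,cutoff filter order and cutoff in Hz.
#' @return low-passed series, same length as the input.
#' @export
extract_dc <- function(samples, sampling_rate, order = 10, cutoff = 0.01) {
  min_n <- 4L * order
  if (length(samples) < min_n)
    stop(sprintf("signal too short for DC extraction: %d samples, need >= %d",
                 length(samples), min_n))
  sos <- butter_sos(order, cutoff, fs = sampling_rate, type = "low")
  sosfiltfilt(samples, sos,
              padlen = min(length(samples) - 1, round(30 * sampling_rate)))
}

#' Extract the AC (pulsatile) component of a PPG signal
#'
#' Zero-phase 8th-order Butterworth band-pass between 0.3 and 10 Hz.
#'
#' @inheritParams extract_dc
#' @param band band edges in Hz.
#' @export
extract_ac <- function(samples, sampling_rate, order = 8, band = c(0.3, 10)) {
  if (sampling_rate <= 2 * band[2])
    stop(sprintf("sampling rate %.3g Hz too low: need > %g Hz (Nyquist above the %g Hz band edge)",
                 sampling_rate, 2 * band[2], band[2]))
  min_n <- 4L * order
  if (length(samples) < min_n)
    stop(sprintf("signal too short for AC extraction: %d samples, need >= %d",
                 length(samples), min_n))
  sos <- butter_sos(order, band, fs = sampling_rate, type = "band")
  sosfiltfilt(samples, sos,
              padlen = min(length(samples) - 1, round(10 * sampling_rate)))
}

#' Upsample a series by linear interpolation
#'
#' Original samples are preserved at stride `factor`; inserted samples
#' interpolate linearly between neighbours. Output length is
#' `(n - 1) * factor + 1`.
#'
#' @param series numeric vector.
#' @param factor integer upsampling factor (>= 1).
#' @export
upsample <- function(series, factor) {
  if (length(factor) != 1 || factor < 1 || factor != round(factor))
    stop("`factor` must be a positive integer")
  factor <- as.integer(factor)
  n <- length(series)
  if (factor == 1L || n < 2) return(as.numeric(series))
  approx(seq_len(n), series, xout = seq(1, n, by = 1 / factor))$y
}

# Strict local extrema of a series (strictly below/above both neighbours;
# flat plateaus yield no extremum).
local_extrema <- function(x, what = c("min", "max")) {
  what <- match.arg(what)
  if (what == "max") x <- -x
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] < x[3:n]) + 1L
}

# Keep extrema at least `min_gap` samples apart; ties resolved in favour
# of the more extreme value.
enforce_separation <- function(idx, values, min_gap, decreasing = TRUE) {
  if (length(idx) == 0) return(idx)
  ord <- order(values, decreasing = decreasing)
  kept <- integer(0)
  for (i in ord) {
    cand <- idx[i]
    if (!any(abs(kept - cand) < min_gap)) kept <- c(kept, cand)
  }
  sort(kept)
}

#' Detect the lower envelope via spline interpolation and subtract it
#'
#' Local minima are located (with a refractory separation so in-band noise
#' does not litter the envelope with micro-minima), a natural cubic spline
#' is drawn through them, extended as a constant beyond the terminal
#' minima, and subtracted. The corrected series is exactly zero at the
#' interpolation knots.
#'
#' The knot separation defaults to 0.5 s (120 bpm): wide enough that the
#' dicrotic-notch minimum inside a cycle is not mistaken for a cycle
#' trough, which would drag the envelope through the middle of the
#' waveform.
#'
#' @param series band-passed (and typically upsampled) PPG series.
#' @param sampling_rate rate of `series` in Hz (sets the refractory gap).
#' @param min_separation minimum spacing between envelope knots, seconds.
#' @return list with `corrected` and `envelope`, both the length of the
#'   input, plus `knots` (the minima indices used).
#' @export
remove_baseline <- function(series, sampling_rate, min_separation = 0.5) {
  mins <- local_extrema(series, "min")
  gap <- max(1, round(min_separation * sampling_rate))
  mins <- enforce_separation(mins, series[mins], gap, decreasing = FALSE)
  if (length(mins) < 4)
    stop(sprintf("only %d local minima found; need >= 4 for the lower-envelope spline (recording unusable)",
                 length(mins)))
  env_fun <- splinefun(mins, series[mins], method = "natural")
  env <- env_fun(seq_along(series))
  env[seq_along(series) < mins[1]] <- series[mins[1]]
  env[seq_along(series) > mins[length(mins)]] <- series[mins[length(mins)]]
  list(corrected = series - env, envelope = env, knots = mins)
}

#' Detect systolic peaks and the troughs between them
#'
#' Candidate peaks are strict local maxima; a refractory period (default
#' 0.3 s, i.e. at most 200 bpm) suppresses secondary maxima, and peaks
#' whose local span falls below `prominence_frac` times the median span
#' are discarded as noise. Troughs are located between consecutive
#' accepted peaks (plus a leading and a trailing one), so every returned
#' peak has a trough on both sides and the two sequences strictly
#' alternate.
#'
#' Because the diastolic baseline of a PPG beat is nearly flat, the raw
#' minimum between two peaks wanders under sensor noise. Troughs are
#' therefore anchored at the foot of the following systolic upstroke:
#' the signal is smoothed over 50 ms and the trough is the *last* point
#' of the inter-peak segment lying within 5% of the segment's span above
#' its minimum - the point where the steep upstroke leaves the valley,
#' which is robust to noise in the flat region.
#'
#' @param corrected baseline-corrected series.
#' @param sampling_rate rate of `corrected` in Hz.
#' @param min_separation refractory period in seconds.
#' @param prominence_frac fraction of the median peak span below which a
#'   peak is rejected.
#' @return list with integer vectors `peaks` and `troughs`
#'   (`length(troughs) == length(peaks) + 1`).
#' @export
detect_peaks_troughs <- function(corrected, sampling_rate,
                                 min_separation = 0.3,
                                 prominence_frac = 0.3) {
  n <- length(corrected)
  cands <- local_extrema(corrected, "max")
  if (length(cands) == 0) stop("no peaks found in recording")
  gap <- max(1, round(min_separation * sampling_rate))
  peaks <- enforce_separation(cands, corrected[cands], gap, decreasing = TRUE)

  # 50 ms moving average for trough localisation only
  k_sm <- max(1L, round(0.05 * sampling_rate))
  sm <- if (k_sm > 1)
    as.numeric(stats::filter(corrected, rep(1 / k_sm, k_sm), sides = 2))
  else corrected
  sm[is.na(sm)] <- corrected[is.na(sm)]

  # foot of the upstroke: last near-minimal smoothed point of a segment
  foot <- function(seg, span_top) {
    m <- min(sm[seg])
    thr <- m + 0.05 * max(span_top - m, 0)
    seg[max(which(sm[seg] <= thr))]
  }

  troughs_of <- function(pk) {
    k <- length(pk)
    tr <- integer(k + 1)
    tr[1] <- foot(1:pk[1], corrected[pk[1]])
    if (k > 1) {
      for (i in seq_len(k - 1)) {
        seg <- (pk[i] + 1):(pk[i + 1] - 1)
        tr[i + 1] <- foot(seg, min(corrected[pk[i]], corrected[pk[i + 1]]))
      }
    }
    seg <- pk[k]:n
    tr[k + 1] <- seg[which.min(sm[seg])]
    tr
  }

  # span-based pruning: peak height above the mean of its adjacent troughs
  tr <- troughs_of(peaks)
  span <- corrected[peaks] -
    (corrected[tr[-length(tr)]] + corrected[tr[-1]]) / 2
  keep <- span >= prominence_frac * median(span)
  peaks <- peaks[keep]
  if (length(peaks) == 0) stop("no peaks found in recording")
  tr <- troughs_of(peaks)

  # drop edge peaks that coincide with their boundary trough
  if (tr[1] == peaks[1] || tr[length(tr)] == peaks[length(peaks)]) {
    ok <- rep(TRUE, length(peaks))
    if (tr[1] == peaks[1]) ok[1] <- FALSE
    if (tr[length(tr)] == peaks[length(peaks)]) ok[length(peaks)] <- FALSE
    peaks <- peaks[ok]
    if (length(peaks) == 0) stop("no peaks found in recording")
    tr <- troughs_of(peaks)
  }
  list(peaks = peaks, troughs = tr)
}

#' Pre-process one raw PPG recording
#'
#' Runs the full conditioning chain: DC extraction on the raw signal,
#' AC band-pass, linear-interpolation upsampling, lower-envelope baseline
#' removal, and peak/trough detection on the corrected series.
#'
#' @param recording a `ppg_recording` (see [gen_recording()]) or a list
#'   with at least `samples` and `sampling_rate`.
#' @param upsample_factor integer upsampling factor (default 4).
#' @param dc_order,dc_cutoff,ac_order,ac_band filter settings.
#' @param min_separation,prominence_frac peak-detector settings.
#' @param envelope_separation knot refractory for the lower envelope, s.
#' @return object of class `ppg_processed`: the source metadata plus
#'   `dc_series`, `dc_value`, `ac_series` (upsampled, baseline-corrected),
#'   `envelope`, `upsampled_rate`, `peaks`, `troughs`.
#' @export
preprocess_recording <- function(recording, upsample_factor = 4,
                                 dc_order = 10, dc_cutoff = 0.01,
                                 ac_order = 8, ac_band = c(0.3, 10),
                                 min_separation = 0.3,
                                 prominence_frac = 0.3,
                                 envelope_separation = 0.5) {
  fs <- recording$sampling_rate
  dc_series <- extract_dc(recording$samples, fs, dc_order, dc_cutoff)
  ac <- extract_ac(recording$samples, fs, ac_order, ac_band)
  up <- upsample(ac, upsample_factor)
  up_rate <- fs * upsample_factor
  bl <- remove_baseline(up, up_rate, envelope_separation)
  pt <- detect_peaks_troughs(bl$corrected, up_rate, min_separation,
                             prominence_frac)
  structure(list(
    subject_id = recording$subject_id, day = recording$day,
    timepoint = recording$timepoint, repeat_index = recording$repeat_index,
    recording_id = recording$recording_id,
    reference_bgl = recording$reference_bgl, true_bgl = recording$true_bgl,
    sampling_rate = fs, upsampled_rate = up_rate,
    dc_series = dc_series, dc_value = mean(dc_series),
    ac_series = bl$corrected, envelope = bl$envelope,
    peaks = pt$peaks, troughs = pt$troughs
  ), class = "ppg_processed")
}

#' @export
print.ppg_processed <- function(x, ...) {
  cat(sprintf("<ppg_processed> %s: %d samples @ %g Hz, %d peaks, DC %.3g\n",
              x$recording_id %||% "?", length(x$ac_series),
              x$upsampled_rate, length(x$peaks), x$dc_value))
  invisible(x)
}
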