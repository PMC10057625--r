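#' Subject profile for the synthetic PPG cohort
#'
#' Describes one simulated subject: a glucose trajectory model (fasting
#' level, postprandial peak, rise/decay times, day-to-day and
#' within-day variability) and a glucose-to-PPG-morphology coupling.
#' The coupling encodes the empirical observation that PPG cycles show
#' higher amplitudes and narrower peaks at low glucose: the pulse
#' amplitude decreases linearly with glucose
#' (`amplitude_glucose_slope < 0`) and the pulse width increases
#' (`width_glucose_slope > 0`).
#'
#' Phenotype defaults are calibrated so that a 9-day simulation spans
#' the published per-phenotype glucose ranges (non-diabetic
#' 75.6-142.2, pre-diabetic 86.4-194.4, type 1 63.0-174.6, type 2
#' 183.6-345.7 mg/dL). The type 1 profile adds random insulin-event
#' perturbations (`insulin_event_sd`) so the fasting/postprandial
#' ordering can invert, mimicking the unpredictability of
#' insulin-treated glucose dynamics.
#'
#' @param subject_id short identifier.
#' @param phenotype one of `"non_diabetic"`, `"pre_diabetic"`,
#'   `"type1"`, `"type2"`.
#' @param ... overrides for any profile field (see Details).
#' @return object of class `subject_profile` (a named list).
#' @export
subject_profile <- function(subject_id,
                            phenotype = c("non_diabetic", "pre_diabetic",
                                          "type1", "type2"),
                            ...) {
  phenotype <- match.arg(phenotype)
  defaults <- list(
    non_diabetic = list(fasting_bgl = 90,  postprandial_peak_bgl = 142,
                        rise_time = 30, decay_time = 45,
                        bgl_noise_sd = 8,  insulin_event_sd = 0,
                        heart_rate = 68, artifact_rate = 7),
    pre_diabetic = list(fasting_bgl = 100, postprandial_peak_bgl = 194,
                        rise_time = 45, decay_time = 90,
                        bgl_noise_sd = 8,  insulin_event_sd = 0,
                        heart_rate = 72, artifact_rate = 7),
    type1        = list(fasting_bgl = 95,  postprandial_peak_bgl = 150,
                        rise_time = 40, decay_time = 60,
                        bgl_noise_sd = 8,  insulin_event_sd = 20,
                        heart_rate = 75, artifact_rate = 8),
    type2        = list(fasting_bgl = 200, postprandial_peak_bgl = 340,
                        rise_time = 60, decay_time = 180,
                        bgl_noise_sd = 10, insulin_event_sd = 0,
                        heart_rate = 80, artifact_rate = 9)
  )[[phenotype]]
  common <- list(
    cycle_amplitude_at_fasting = 1.0,
    amplitude_glucose_slope = -0.002,   # PPG units per mg/dL (negative)
    width_glucose_slope = 0.0003,       # s of pulse width per mg/dL (positive)
    dc_level = 100,
    systolic_width = 0.11,              # Gaussian sd of the systolic pulse, s
    baseline_wander_amplitude = 0.5,
    baseline_wander_freq = 0.2,
    noise_sd = 0.034,                   # ~20 dB SNR against the pulsatile rms
    artifact_amplitude = 0.5,           # burst noise sd, x fasting amplitude
    artifact_duration = 0.6,            # burst length, s
    heart_rate_jitter = 0.02            # per-cycle fractional HR jitter sd
  )
  p <- utils::modifyList(c(list(subject_id = subject_id,
                                phenotype = phenotype),
                           defaults, common),
                         list(...))
  if (p$fasting_bgl <= 0) stop("fasting_bgl must be positive")
  if (phenotype != "type1" && p$postprandial_peak_bgl < p$fasting_bgl)
    stop("postprandial_peak_bgl must be >= fasting_bgl for this phenotype")
  if (p$amplitude_glucose_slope >= 0)
    stop("amplitude_glucose_slope must be negative (amplitude shrinks with glucose)")
  if (p$width_glucose_slope <= 0)
    stop("width_glucose_slope must be positive (pulses widen with glucose)")
  structure(p, class = "subject_profile")
}

#' The default four-phenotype cohort
#'
#' One subject per diabetic condition, mirroring a four-subject
#' proof-of-concept cohort (non-diabetic, pre-diabetic, type 1, type 2).
#' @return list of four [subject_profile()] objects.
#' @export
default_cohort_profiles <- function() {
  list(subject_profile("S1", "non_diabetic"),
       subject_profile("S2", "pre_diabetic"),
       subject_profile("S3", "type1"),
       subject_profile("S4", "type2"))
}

#' Simulation schedule
#'
#' The recording protocol: each subject attends `n_days` days; on each
#' day the glucose and PPG are sampled at `timepoints` minutes relative
#' to breakfast (negative = fasting), with `recordings_per_timepoint`
#' back-to-back PPG recordings of `recording_duration` seconds per
#' glucometer measurement. The default follows the protocol of 9 days,
#' 2-minute recordings repeated twice, one fasting measurement plus
#' postprandial measurements up to 2 h after the meal.
#'
#' @param n_days number of recording days.
#' @param recordings_per_timepoint repeated PPG recordings per measurement.
#' @param recording_duration seconds per recording.
#' @param timepoints minutes since meal (negative = fasting).
#' @param sampling_rate PPG sampling rate, Hz.
#' @export
simulation_schedule <- function(n_days = 9, recordings_per_timepoint = 2,
                                recording_duration = 120,
                                timepoints = c(-5, 30, 60, 120),
                                sampling_rate = 100) {
  if (n_days < 1) stop("n_days must be >= 1")
  if (recording_duration <= 0) stop("recording_duration must be positive")
  if (length(timepoints) == 0) stop("timepoints must be non-empty")
  if (!any(timepoints < 0))
    stop("at least one fasting (negative) timepoint is required: the high/low split threshold is the fasting mean")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  structure(list(n_days = as.integer(n_days),
                 recordings_per_timepoint = as.integer(recordings_per_timepoint),
                 recording_duration = recording_duration,
                 timepoints = sort(timepoints),
                 sampling_rate = sampling_rate),
            class = "simulation_schedule")
}

# Deterministic meal-response curve: fasting level before the meal, a
# smooth sin^2 rise peaking exactly at `rise_time`, then exponential
# decay back towards fasting with time constant `decay_time`.
bgl_curve <- function(timepoint, profile) {
  f <- profile$fasting_bgl
  pk <- profile$postprandial_peak_bgl
  tr <- profile$rise_time
  shape <- ifelse(timepoint < 0, 0,
           ifelse(timepoint <= tr, sin(pi * timepoint / (2 * tr))^2,
                  exp(-(timepoint - tr) / profile$decay_time)))
  f + (pk - f) * shape
}

#' Simulate a subject's true glucose trajectory
#'
#' For each (day, timepoint) of the schedule: the deterministic meal
#' curve, plus a day-level offset (`bgl_noise_sd`), plus a smaller
#' within-day measurement-to-measurement jitter (`bgl_noise_sd / 2`),
#' plus - for profiles with `insulin_event_sd > 0` - an independent
#' per-timepoint insulin-event perturbation that can invert the
#' fasting/postprandial ordering. Values are clipped to 40-600 mg/dL.
#'
#' @param profile a [subject_profile()].
#' @param schedule a [simulation_schedule()].
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return `data.table` with columns `day`, `timepoint`, `true_bgl`.
#' @export
gen_glucose_profile <- function(profile, schedule, seed = NULL) {
  if (length(schedule$timepoints) == 0) stop("timepoints must be non-empty")
  with_seed(seed, {
    grid <- CJ(day = seq_len(schedule$n_days),
               timepoint = schedule$timepoints, sorted = FALSE)
    setorder(grid, day, timepoint)
    day_offset <- rnorm(schedule$n_days, 0, profile$bgl_noise_sd)
    n <- nrow(grid)
    tp_jitter <- rnorm(n, 0, profile$bgl_noise_sd / 2)
    insulin <- if (profile$insulin_event_sd > 0)
      rnorm(n, 0, profile$insulin_event_sd) else numeric(n)
    grid[, true_bgl := clip(bgl_curve(timepoint, profile) +
                              day_offset[day] + tp_jitter + insulin,
                            40, 600)]
    grid[]
  })
}

#' Generate one glucose-modulated PPG cycle
#'
#' One cardiac cycle of duration `60 / heart_rate` seconds, modelled as a
#' positive DC offset plus a Gaussian systolic pulse and a smaller,
#' delayed diastolic shoulder, normalised so the peak-to-trough span of
#' the cycle equals the pulse amplitude exactly. The glucose coupling is
#' linear: pulse amplitude `cycle_amplitude_at_fasting +
#' amplitude_glucose_slope * (bgl - fasting_bgl)` (floored at 10% of the
#' fasting amplitude) and systolic width `systolic_width +
#' width_glucose_slope * (bgl - fasting_bgl)` (floored at 30% of the
#' resting width).
#'
#' @param bgl blood glucose level, mg/dL.
#' @param profile a [subject_profile()].
#' @param sampling_rate Hz.
#' @param heart_rate optional beats/min override (per-cycle jitter).
#' @return numeric waveform of `round(60 / heart_rate * sampling_rate)`
#'   samples.
#' @export
gen_ppg_cycle <- function(bgl, profile, sampling_rate, heart_rate = NULL) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (bgl <= 0) stop("bgl must be positive")
  hr <- heart_rate %||% profile$heart_rate
  period <- 60 / hr
  n <- round(period * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  dg <- bgl - profile$fasting_bgl
  amp <- max(profile$cycle_amplitude_at_fasting +
               profile$amplitude_glucose_slope * dg,
             0.1 * profile$cycle_amplitude_at_fasting)
  sw <- max(profile$systolic_width + profile$width_glucose_slope * dg,
            0.3 * profile$systolic_width)
  ts <- 0.3 * period
  td <- ts + 0.18 * period
  pulse <- exp(-(t - ts)^2 / (2 * sw^2)) +
    0.35 * exp(-(t - td)^2 / (2 * (1.4 * sw)^2))
  # normalise so the cycle's peak-to-trough span is exactly `amp`
  profile$dc_level + amp * (pulse - min(pulse)) / (max(pulse) - min(pulse))
}

#' Generate one raw PPG recording
#'
#' Concatenates glucose-modulated cycles with per-cycle heart-rate
#' jitter until the scheduled duration is filled, then adds sinusoidal
#' baseline wander, white sensor noise, and Poisson-placed motion
#' artifact bursts (0.6 s of high-amplitude broadband noise). The
#' reference glucometer reading is the true BGL plus zero-mean noise
#' with sd `glucometer_cv * true_bgl`, clipped to the glucometer's
#' 10-600 mg/dL measuring interval.
#'
#' @param profile a [subject_profile()].
#' @param schedule a [simulation_schedule()].
#' @param day 1-based day index.
#' @param timepoint minutes since meal (must be in the schedule).
#' @param true_bgl simulation ground-truth BGL for this measurement; if
#'   `NULL` it is derived from [gen_glucose_profile()] (seeded).
#' @param repeat_index which of the repeated recordings this is.
#' @param glucometer_cv coefficient of variation of the reference meter.
#' @param seed optional integer seed.
#' @return object of class `ppg_recording`.
#' @export
gen_recording <- function(profile, schedule, day, timepoint,
                          true_bgl = NULL, repeat_index = 1L,
                          glucometer_cv = 0.05, seed = NULL) {
  if (!day %in% seq_len(schedule$n_days))
    stop("`day` is not in the schedule")
  if (!timepoint %in% schedule$timepoints)
    stop("`timepoint` is not in the schedule")
  with_seed(seed, {
    if (is.null(true_bgl)) {
      gp <- gen_glucose_profile(profile, schedule)
      true_bgl <- gp[gp$day == day & gp$timepoint == timepoint]$true_bgl[1]
    }
    fs <- schedule$sampling_rate
    n_target <- round(schedule$recording_duration * fs)
    chunks <- list()
    total <- 0L
    while (total < n_target + fs) {
      hr <- profile$heart_rate *
        (1 + profile$heart_rate_jitter * rnorm(1))
      cyc <- gen_ppg_cycle(true_bgl, profile, fs, heart_rate = hr)
      chunks[[length(chunks) + 1L]] <- cyc
      total <- total + length(cyc)
    }
    x <- unlist(chunks, use.names = FALSE)[seq_len(n_target)]
    t <- (seq_len(n_target) - 1) / fs
    if (profile$baseline_wander_amplitude > 0) {
      x <- x + profile$baseline_wander_amplitude *
        sin(2 * pi * profile$baseline_wander_freq * t + runif(1, 0, 2 * pi))
    }
    if (profile$noise_sd > 0) x <- x + rnorm(n_target, 0, profile$noise_sd)
    n_art <- rpois(1, profile$artifact_rate *
                     schedule$recording_duration / 60)
    if (n_art > 0) {
      burst_len <- round(profile$artifact_duration * fs)
      amp <- profile$artifact_amplitude * profile$cycle_amplitude_at_fasting
      for (k in seq_len(n_art)) {
        start <- sample.int(n_target - burst_len, 1)
        span <- start:(start + burst_len - 1)
        x[span] <- x[span] + amp * rnorm(burst_len)
      }
    }
    reference_bgl <- clip(true_bgl + rnorm(1, 0, glucometer_cv * true_bgl),
                          10, 600)
    structure(list(
      subject_id = profile$subject_id, phenotype = profile$phenotype,
      day = as.integer(day), timepoint = timepoint,
      repeat_index = as.integer(repeat_index),
      recording_id = sprintf("%s_d%02d_t%+04d_r%d", profile$subject_id,
                             as.integer(day), round(timepoint),
                             as.integer(repeat_index)),
      sampling_rate = fs, samples = x,
      reference_bgl = reference_bgl, true_bgl = true_bgl
    ), class = "ppg_recording")
  })
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording> %s: %g s @ %g Hz, ref BGL %.1f mg/dL\n",
              x$recording_id, length(x$samples) / x$sampling_rate,
              x$sampling_rate, x$reference_bgl))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' One recording per (subject, day, timepoint, repeat). All randomness is
#' drawn from a single seeded stream in a fixed order, so identical
#' `(profiles, schedule, seed)` yield identical cohorts.
#'
#' @param profiles list of [subject_profile()] objects (unique ids).
#' @param schedule a [simulation_schedule()].
#' @param seed integer seed.
#' @param glucometer_cv reference-meter coefficient of variation.
#' @param out_dir if non-`NULL`, the cohort is also written to disk via
#'   [write_cohort()].
#' @return object of class `ppg_cohort`: list with `recordings` (list of
#'   `ppg_recording`) and `metadata` (a `data.table`), plus the seed.
#' @export
gen_cohort <- function(profiles, schedule = simulation_schedule(),
                       seed = 1L, glucometer_cv = 0.05, out_dir = NULL) {
  if (length(profiles) < 1) stop("need at least one profile")
  ids <- vapply(profiles, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  recordings <- list()
  meta <- list()
  with_seed(seed, {
    for (profile in profiles) {
      gp <- gen_glucose_profile(profile, schedule)
      for (i in seq_len(nrow(gp))) {
        for (r in seq_len(schedule$recordings_per_timepoint)) {
          rec <- gen_recording(profile, schedule, gp$day[i],
                               gp$timepoint[i], true_bgl = gp$true_bgl[i],
                               repeat_index = r,
                               glucometer_cv = glucometer_cv)
          recordings[[rec$recording_id]] <- rec
          meta[[length(meta) + 1L]] <- data.table(
            subject_id = rec$subject_id, phenotype = rec$phenotype,
            day = rec$day, timepoint_min = rec$timepoint,
            repeat_index = rec$repeat_index,
            sampling_rate_hz = rec$sampling_rate,
            reference_bgl_mgdl = rec$reference_bgl,
            true_bgl_mgdl = rec$true_bgl,
            file = paste0(rec$recording_id, ".csv"),
            recording_id = rec$recording_id)
        }
      }
    }
  })
  cohort <- structure(list(recordings = recordings,
                           metadata = rbindlist(meta),
                           schedule = schedule, seed = seed),
                      class = "ppg_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat(sprintf("<ppg_cohort> %d recordings, %d subjects, seed %s\n",
              length(x$recordings),
              length(unique(x$metadata$subject_id)), x$seed))
  invisible(x)
}
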