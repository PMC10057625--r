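# Synthetic cohort generator: glucose trajectories, glucose-modulated
# cycles, recordings and cohorts.

test_that("glucose profile honours fasting level and peak timing", {
  sch <- simulation_schedule(timepoints = c(-5, 30, 60))
  p <- noise_free_profile()  # fasting 90, peak 142, zero noise
  gp <- gen_glucose_profile(p, sch, seed = 1)
  expect_equal(gp[gp$timepoint < 0]$true_bgl, rep(90, sch$n_days))

  # curve evaluated exactly at rise_time returns the postprandial peak
  p2 <- noise_free_profile(rise_time = 30, decay_time = 30)
  gp2 <- gen_glucose_profile(p2, sch, seed = 1)
  expect_equal(gp2[gp2$timepoint == 30]$true_bgl, rep(142, sch$n_days))
})

test_that("type-2 defaults track the published 183.6-345.7 mg/dL range", {
  p <- subject_profile("S4", "type2")
  gp <- gen_glucose_profile(p, simulation_schedule(), seed = 42)
  expect_gte(min(gp$true_bgl), 183.6 * 0.85)
  expect_lte(max(gp$true_bgl), 345.7 * 1.15)
})

test_that("cycle amplitude follows the linear glucose coupling", {
  p <- noise_free_profile()
  cyc <- gen_ppg_cycle(p$fasting_bgl, p, 400)
  expect_equal(max(cyc) - min(cyc), p$cycle_amplitude_at_fasting,
               tolerance = 0.02)

  # slope -0.002/ (mg/dL), fasting amplitude 1.0, +100 mg/dL -> 0.8
  cyc_hi <- gen_ppg_cycle(p$fasting_bgl + 100, p, 400)
  expect_equal(max(cyc_hi) - min(cyc_hi), 0.8, tolerance = 0.03)

  expect_error(gen_ppg_cycle(90, p, -10), "sampling_rate")
  expect_error(gen_ppg_cycle(-5, p, 100), "bgl")
})

fwhm <- function(y, rate) {
  level <- min(y) + (max(y) - min(y)) / 2
  above <- which(y > level)
  (above[length(above)] - above[1]) / rate
}

test_that("low-glucose cycles are taller and narrower (measured)", {
  p <- noise_free_profile()
  lo <- gen_ppg_cycle(80, p, 1000)
  hi <- gen_ppg_cycle(200, p, 1000)
  expect_gt(max(lo) - min(lo), max(hi) - min(hi))
  expect_lt(fwhm(lo, 1000), fwhm(hi, 1000))
})

test_that("coupling is strictly monotone over a BGL grid", {
  p <- noise_free_profile()
  grid <- seq(60, 300, by = 30)
  amps <- widths <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cyc <- gen_ppg_cycle(grid[i], p, 1000)
    amps[i] <- max(cyc) - min(cyc)
    widths[i] <- fwhm(cyc, 1000)
  }
  expect_true(all(diff(amps) < 0))
  expect_true(all(diff(widths) > 0))
})

test_that("recordings have the scheduled length and are seed-deterministic", {
  p <- subject_profile("X", "non_diabetic")
  sch <- simulation_schedule(recording_duration = 30)
  r1 <- gen_recording(p, sch, 2, 30, true_bgl = 120, seed = 5)
  r2 <- gen_recording(p, sch, 2, 30, true_bgl = 120, seed = 5)
  expect_length(r1$samples, 30 * sch$sampling_rate)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$reference_bgl, r2$reference_bgl)
  expect_error(gen_recording(p, sch, 99, 30, true_bgl = 120), "day")
})

test_that("a noise-free recording is a near-periodic cycle train", {
  rec <- clean_recording()  # hr 60, 120 s, no noise/jitter/artifacts
  proc <- preprocess_recording(rec)
  cycles <- segment_cycles(proc)
  tpl <- build_template(cycles)
  qc <- filter_cycles(cycles, tpl)
  interior <- qc$correlations[3:(length(qc$correlations) - 2)]
  expect_true(all(interior > 0.99))
  expect_gte(length(cycles), 118)
  expect_lte(length(cycles), 120)
})

test_that("default cohort bookkeeping matches the stated protocol", {
  prof <- list(subject_profile("A", "non_diabetic"))
  sch1 <- simulation_schedule(n_days = 1, recordings_per_timepoint = 1,
                              timepoints = c(-5), recording_duration = 10)
  one <- gen_cohort(prof, sch1, seed = 3)
  expect_length(one$recordings, 1)

  # default schedule: 9 days x 4 timepoints x 2 repeats = 72 per subject,
  # inside the observed per-subject range of 44-84 recordings
  counts <- simulation_schedule()
  expect_equal(counts$n_days * length(counts$timepoints) *
                 counts$recordings_per_timepoint, 72)

  expect_error(gen_cohort(list(subject_profile("A", "type1"),
                               subject_profile("A", "type2")),
                          sch1, seed = 1), "duplicate")
})

test_that("cohorts are deterministic and cover the phenotype ranges", {
  sch <- simulation_schedule(recording_duration = 5,
                             recordings_per_timepoint = 1)
  c1 <- gen_cohort(default_cohort_profiles(), sch, seed = 42)
  c2 <- gen_cohort(default_cohort_profiles(), sch, seed = 42)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$recordings[[10]]$samples, c2$recordings[[10]]$samples)

  # per-subject min/max true BGL within +/-15% of the published ranges
  ranges <- list(S1 = c(75.6, 142.2), S2 = c(86.4, 194.4),
                 S3 = c(63.0, 174.6), S4 = c(183.6, 345.7))
  m <- c1$metadata
  for (sid in names(ranges)) {
    tb <- m[m$subject_id == sid]$true_bgl_mgdl
    expect_gte(min(tb), ranges[[sid]][1] * 0.85)
    expect_lte(min(tb), ranges[[sid]][1] * 1.15)
    expect_gte(max(tb), ranges[[sid]][2] * 0.85)
    expect_lte(max(tb), ranges[[sid]][2] * 1.15)
  }
})
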