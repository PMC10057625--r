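# Segmentation, matched-filter template QC, TKEO and feature extraction.

test_that("segmentation yields one cycle per interior peak with shared troughs", {
  proc <- preprocess_recording(clean_recording())
  cycles <- segment_cycles(proc)
  expect_gte(length(cycles), 118)
  expect_lte(length(cycles), 120)
  # right trough of cycle k is the left trough of cycle k+1
  for (k in seq_len(length(cycles) - 1)) {
    expect_identical(cycles[[k]]$right_trough_value,
                     cycles[[k + 1]]$left_trough_value)
  }
  durs <- vapply(cycles, `[[`, numeric(1), "duration")
  expect_true(all(durs > 0))
  pk <- vapply(cycles, `[[`, numeric(1), "peak_value")
  lt <- vapply(cycles, `[[`, numeric(1), "left_trough_value")
  rt <- vapply(cycles, `[[`, numeric(1), "right_trough_value")
  expect_true(all(pk >= pmax(lt, rt)))
})

test_that("template averages the middle ten cycles", {
  # identical cycles: template equals any one of them resampled
  cyc <- triangle_cycle()
  cycles <- replicate(20, cyc, simplify = FALSE)
  tpl <- build_template(cycles, template_length = 100)
  expect_equal(tpl$waveform, resample_linear(cyc$samples, 100),
               tolerance = 1e-9)
  expect_equal(tpl$n_source_cycles, 10)

  # fewer than ten -> all are used
  tpl5 <- build_template(cycles[1:5])
  expect_equal(tpl5$n_source_cycles, 5)
  expect_error(build_template(list()), "zero cycles")
})

test_that("middle-ten selection matches a brute-force closest-to-centre oracle", {
  closest_ten <- function(n) {
    centre <- n %/% 2                       # 0-based centre index
    d <- abs((seq_len(n) - 1) - centre)
    # ten smallest distances, ties resolved towards the lower index
    order(d, seq_len(n))[1:10]
  }
  for (n in c(10, 11, 15, 20, 30, 31, 101)) {
    got <- ppglucose:::middle_ten(n)
    expect_length(got, 10)
    expect_setequal(got, sort(closest_ten(n)))
  }
  # the documented example: n = 30 -> 0-based indices 10..19
  expect_equal(ppglucose:::middle_ten(30) - 1L, 10:19)
})

test_that("matched filter keeps faithful cycles and rejects noise", {
  cyc <- triangle_cycle()
  cycles <- replicate(12, cyc, simplify = FALSE)
  tpl <- build_template(cycles)
  qc <- filter_cycles(cycles, tpl)
  expect_true(all(qc$correlations == 1))
  expect_length(qc$rejected, 0)

  # replace one cycle by white noise: it is the only rejection
  set.seed(7)
  cycles[[3]] <- make_cycle(rnorm(101))
  tpl <- build_template(cycles)
  qc <- filter_cycles(cycles, tpl)
  expect_lt(qc$correlations[3], 0.5)
  expect_length(qc$rejected, 1)

  # zero-variance cycle: r defined as 0, rejected
  cycles[[3]] <- make_cycle(rep(1, 101))
  qc <- filter_cycles(cycles, build_template(cycles[-3]))
  expect_identical(qc$correlations[3], 0)
})

test_that("filter_cycles agrees with a direct Pearson recomputation", {
  set.seed(11)
  for (rep in 1:25) {
    cycles <- lapply(1:8, function(i) {
      t <- seq(0, 1, length.out = sample(60:140, 1))
      make_cycle(sin(pi * t)^2 + rnorm(length(t), 0, 0.2))
    })
    tpl <- build_template(cycles)
    qc <- filter_cycles(cycles, tpl)
    manual <- vapply(cycles, function(cy) {
      y <- approx(seq(0, 1, length.out = length(cy$samples)), cy$samples,
                  xout = seq(0, 1, length.out = 100))$y
      my <- mean(y); mt <- mean(tpl$waveform)
      sum((y - my) * (tpl$waveform - mt)) /
        sqrt(sum((y - my)^2) * sum((tpl$waveform - mt)^2))
    }, numeric(1))
    expect_equal(qc$correlations, manual, tolerance = 1e-12)
  }
})

test_that("TKEO closed forms hold", {
  expect_equal(tkeo(rep(3, 4)), c(0, 0))
  expect_equal(tkeo(1:10), rep(1, 8))
  n <- 0:499
  e <- tkeo(sin(0.2 * n))
  expect_lt(max(abs(e - sin(0.2)^2)), 1e-9)
  expect_error(tkeo(c(1, 2)), "3 samples")
})

test_that("triangle-cycle features match their geometry", {
  fv <- extract_features(triangle_cycle())
  expect_length(fv, 18)
  expect_identical(names(fv), feature_names())
  expect_equal(unname(fv["delta_ac"]), 1)
  expect_equal(unname(fv["rise_time"]), 0.5)
  expect_equal(unname(fv["fall_time"]), 0.5)
  expect_equal(unname(fv["rise_slope"]), 2)
  expect_equal(unname(fv["fall_slope"]), -2)
  expect_equal(unname(fv["base_width"]), 1)
  expect_equal(unname(fv["width_quarter"]), 0.75, tolerance = 1e-9)
  expect_equal(unname(fv["width_three_quarter"]), 0.25, tolerance = 1e-9)
  expect_equal(unname(fv["area"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(fv["tkeo_std"])^2, unname(fv["tkeo_variance"]),
               tolerance = 1e-12)
  expect_all_finite(fv)
})

test_that("optical density follows its closed form", {
  cyc <- triangle_cycle(dc = 100)
  expect_equal(unname(extract_features(cyc)["optical_density"]),
               log10(1 + 1 / 100))
  # delta_ac == dc -> log10(2)
  cyc1 <- triangle_cycle(dc = 1)
  expect_equal(unname(extract_features(cyc1)["optical_density"]),
               log10(2), tolerance = 1e-12)
  # flat cycle -> delta_ac 0 -> OD 0
  flat <- make_cycle(rep(0, 100), peak_offset = 50)
  expect_equal(unname(extract_features(flat)["optical_density"]), 0)
  # dc <= 0 -> undefined -> dropped with warning
  bad <- triangle_cycle(dc = 0)
  expect_warning(out <- extract_features(bad), "optical density")
  expect_null(out)
})

test_that("features scale as amplitudes (x alpha) vs timings (invariant)", {
  cyc <- triangle_cycle()
  a <- 3.2
  scaled <- make_cycle(a * cyc$samples, rate = 100)
  f1 <- extract_features(cyc)
  f2 <- extract_features(scaled)
  amp_feats <- c("peak_value", "delta_ac", "rise_slope", "fall_level",
                 "fall_slope", "area")
  time_feats <- c("rise_time", "fall_time", "width_quarter",
                  "width_three_quarter", "base_width")
  expect_equal(unname(f2[amp_feats]), unname(a * f1[amp_feats]),
               tolerance = 1e-9)
  expect_equal(unname(f2[time_feats]), unname(f1[time_feats]),
               tolerance = 1e-9)
})

test_that("extracted features track the glucose coupling on clean cycles", {
  p <- noise_free_profile()
  grid <- seq(60, 280, by = 20)
  feats <- t(vapply(grid, function(g) {
    y <- gen_ppg_cycle(g, p, 400)
    cyc <- make_cycle(y - min(y), rate = 400)
    extract_features(cyc)
  }, numeric(18)))
  expect_true(all(diff(feats[, "delta_ac"]) < 0))
  expect_true(all(diff(feats[, "width_quarter"]) > 0))
})
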