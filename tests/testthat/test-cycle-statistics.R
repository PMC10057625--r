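# Fasting-mean split, pointwise ensemble-cycle comparison, feature ranking.

test_that("fasting-mean threshold and boundary routing", {
  cycles <- lapply(c(85, 89.9, 90, 95, 130), function(b) {
    cy <- triangle_cycle(); cy$bgl_label <- b; cy
  })
  split <- split_by_fasting_mean(cycles, c(90, 92, 88))
  expect_equal(split$threshold, 90)
  lows <- vapply(split$low, `[[`, numeric(1), "bgl_label")
  highs <- vapply(split$high, `[[`, numeric(1), "bgl_label")
  expect_setequal(lows, c(85, 89.9))        # 89.9 -> low
  expect_setequal(highs, c(90, 95, 130))    # boundary 90 -> high
  expect_error(split_by_fasting_mean(cycles, numeric(0)), "fasting")
  expect_warning(split_by_fasting_mean(cycles, c(300)), "one side")
})

test_that("threshold shifts by exactly c under a BGL translation", {
  set.seed(3)
  bgls <- runif(40, 80, 180)
  fasting <- runif(5, 85, 95)
  tab <- data.frame(bgl_label = bgls)
  s0 <- split_by_fasting_mean(tab, fasting)
  s1 <- split_by_fasting_mean(transform(tab, bgl_label = bgl_label + 25),
                              fasting + 25)
  expect_equal(s1$threshold, s0$threshold + 25)
  expect_equal(nrow(s1$low), nrow(s0$low))
  expect_equal(s1$low$bgl_label, s0$low$bgl_label + 25)
})

test_that("identical groups produce an empty rejection mask", {
  cycles <- replicate(8, triangle_cycle(), simplify = FALSE)
  split <- structure(list(threshold = 1, low = cycles[1:4],
                          high = cycles[5:8]), class = "glucose_split")
  cmp <- compare_cycles(split)
  expect_false(any(cmp$reject_mask))
  expect_equal(cmp$mean_low, cmp$mean_high)
  expect_error(compare_cycles(structure(list(low = cycles[1],
                                             high = cycles[2:4]),
                                        class = "glucose_split")),
               "at least 2")
})

test_that("a 5-sigma amplitude difference is detected at the peak", {
  set.seed(21)
  noise_sd <- 0.05
  gen_group <- function(n, amp) lapply(seq_len(n), function(i) {
    t <- seq(0, 1, length.out = 100)
    make_cycle(amp * sin(pi * t)^2 + rnorm(100, 0, noise_sd))
  })
  split <- structure(list(low = gen_group(100, 1 + 5 * noise_sd),
                          high = gen_group(100, 1)),
                     class = "glucose_split")
  cmp <- compare_cycles(split)
  peak_region <- 45:55
  expect_true(all(cmp$reject_mask[peak_region]))
})

test_that("Welch statistic matches a hand computation on 3-sample groups", {
  a <- c(1.0, 1.4, 1.1)
  b <- c(2.0, 2.6, 2.9)
  w <- ppglucose:::welch_t_cols(matrix(a), matrix(b))
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  # and against the stock implementation
  tt <- t.test(a, b)
  expect_equal(unname(w$t), unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w$p, tt$p.value, tolerance = 1e-12)
})

test_that("feature ranking orders by percentage difference", {
  set.seed(5)
  n <- 30
  base <- as.data.frame(matrix(rnorm(n * 18, 10, 0.01), n, 18))
  names(base) <- feature_names()
  low <- base
  high <- base
  high$delta_ac <- high$delta_ac * 1.2      # 20% difference
  high$area <- high$area * 1.05             # 5% difference
  split <- structure(list(low = low, high = high), class = "glucose_split")
  rk <- rank_features(split)
  expect_equal(rk$feature[1], "delta_ac")
  expect_equal(rk$feature[2], "area")
  expect_equal(rk$percent_difference[1], 20, tolerance = 0.2)
  expect_equal(rk$percent_difference[2], 5, tolerance = 0.2)

  # identical groups -> all zero
  rk0 <- rank_features(structure(list(low = base, high = base),
                                 class = "glucose_split"))
  expect_true(all(rk0$percent_difference == 0))

  # zero low-group mean -> flagged NA and placed last
  low2 <- base; high2 <- base
  low2$tkeo_mean <- 0
  rk2 <- rank_features(structure(list(low = low2, high = high2),
                                 class = "glucose_split"))
  expect_true(is.na(rk2$percent_difference[18]))
  expect_equal(rk2$feature[18], "tkeo_mean")
})
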