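test_that("noise-free ovulatory cycles have the exact constructed geometry", {
  s <- clean_cycle(len = 28, luteal = 14, f = 36.3, shift = 0.4, nadir = 0.2)
  t <- s$data$temp_c
  expect_equal(s$truth$ovulation_day, 14)
  # luteal days sit exactly shift above the follicular plateau
  expect_equal(t[15:28], rep(36.7, 14))
  expect_equal(t[1:13], rep(36.3, 13))
  expect_equal(max(t[15:28]) - min(t[15:28]), 0)
  # the ovulation day is the cycle minimum (the nadir)
  expect_equal(which.min(t), 14)
  expect_equal(t[14], 36.1)
})

test_that("anovulatory cycles are flat at the follicular mean", {
  s <- clean_cycle(ovulatory = FALSE)
  expect_true(all(s$data$temp_c == 36.3))
  expect_true(is.na(s$truth$ovulation_day))
})

test_that("fever days are elevated and flagged; missing days stay missing", {
  p <- cycle_params(cycle_length = 28, luteal_length = 14, daily_noise_sd = 0,
                    missing_prob = 0, fever_days = c(5, 6), fever_delta = 0.8)
  s <- generate_cycle(p, seed = 1)
  expect_equal(s$data$temp_c[5:6], rep(36.29 + 0.8, 2))
  expect_equal(s$data$illness, seq_len(28) %in% c(5, 6))

  p2 <- cycle_params(cycle_length = 28, luteal_length = 14, missing_prob = 0.5)
  s2 <- generate_cycle(p2, seed = 7)
  expect_true(anyNA(s2$data$temp_c))
})

test_that("invalid cycle parameters are rejected", {
  expect_error(cycle_params(cycle_length = 28, luteal_length = 28), "luteal")
  expect_error(cycle_params(daily_noise_sd = -0.1), "daily_noise_sd")
  expect_error(cycle_params(missing_prob = 1), "missing_prob")
  expect_error(device_model(clip_low = 37, clip_high = 36), "clip_low")
})

test_that("mean luteal-follicular contrast recovers the shift magnitude", {
  set.seed(42)
  contrasts <- replicate(500, {
    p <- cycle_params(cycle_length = 28, luteal_length = 14,
                      shift_magnitude = 0.3, daily_noise_sd = 0.1,
                      missing_prob = 0, nadir_depth = 0.15)
    s <- generate_cycle(p)
    t <- s$data$temp_c
    mean(t[15:28]) - mean(t[1:13])
  })
  expect_lt(abs(mean(contrasts) - 0.3), 0.02)
})

test_that("fraction of missing days converges to missing_prob", {
  set.seed(3)
  n_na <- 0; n_days <- 0
  for (i in 1:357) {
    p <- cycle_params(cycle_length = 28, luteal_length = 14, missing_prob = 0.1)
    s <- generate_cycle(p)
    n_na <- n_na + sum(is.na(s$data$temp_c))
    n_days <- n_days + 28
  }
  ci <- binom.test(n_na, n_days, p = 0.1, conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.1 && 0.1 <= ci[2])
})

test_that("post-stabilization stream minutes equal the device affine transform", {
  s <- clean_cycle(f = 36.4, shift = 0, nadir = 0, ovulatory = FALSE)
  dev <- device_model(bias_at_reference = -1.8, proportional_bias_slope = 0,
                      stream_noise_sd = 0, night_effect_sd = 0,
                      stabilization_minutes = 30)
  st <- generate_overnight_stream(s, 1, dev, seed = 1, night_effect = 0)
  on <- st$data$temp_c[st$data$on_body]
  expect_equal(on[31:480], rep(36.4 - 1.8, 450))
  # stabilization ramp climbs from 2 C below the level
  expect_lt(on[1], 34.6 - 1.5)
  expect_true(all(diff(on[1:30]) > 0))
})

test_that("noisy post-stabilization stream mean matches the level to sampling precision", {
  s <- clean_cycle(f = 36.4, shift = 0, nadir = 0, ovulatory = FALSE)
  dev <- device_model(stream_noise_sd = 0.15, night_effect_sd = 0,
                      stabilization_minutes = 30)
  st <- generate_overnight_stream(s, 1, dev, seed = 5, night_effect = 0)
  on <- st$data$temp_c[st$data$on_body]
  level <- 36.4 - 1.8
  expect_lt(abs(mean(on[31:480]) - level), 4 * 0.15 / sqrt(450))
})

test_that("a negative proportional-bias slope widens the difference at lower temperatures", {
  dev <- device_model(bias_at_reference = -1.8, proportional_bias_slope = -0.5,
                      stream_noise_sd = 0, night_effect_sd = 0,
                      stabilization_minutes = 0)
  warm <- clean_cycle(f = 36.4, ovulatory = FALSE)
  cool <- clean_cycle(f = 35.4, ovulatory = FALSE)
  st_w <- generate_overnight_stream(warm, 1, dev, seed = 1, night_effect = 0)
  st_c <- generate_overnight_stream(cool, 1, dev, seed = 1, night_effect = 0)
  diff_warm <- 36.4 - mean(st_w$data$temp_c[st_w$data$on_body])
  diff_cool <- 35.4 - mean(st_c$data$temp_c[st_c$data$on_body])
  expect_gt(diff_cool, diff_warm)
  expect_equal(diff_warm, 1.8)
  expect_equal(diff_cool, 1.8 + 0.5)
})

test_that("stream values respect the device recording limits", {
  s <- clean_cycle(f = 36.4, ovulatory = FALSE)
  dev <- device_model(night_effect_sd = 0)
  st <- generate_overnight_stream(s, 1, dev, seed = 2, night_effect = -8)
  expect_true(all(st$data$temp_c >= dev$clip_low))
  expect_true(all(st$data$temp_c <= dev$clip_high))
})

test_that("a non-wear night is off-body throughout", {
  s <- clean_cycle()
  st <- generate_overnight_stream(s, 3, device_model(), seed = 1, worn = FALSE)
  expect_false(any(st$data$on_body))
})

test_that("ground-truth ovulatory fractions behave binomially", {
  cfg <- cohort_config(n_participants = 10, fraction_ovulatory = 1,
                       fraction_control = 0, seed = 11)
  co <- generate_cohort(cfg, streams = FALSE)
  expect_equal(sum(co$truth$ovulatory), 10)

  cfg2 <- cohort_config(n_participants = 1000, fraction_ovulatory = 0.5,
                        fraction_control = 0, seed = 12)
  co2 <- generate_cohort(cfg2, streams = FALSE)
  k <- sum(co2$truth$ovulatory)
  ci99 <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_true(k >= ci99[1] && k <= ci99[2])
})

test_that("regenerating a cohort with the same seed is bit-identical on disk", {
  cfg <- cohort_config(n_participants = 3, seed = 99)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in c("daily.csv", "minutes.csv", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
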