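test_that("expected ovulation day leaves two weeks to the next menses", {
  expect_equal(expected_ovulation_day(clean_cycle(len = 28, luteal = 14)), 15)
  expect_equal(expected_ovulation_day(clean_cycle(len = 21, luteal = 12)), 8)
  s <- clean_cycle()
  s$next_menses_known <- FALSE
  expect_true(is.na(expected_ovulation_day(s)))
})

test_that("the three-over-six shift is found exactly where constructed", {
  s <- clean_cycle(len = 28, luteal = 14, shift = 0.4)
  res <- detect_biphasic_shift(s)
  expect_equal(res$shift_day, 15)
  expect_false(res$undetermined)

  flat <- clean_cycle(ovulatory = FALSE)
  res_flat <- detect_biphasic_shift(flat)
  expect_true(is.na(res_flat$shift_day))
  expect_false(res_flat$undetermined)
})

test_that("a shift of exactly the threshold does not count (strict >0.2)", {
  s <- clean_cycle(shift = 0.2, nadir = 0)
  expect_true(is.na(detect_biphasic_shift(s)$shift_day))
  s2 <- clean_cycle(shift = 0.21, nadir = 0)
  expect_equal(detect_biphasic_shift(s2)$shift_day, 15)
})

test_that("too few evaluable candidate days is undetermined, not anovulatory", {
  s <- clean_cycle(len = 28, luteal = 14)
  s$data$temp_c[1:14] <- NA  # <6 observed days before every candidate
  res <- detect_biphasic_shift(s)
  expect_true(res$undetermined)
})

test_that("shift detection matches an exhaustive scan on random cycles", {
  set.seed(101)
  for (i in 1:40) {
    temps <- random_cycle_temps(28)
    s <- cycle_series("PX", temps)
    center <- expected_ovulation_day(s)
    mine <- detect_biphasic_shift(s, center, 4L)
    oracle <- biphasic_bruteforce(temps, center - 4, center + 4)
    expect_equal(mine$shift_day, oracle$shift_day)
    expect_equal(mine$undetermined, oracle$undetermined)
  }
})

test_that("thermal-shift adequacy enforces duration, rise speed and no deep falls", {
  good <- clean_cycle(len = 28, luteal = 14)
  res <- check_thermal_shift_adequacy(good, 15)
  expect_true(res$passed)
  expect_equal(res$luteal_length, 14)
  expect_equal(res$rise_days, 1)

  short <- clean_cycle(len = 28, luteal = 8)
  res_s <- check_thermal_shift_adequacy(short, 21)
  expect_false(res_s$passed)
  expect_match(res_s$detail, "sustained")

  dip <- clean_cycle(len = 28, luteal = 14)
  dip$data$temp_c[20] <- 36.3  # falls back to the follicular level for a day
  res_d <- check_thermal_shift_adequacy(dip, 15)
  expect_false(res_d$passed)
  expect_match(res_d$detail, "deep fall")

  gappy <- clean_cycle(len = 28, luteal = 14)
  gappy$data$temp_c[c(17, 20, 23)] <- NA
  expect_true(is.na(check_thermal_shift_adequacy(gappy, 15)$passed))
})

test_that("the nadir is found when constructed and absent otherwise", {
  s <- clean_cycle(nadir = 0.2)
  expect_equal(detect_nadir(s, 15), 14)

  none <- clean_cycle(nadir = 0)
  expect_true(is.na(detect_nadir(none, 15)))

  rising <- cycle_series("PX", 36 + (1:28) * 0.05)
  expect_true(is.na(detect_nadir(rising, 15)))
})

test_that("visual classification maps archetypes to the right categories", {
  ov <- classify_visual(clean_cycle())
  expect_equal(ov$category, "ovulatory")
  expect_equal(ov$shift_day, 15)
  expect_equal(ov$nadir_day, 14)
  expect_gte(ov$luteal_length_days, 11)

  an <- classify_visual(clean_cycle(ovulatory = FALSE))
  expect_equal(an$category, "anovulatory")

  short <- cycle_series("PX", rep(36.3, 4))
  expect_equal(classify_visual(short)$category, "inconclusive")
})

test_that("visual classification is invariant to off-window missing days", {
  s <- clean_cycle(len = 30, luteal = 15)
  base <- classify_visual(s)
  s$data$temp_c[c(2, 3)] <- NA  # early follicular days, outside every window
  with_gaps <- classify_visual(s)
  expect_equal(with_gaps$category, base$category)
  expect_equal(with_gaps$shift_day, base$shift_day)
})

test_that("an unobserved next menses makes the call inconclusive", {
  s <- clean_cycle()
  s$next_menses_known <- FALSE
  expect_equal(classify_visual(s)$category, "inconclusive")
})

test_that("raising the shift never flips ovulatory to anovulatory", {
  set.seed(55)
  for (i in 1:20) {
    noise <- rnorm(28, 0, 0.05)
    shifts <- c(0.25, 0.35, 0.5)
    cats <- vapply(shifts, function(sh) {
      p <- cycle_params(cycle_length = 28, luteal_length = 14,
                        shift_magnitude = sh, daily_noise_sd = 0,
                        missing_prob = 0, nadir_depth = 0.15)
      s <- generate_cycle(p)
      s$data$temp_c <- s$data$temp_c + noise  # same noise realization
      classify_visual(s)$category
    }, character(1))
    seen_ov <- FALSE
    for (c in cats) {
      if (c == "ovulatory") seen_ov <- TRUE
      if (seen_ov) expect_false(c == "anovulatory")
    }
  }
})

test_that("the mean temperature method agrees with visual calls on archetypes", {
  ov <- classify_mtm(clean_cycle(shift = 0.4))
  expect_equal(ov$category, "ovulatory")
  expect_equal(ov$category, classify_visual(clean_cycle(shift = 0.4))$category)

  flat <- classify_mtm(clean_cycle(ovulatory = FALSE))
  expect_equal(flat$category, "anovulatory")
  expect_equal(classify_mtm(cycle_series("PX", rep(36.3, 4)))$category,
               "inconclusive")
})

test_that("fever days are excluded from criterion computations", {
  p <- cycle_params(cycle_length = 28, luteal_length = 14, daily_noise_sd = 0,
                    missing_prob = 0, fever_days = c(10, 11), fever_delta = 0.8,
                    shift_magnitude = 0.4)
  s <- generate_cycle(p, seed = 1)
  # the fever spike sits just before the window; were it included, the
  # six-day reference maximum would swallow the true shift
  expect_equal(classify_visual(s)$category, "ovulatory")
  expect_equal(classify_visual(s)$shift_day, 15)
})

test_that("majority adjudication follows the two-then-three rater protocol", {
  expect_equal(adjudicate_majority(c("ovulatory", "ovulatory"))$category,
               "ovulatory")
  esc <- adjudicate_majority(c("ovulatory", "anovulatory"))
  expect_true(esc$escalate)
  expect_true(is.na(esc$category))
  expect_equal(
    adjudicate_majority(c("ovulatory", "anovulatory", "ovulatory"))$category,
    "ovulatory")
  expect_equal(
    adjudicate_majority(c("ovulatory", "anovulatory", "inconclusive"))$category,
    "inconclusive")
  expect_error(adjudicate_majority(list()), "no calls")
  calls <- list(classify_visual(clean_cycle()), classify_visual(clean_cycle()))
  expect_equal(adjudicate_majority(calls)$category, "ovulatory")
})
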