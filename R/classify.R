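# Ovulation classification from a daily BBT series.
#
# Two independent readings of the same chart:
#  * visual criteria: a >0.2 C three-day shift over the six preceding
#    temperatures near the expected ovulation day, sustained >=11 days with a
#    fast rise and no deep luteal falls; a pre-shift nadir is supportive only;
#  * quantitative mean temperature method (MTM): days are compared against the
#    cycle-wide mean temperature.
#
# Strict ">" comparisons on measured temperatures use a 1e-6 C guard so that
# a shift of exactly the threshold never passes through floating-point noise.

EPS <- 1e-6

criterion_outcome <- function(name, passed, detail = "") {
  list(name = name, passed = passed, detail = detail)
}

#' An ovulation call for one cycle
#'
#' @param category One of `"ovulatory"`, `"anovulatory"`, `"inconclusive"`.
#' @param shift_day First day of the sustained temperature shift, or `NA`.
#' @param nadir_day Day of the supportive pre-shift nadir, or `NA`.
#' @param luteal_length_days Days from `shift_day` through cycle end, or `NA`.
#' @param rise_days Days between the last pre-shift temperature and the
#'   shifted plateau, or `NA`.
#' @param reasons List of criterion outcomes (name, passed, detail).
#' @param method Label of the classifying method (e.g. `"visual"`, `"mtm"`).
#' @return An object of class `ovulation_call`.
#' @export
ovulation_call <- function(category,
                           shift_day = NA_integer_,
                           nadir_day = NA_integer_,
                           luteal_length_days = NA_integer_,
                           rise_days = NA_integer_,
                           reasons = list(),
                           method = NA_character_) {
  category <- match.arg(category, c("ovulatory", "anovulatory", "inconclusive"))
  if (category == "ovulatory" && is.na(shift_day)) {
    stop("an ovulatory call requires a shift day", call. = FALSE)
  }
  structure(
    list(
      category = category,
      shift_day = as.integer(shift_day),
      nadir_day = as.integer(nadir_day),
      luteal_length_days = as.integer(luteal_length_days),
      rise_days = as.integer(rise_days),
      reasons = reasons,
      method = method
    ),
    class = "ovulation_call"
  )
}

#' @export
print.ovulation_call <- function(x, ...) {
  cat(sprintf("<ovulation_call> %s (%s)", x$category,
              ifelse(is.na(x$method), "?", x$method)))
  if (!is.na(x$shift_day)) {
    cat(sprintf(", shift day %d, luteal %d d", x$shift_day, x$luteal_length_days))
  }
  if (!is.na(x$nadir_day)) cat(sprintf(", nadir day %d", x$nadir_day))
  cat("\n")
  for (r in x$reasons) {
    cat(sprintf("  %-13s %s  %s\n", r$name,
                if (is.na(r$passed)) "undetermined" else if (r$passed) "pass" else "fail",
                r$detail))
  }
  invisible(x)
}

#' Expected day of ovulation from cycle length
#'
#' The expected ovulation day is two weeks before the following menses:
#' `cycle_length - 13`, the day such that exactly 14 days remain through the
#' last cycle day. It anchors the search window for the biphasic shift and is
#' only defined when the following menses was observed.
#'
#' @param series A [cycle_series()].
#' @return The cycle day, or `NA` when the next menses is unknown (the
#'   biphasic window cannot be anchored).
#' @export
expected_ovulation_day <- function(series) {
  stopifnot(inherits(series, "cycle_series"))
  if (!series$next_menses_known) return(NA_integer_)
  as.integer(series$cycle_length - 13L)
}

#' Detect a three-day sustained biphasic shift
#'
#' Scans candidate days `d` inside the window around the expected ovulation
#' day and returns the first for which the temperatures on `d`, `d+1`, `d+2`
#' each exceed the mean of the six preceding observed temperatures by more
#' than `threshold` (a three-over-six reading of a biphasic chart; the
#' six-day mean serves as the coverline, making the reference robust to a
#' single noisy spike among the six). Fever-flagged days are excluded
#' throughout. A candidate with fewer
#' than six observed preceding days, or with a missing day in its three-day
#' plateau, cannot be evaluated; if no candidate can be evaluated the result
#' is undetermined rather than negative.
#'
#' @param series A [cycle_series()].
#' @param window_center Centre of the search window; defaults to
#'   [expected_ovulation_day()].
#' @param window_halfwidth Half-width of the search window in days.
#' @param threshold Shift size that must be exceeded, degrees C.
#' @return A list with `shift_day` (integer or `NA`) and `undetermined`
#'   (logical).
#' @export
detect_biphasic_shift <- function(series,
                                  window_center = expected_ovulation_day(series),
                                  window_halfwidth = 4L,
                                  threshold = 0.2) {
  stopifnot(inherits(series, "cycle_series"))
  t <- usable_temps(series)
  n <- series$cycle_length
  if (is.na(window_center)) {
    return(list(shift_day = NA_integer_, undetermined = TRUE))
  }
  lo <- max(1L, window_center - window_halfwidth)
  hi <- min(n - 2L, window_center + window_halfwidth)
  if (hi < lo) return(list(shift_day = NA_integer_, undetermined = TRUE))
  any_evaluable <- FALSE
  for (d in lo:hi) {
    prev <- which(!is.na(t[seq_len(d - 1L)]))
    plateau <- t[d:(d + 2L)]
    if (length(prev) < 6L || anyNA(plateau)) next
    any_evaluable <- TRUE
    ref <- mean(t[utils::tail(prev, 6L)])
    if (all(plateau - ref > threshold + EPS)) {
      return(list(shift_day = as.integer(d), undetermined = FALSE))
    }
  }
  list(shift_day = NA_integer_, undetermined = !any_evaluable)
}

#' Check adequacy of a detected thermal shift
#'
#' Given a shift day, verifies the three adequacy sub-criteria: the elevated
#' run from the shift day through the end of the cycle spans at least 11
#' days; the rise from the last observed pre-shift day is fast (the plateau
#' begins within 2 days of it); and no luteal temperature falls back to or
#' below the pre-shift reference level (the maximum of the six preceding
#' observed temperatures). More than two missing luteal temperatures leave
#' the criterion undetermined.
#'
#' @param series A [cycle_series()].
#' @param shift_day Cycle day the shift begins (from
#'   [detect_biphasic_shift()]).
#' @return A list with `passed` (`TRUE`/`FALSE`/`NA` for undetermined),
#'   `detail`, `luteal_length` and `rise_days`.
#' @export
check_thermal_shift_adequacy <- function(series, shift_day) {
  stopifnot(inherits(series, "cycle_series"), !is.na(shift_day))
  t <- usable_temps(series)
  n <- series$cycle_length
  prev <- which(!is.na(t[seq_len(shift_day - 1L)]))
  if (length(prev) < 6L) {
    return(list(passed = NA, detail = "fewer than 6 observed pre-shift days",
                luteal_length = NA_integer_, rise_days = NA_integer_))
  }
  ref <- max(t[utils::tail(prev, 6L)])
  luteal <- t[shift_day:n]
  luteal_length <- n - shift_day + 1L
  rise_days <- shift_day - max(prev)
  if (sum(is.na(luteal)) > 2L) {
    return(list(passed = NA, detail = "more than 2 luteal temperatures missing",
                luteal_length = luteal_length, rise_days = rise_days))
  }
  fails <- character(0)
  if (luteal_length < 11L) {
    fails <- c(fails, sprintf("sustained only %d days (<11)", luteal_length))
  }
  if (rise_days > 2L) {
    fails <- c(fails, sprintf("slow rise (%d days)", rise_days))
  }
  if (any(luteal - ref <= EPS, na.rm = TRUE)) {
    fails <- c(fails, "deep fall in luteal phase")
  }
  list(
    passed = length(fails) == 0L,
    detail = if (length(fails)) paste(fails, collapse = "; ") else "adequate",
    luteal_length = luteal_length,
    rise_days = as.integer(rise_days)
  )
}

#' Locate the supportive pre-shift nadir
#'
#' The nadir is the coolest of the three days immediately preceding the shift
#' day, provided it lies strictly below the mean of the six observed days
#' preceding the shift. Its presence supports an ovulatory reading but its
#' absence never forces an anovulatory one.
#'
#' @param series A [cycle_series()].
#' @param shift_day Cycle day the shift begins.
#' @return The nadir cycle day, or `NA`.
#' @export
detect_nadir <- function(series, shift_day) {
  stopifnot(inherits(series, "cycle_series"), !is.na(shift_day))
  t <- usable_temps(series)
  window <- seq(max(1L, shift_day - 3L), shift_day - 1L)
  if (!length(window) || all(is.na(t[window]))) return(NA_integer_)
  prev <- which(!is.na(t[seq_len(shift_day - 1L)]))
  if (length(prev) < 6L) return(NA_integer_)
  ref_mean <- mean(t[utils::tail(prev, 6L)])
  cand <- window[which.min(t[window])]
  if (t[cand] < ref_mean - EPS) as.integer(cand) else NA_integer_
}

completeness_check <- function(series, min_observed_days, max_missing_fraction) {
  n_obs <- sum(!is.na(series$data$temp_c))
  frac_missing <- 1 - n_obs / series$cycle_length
  ok <- n_obs >= min_observed_days && frac_missing <= max_missing_fraction
  criterion_outcome(
    "completeness", ok,
    sprintf("%d/%d days observed", n_obs, series$cycle_length)
  )
}

#' Classify a cycle by visual chart criteria
#'
#' Applies the visual ovulation-evidence criteria programmatically: the cycle
#' is ovulatory if and only if both the biphasic shift and the thermal-shift
#' adequacy criteria pass; anovulatory when the chart is adequately complete
#' and either necessary criterion fails decisively; inconclusive when the
#' data are too incomplete to judge (fewer than `min_observed_days` observed
#' temperatures or more than `max_missing_fraction` of days missing, the next
#' menses unobserved, or an undetermined criterion). The nadir is recorded as
#' supportive evidence only.
#'
#' @param series A [cycle_series()].
#' @param window_halfwidth Search-window half-width around the expected
#'   ovulation day, days.
#' @param threshold Biphasic shift threshold, degrees C.
#' @param min_observed_days Minimum observed temperatures for a decisive call.
#' @param max_missing_fraction Maximum tolerated fraction of missing days.
#' @return An [ovulation_call()] with `method = "visual"`.
#' @export
classify_visual <- function(series,
                            window_halfwidth = 4L,
                            threshold = 0.2,
                            min_observed_days = 17L,
                            max_missing_fraction = 0.2) {
  stopifnot(inherits(series, "cycle_series"))
  comp <- completeness_check(series, min_observed_days, max_missing_fraction)
  if (!comp$passed) {
    return(ovulation_call("inconclusive", reasons = list(comp), method = "visual"))
  }
  center <- expected_ovulation_day(series)
  if (is.na(center)) {
    return(ovulation_call(
      "inconclusive",
      reasons = list(comp, criterion_outcome("anchor", NA,
        "next menses unobserved; expected ovulation day unknown")),
      method = "visual"
    ))
  }
  bip <- detect_biphasic_shift(series, center, window_halfwidth, threshold)
  if (bip$undetermined) {
    return(ovulation_call(
      "inconclusive",
      reasons = list(comp, criterion_outcome("biphasic", NA,
        "no candidate day evaluable around expected ovulation")),
      method = "visual"
    ))
  }
  if (is.na(bip$shift_day)) {
    return(ovulation_call(
      "anovulatory",
      reasons = list(comp, criterion_outcome("biphasic", FALSE,
        "no 3-day sustained shift >0.2C over 6 preceding temperatures")),
      method = "visual"
    ))
  }
  bip_out <- criterion_outcome("biphasic", TRUE,
                               sprintf("shift begins day %d", bip$shift_day))
  adeq <- check_thermal_shift_adequacy(series, bip$shift_day)
  adeq_out <- criterion_outcome("thermal_shift", adeq$passed, adeq$detail)
  if (is.na(adeq$passed)) {
    return(ovulation_call(
      "inconclusive", shift_day = bip$shift_day,
      luteal_length_days = adeq$luteal_length, rise_days = adeq$rise_days,
      reasons = list(comp, bip_out, adeq_out), method = "visual"
    ))
  }
  nadir <- detect_nadir(series, bip$shift_day)
  nadir_out <- criterion_outcome("nadir", !is.na(nadir),
    if (is.na(nadir)) "no supportive nadir" else sprintf("nadir day %d", nadir))
  if (!adeq$passed) {
    return(ovulation_call(
      "anovulatory", nadir_day = nadir,
      luteal_length_days = adeq$luteal_length, rise_days = adeq$rise_days,
      reasons = list(comp, bip_out, adeq_out, nadir_out), method = "visual"
    ))
  }
  ovulation_call(
    "ovulatory",
    shift_day = bip$shift_day, nadir_day = nadir,
    luteal_length_days = adeq$luteal_length, rise_days = adeq$rise_days,
    reasons = list(comp, bip_out, adeq_out, nadir_out), method = "visual"
  )
}

#' Classify a cycle by the quantitative mean temperature method
#'
#' Compares daily temperatures against the cycle-wide mean of all observed,
#' non-fever temperatures. The cycle is ovulatory if some day `d` starts a
#' run in which the temperatures on `d`, `d+1`, `d+2` all exceed the cycle
#' mean, at least 11 days from `d` through the cycle end exceed the mean, and
#' no day in the run falls more than `tolerance` below it; anovulatory
#' otherwise; inconclusive when the completeness rules of
#' [classify_visual()] fail. The tolerance absorbs single-day noise dips in
#' an otherwise elevated luteal phase.
#'
#' @param series A [cycle_series()].
#' @param tolerance Permitted dip below the cycle mean inside the elevated
#'   run, degrees C.
#' @param min_run Minimum number of above-mean days in the run.
#' @param min_observed_days,max_missing_fraction Completeness rules, as in
#'   [classify_visual()].
#' @return An [ovulation_call()] with `method = "mtm"`.
#' @export
classify_mtm <- function(series,
                         tolerance = 0.1,
                         min_run = 11L,
                         min_observed_days = 17L,
                         max_missing_fraction = 0.2) {
  stopifnot(inherits(series, "cycle_series"))
  comp <- completeness_check(series, min_observed_days, max_missing_fraction)
  if (!comp$passed) {
    return(ovulation_call("inconclusive", reasons = list(comp), method = "mtm"))
  }
  t <- usable_temps(series)
  n <- series$cycle_length
  m <- mean(t, na.rm = TRUE)
  mean_out <- criterion_outcome("cycle_mean", TRUE, sprintf("mean %.3f C", m))
  for (d in seq_len(n - 2L)) {
    plateau <- t[d:(d + 2L)]
    if (anyNA(plateau) || !all(plateau - m > EPS)) next
    run <- t[d:n]
    n_above <- sum(run - m > EPS, na.rm = TRUE)
    deep <- any(m - run > tolerance + EPS, na.rm = TRUE)
    if (n_above >= min_run && !deep) {
      return(ovulation_call(
        "ovulatory",
        shift_day = as.integer(d),
        luteal_length_days = n - d + 1L,
        reasons = list(comp, mean_out, criterion_outcome("mtm_run", TRUE,
          sprintf("%d days above cycle mean from day %d", n_above, d))),
        method = "mtm"
      ))
    }
  }
  ovulation_call(
    "anovulatory",
    reasons = list(comp, mean_out, criterion_outcome("mtm_run", FALSE,
      "no 3-day start with >=11 days sustained above the cycle mean")),
    method = "mtm"
  )
}

#' Adjudicate calls from two or three raters
#'
#' With two concordant calls the shared category stands; two discordant calls
#' escalate to request a third rater; with three calls the modal category is
#' accepted, a three-way tie resolving to inconclusive.
#'
#' @param calls A list of [ovulation_call()] objects (or a character vector
#'   of categories) from 2 or 3 raters.
#' @return A list with `category` (`NA` while escalation is pending),
#'   `escalate` and `n_raters`.
#' @export
adjudicate_majority <- function(calls) {
  if (length(calls) == 0) stop("no calls to adjudicate", call. = FALSE)
  cats <- unname(vapply(calls, function(x) {
    if (inherits(x, "ovulation_call")) x$category else as.character(x)
  }, character(1)))
  if (!all(cats %in% c("ovulatory", "anovulatory", "inconclusive"))) {
    stop("unknown call category", call. = FALSE)
  }
  if (!length(cats) %in% c(2L, 3L)) {
    stop("adjudication takes 2 or 3 calls", call. = FALSE)
  }
  if (length(cats) == 2L) {
    if (cats[1] == cats[2]) {
      return(list(category = cats[1], escalate = FALSE, n_raters = 2L))
    }
    return(list(category = NA_character_, escalate = TRUE, n_raters = 2L))
  }
  tab <- table(cats)
  if (max(tab) == 1L) {
    return(list(category = "inconclusive", escalate = FALSE, n_raters = 3L))
  }
  list(category = names(tab)[which.max(tab)], escalate = FALSE, n_raters = 3L)
}
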