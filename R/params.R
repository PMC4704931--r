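#' Parameters for one simulated menstrual cycle
#'
#' Bundles everything needed to simulate one participant's daily oral BBT
#' series: the cycle geometry (length, luteal length), the thermal signal
#' (follicular baseline, post-ovulatory shift, pre-shift nadir), and the
#' nuisance processes (measurement noise, missing days, fever days).
#'
#' In an ovulatory cycle the ovulation day is `cycle_length - luteal_length`:
#' that day carries the nadir (a dip of `nadir_depth` below baseline) and every
#' later day sits `shift_magnitude` above baseline through the end of the
#' cycle, so the luteal phase spans `luteal_length` days.
#'
#' @param cycle_length Cycle length in days (first day of menses through the
#'   day before the next menses).
#' @param ovulatory Logical; if `FALSE` the series is flat at
#'   `follicular_mean` (an anovulatory cycle, e.g. an OCP-user control).
#' @param luteal_length Days of sustained post-ovulatory elevation (ovulatory
#'   cycles only). Must be < `cycle_length`.
#' @param follicular_mean Follicular-phase baseline temperature, degrees C.
#' @param shift_magnitude Size of the post-ovulatory upward shift, degrees C.
#'   Physiological range is 0.2-0.5.
#' @param nadir_depth Depth of the single-day dip immediately before the
#'   shift, degrees C (0 suppresses the nadir).
#' @param daily_noise_sd SD of iid Gaussian measurement noise per day,
#'   degrees C.
#' @param missing_prob Per-day probability that the oral temperature is
#'   missing (participant forgot).
#' @param fever_days Integer vector of cycle days with intercurrent fever.
#' @param fever_delta Temperature elevation on fever days, degrees C.
#' @return An object of class `cycle_params` (a validated list).
#' @seealso [generate_cycle()]
#' @export
cycle_params <- function(cycle_length = 28L,
                         ovulatory = TRUE,
                         luteal_length = 14L,
                         follicular_mean = 36.29,
                         shift_magnitude = 0.35,
                         nadir_depth = 0.15,
                         daily_noise_sd = 0.2,
                         missing_prob = 0.1,
                         fever_days = integer(0),
                         fever_delta = 0.8) {
  stopifnot(is.numeric(cycle_length), length(cycle_length) == 1, cycle_length >= 1)
  cycle_length <- as.integer(cycle_length)
  if (!is.logical(ovulatory) || length(ovulatory) != 1 || is.na(ovulatory)) {
    stop("`ovulatory` must be TRUE or FALSE", call. = FALSE)
  }
  if (daily_noise_sd < 0) stop("`daily_noise_sd` must be >= 0", call. = FALSE)
  if (missing_prob < 0 || missing_prob >= 1) {
    stop("`missing_prob` must be in [0, 1)", call. = FALSE)
  }
  if (ovulatory) {
    luteal_length <- as.integer(luteal_length)
    if (luteal_length >= cycle_length) {
      stop("`luteal_length` must be smaller than `cycle_length`", call. = FALSE)
    }
    if (luteal_length < 1) stop("`luteal_length` must be >= 1", call. = FALSE)
    if (shift_magnitude <= 0) stop("`shift_magnitude` must be > 0", call. = FALSE)
    if (nadir_depth < 0) stop("`nadir_depth` must be >= 0", call. = FALSE)
  }
  fever_days <- as.integer(fever_days)
  if (any(fever_days < 1 | fever_days > cycle_length)) {
    stop("`fever_days` must lie within the cycle", call. = FALSE)
  }
  structure(
    list(
      cycle_length = cycle_length,
      ovulatory = ovulatory,
      ovulation_day = if (ovulatory) cycle_length - as.integer(luteal_length) else NA_integer_,
      luteal_length = if (ovulatory) as.integer(luteal_length) else NA_integer_,
      follicular_mean = follicular_mean,
      shift_magnitude = if (ovulatory) shift_magnitude else 0,
      nadir_depth = if (ovulatory) nadir_depth else 0,
      daily_noise_sd = daily_noise_sd,
      missing_prob = missing_prob,
      fever_days = fever_days,
      fever_delta = fever_delta
    ),
    class = "cycle_params"
  )
}

#' Measurement model for the armband skin-temperature device
#'
#' Describes how the armband's overnight skin-temperature stream relates to
#' the same day's true basal temperature. The post-stabilization stream level
#' for a night with true temperature `T` is
#'
#'   `level = T + bias_at_reference - proportional_bias_slope * (T - reference_temp)`
#'
#' so `bias_at_reference` is the (negative) armband-minus-oral offset at the
#' reference temperature and `proportional_bias_slope` is the change in the
#' oral-minus-armband difference per degree of true temperature: a negative
#' slope makes the difference larger at lower temperatures, the pattern a
#' downward-sloping Bland-Altman cloud displays.
#'
#' @param reference_temp Reference true temperature, degrees C.
#' @param bias_at_reference Armband minus oral at the reference, degrees C
#'   (negative: skin reads cooler than core).
#' @param proportional_bias_slope Change in the oral-minus-armband difference
#'   per degree C of true temperature (unitless; negative default).
#' @param stream_noise_sd SD of minute-to-minute sensor noise, degrees C.
#' @param night_effect_sd SD of the shared night-level deviation of the
#'   stream level, degrees C: room temperature, bedding and wear position vary
#'   night to night and move every minute of that night together. This, not
#'   the minute noise, is what makes armband daily means far more dispersed
#'   than oral readings.
#' @param stabilization_minutes Minutes the sensor needs after going on-body
#'   before it reads the stable level; readings ramp up linearly from 2
#'   degrees C below level during this period.
#' @param clip_low,clip_high Recording limits of the device, degrees C.
#' @return An object of class `device_model`.
#' @seealso [generate_overnight_stream()]
#' @export
device_model <- function(reference_temp = 36.4,
                         bias_at_reference = -1.8,
                         proportional_bias_slope = -0.15,
                         stream_noise_sd = 0.15,
                         night_effect_sd = 1.1,
                         stabilization_minutes = 30L,
                         clip_low = 29.7,
                         clip_high = 36.7) {
  if (clip_low >= clip_high) stop("`clip_low` must be < `clip_high`", call. = FALSE)
  if (stream_noise_sd < 0 || night_effect_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  stabilization_minutes <- as.integer(stabilization_minutes)
  if (stabilization_minutes < 0) {
    stop("`stabilization_minutes` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      reference_temp = reference_temp,
      bias_at_reference = bias_at_reference,
      proportional_bias_slope = proportional_bias_slope,
      stream_noise_sd = stream_noise_sd,
      night_effect_sd = night_effect_sd,
      stabilization_minutes = stabilization_minutes,
      clip_low = clip_low,
      clip_high = clip_high
    ),
    class = "device_model"
  )
}

#' Configuration for a simulated study cohort
#'
#' Defaults emulate the comparison study's analyzable sample: 15 participants,
#' of whom a fifth are OCP-user controls with flat (anovulatory) cycles, the
#' rest mostly ovulatory; each participant logs one full menstrual cycle with
#' an oral thermometer and wears the armband overnight.
#'
#' Per-participant cycle parameters are drawn from `params_range`:
#' cycle length uniform on `cycle_length` (integer range), luteal length
#' uniform on `luteal_length`, shift magnitude uniform on `shift_magnitude`,
#' nadir depth uniform on `nadir_depth`, follicular baseline Gaussian with SD
#' `follicular_sd` around `follicular_mean`. A per-participant armband
#' placement offset (SD `placement_sd`) is added to all of that participant's
#' stream levels. The default follicular baseline is set so the expected
#' cycle-wide oral mean is 36.4 degrees C under the default mix of ovulatory
#' and flat cycles.
#'
#' @param n_participants Number of participants.
#' @param fraction_ovulatory Probability a non-control participant has an
#'   ovulatory cycle.
#' @param fraction_control Probability a participant is an OCP-user control
#'   (flat cycle by construction).
#' @param params_range Named list of ranges/values overriding the defaults
#'   described above. Recognised names: `cycle_length`, `luteal_length`,
#'   `shift_magnitude`, `nadir_depth`, `follicular_mean`, `follicular_sd`,
#'   `daily_noise_sd`, `missing_prob`, `fever_prob`, `fever_delta`,
#'   `placement_sd`.
#' @param device A [device_model()].
#' @param seed Integer seed; every random draw in [generate_cohort()] derives
#'   from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 15L,
                          fraction_ovulatory = 0.8,
                          fraction_control = 0.2,
                          params_range = list(),
                          device = device_model(),
                          seed = 1L) {
  n_participants <- as.integer(n_participants)
  if (n_participants < 1) stop("`n_participants` must be >= 1", call. = FALSE)
  for (p in c(fraction_ovulatory, fraction_control)) {
    if (p < 0 || p > 1) stop("fractions must be probabilities in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(device, "device_model"))
  defaults <- list(
    cycle_length = c(26L, 32L),
    luteal_length = c(12L, 16L),
    shift_magnitude = c(0.2, 0.5),
    nadir_depth = c(0.05, 0.25),
    follicular_mean = 36.29,
    follicular_sd = 0.12,
    daily_noise_sd = 0.2,
    missing_prob = 0.1,
    fever_prob = 0.15,
    fever_delta = 0.8,
    placement_sd = 0.2
  )
  unknown <- setdiff(names(params_range), names(defaults))
  if (length(unknown)) {
    stop("unknown `params_range` entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(params_range)] <- params_range
  structure(
    list(
      n_participants = n_participants,
      fraction_ovulatory = fraction_ovulatory,
      fraction_control = fraction_control,
      params_range = defaults,
      device = device,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}
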