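#' Simulate one cycle's daily oral BBT series
#'
#' Constructs the day-by-day true temperature profile implied by
#' [cycle_params()] and overlays measurement noise, missing days and fever
#' days. In an ovulatory cycle the profile is a follicular plateau, a one-day
#' nadir on the ovulation day, then a step of `shift_magnitude` sustained
#' through the last cycle day; an anovulatory cycle is flat. Missing days are
#' recorded as `NA`, never imputed; fever days are elevated by `fever_delta`
#' and flagged as illness.
#'
#' @param params A [cycle_params()] object.
#' @param seed Optional integer seed; leave `NULL` to draw from the current
#'   RNG stream (as [generate_cohort()] does).
#' @param participant_id Identifier stored on the series.
#' @param start_date Calendar date of cycle day 1.
#' @return A [cycle_series()] whose `truth` field holds the ground truth:
#'   `ovulatory`, `ovulation_day` and the noise-free `true_temp` profile.
#' @examples
#' p <- cycle_params(cycle_length = 28, luteal_length = 14,
#'                   daily_noise_sd = 0, missing_prob = 0)
#' s <- generate_cycle(p, seed = 1)
#' s$truth$ovulation_day  # 14
#' @export
generate_cycle <- function(params, seed = NULL, participant_id = "P01",
                           start_date = as.Date("2015-06-01")) {
  stopifnot(inherits(params, "cycle_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$cycle_length
  level <- rep(params$follicular_mean, n)
  if (params$ovulatory) {
    od <- params$ovulation_day
    level[od] <- params$follicular_mean - params$nadir_depth
    level[(od + 1):n] <- params$follicular_mean + params$shift_magnitude
  }
  illness <- rep(FALSE, n)
  if (length(params$fever_days)) {
    level[params$fever_days] <- level[params$fever_days] + params$fever_delta
    illness[params$fever_days] <- TRUE
  }
  obs <- level + stats::rnorm(n, 0, params$daily_noise_sd)
  obs[stats::runif(n) < params$missing_prob] <- NA_real_
  cycle_series(
    participant_id = participant_id,
    temp_c = obs,
    device = "oral",
    start_date = start_date,
    illness = illness,
    next_menses_known = TRUE,
    truth = list(
      ovulatory = params$ovulatory,
      ovulation_day = params$ovulation_day,
      true_temp = level
    )
  )
}

#' Simulate one overnight armband skin-temperature stream
#'
#' Produces a minute-resolution stream for one night of a cycle. The
#' post-stabilization level is the device-model affine transform of that
#' day's true temperature (see [device_model()]) plus a night-level
#' environmental deviation and a per-participant placement offset. The first
#' `stabilization_minutes` ramp up linearly from 2 degrees C below the level
#' (the sensor warming to skin temperature); minute noise is added and values
#' are clipped to the device recording limits. The on-body flag is `TRUE`
#' during wear and `FALSE` for a short tail after the participant removes the
#' band on waking. Wake time is the nominal wake hour jittered uniformly
#' (irregular wakening).
#'
#' @param cycle A [generate_cycle()] result (its `truth$true_temp` supplies
#'   the night's underlying temperature).
#' @param night_index Cycle day of the night (the night following that day's
#'   morning reading).
#' @param device A [device_model()].
#' @param seed Optional integer seed.
#' @param worn If `FALSE`, the participant forgot the band: the stream is
#'   off-body throughout and carries no basal information.
#' @param window_minutes Length of the overnight wear window, minutes.
#' @param nominal_wake_hour Clock hour of the average wake time.
#' @param wake_jitter_minutes Half-width of the uniform wake-time jitter.
#' @param night_effect Night-level deviation of the stream level; drawn
#'   `N(0, night_effect_sd)` when `NULL`.
#' @param placement Per-participant placement offset, degrees C.
#' @param post_wake_minutes Off-body minutes recorded after removal.
#' @return A [minute_stream()].
#' @export
generate_overnight_stream <- function(cycle, night_index, device,
                                      seed = NULL,
                                      worn = TRUE,
                                      window_minutes = 480L,
                                      nominal_wake_hour = 7L,
                                      wake_jitter_minutes = 60L,
                                      night_effect = NULL,
                                      placement = 0,
                                      post_wake_minutes = 10L) {
  stopifnot(inherits(cycle, "cycle_series"), inherits(device, "device_model"))
  if (night_index < 1 || night_index > cycle$cycle_length) {
    stop("`night_index` outside the cycle", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  true_temp <- if (!is.null(cycle$truth)) {
    cycle$truth$true_temp[night_index]
  } else {
    cycle$data$temp_c[night_index]
  }
  if (is.na(true_temp)) {
    stop("no underlying temperature available for this night", call. = FALSE)
  }
  if (is.null(night_effect)) {
    night_effect <- stats::rnorm(1, 0, device$night_effect_sd)
  }
  night_date <- cycle$data$date[night_index]
  jitter <- round(stats::runif(1, -wake_jitter_minutes, wake_jitter_minutes))
  wake <- as.POSIXct(paste0(format(night_date + 1), " 00:00:00"), tz = "UTC") +
    nominal_wake_hour * 3600 + jitter * 60

  level <- true_temp + device$bias_at_reference -
    device$proportional_bias_slope * (true_temp - device$reference_temp) +
    night_effect + placement

  nw <- as.integer(window_minutes)
  if (worn) {
    base <- rep(level, nw)
    stab <- min(device$stabilization_minutes, nw)
    if (stab > 0) {
      i <- seq_len(stab)
      base[i] <- level - 2 * (stab - i) / stab
    }
    npost <- as.integer(post_wake_minutes)
    # removed band cools toward ambient
    post <- level - seq(0.5, 3, length.out = max(npost, 1))[seq_len(npost)]
    temps <- c(base, post) + stats::rnorm(nw + npost, 0, device$stream_noise_sd)
    on_body <- c(rep(TRUE, nw), rep(FALSE, npost))
  } else {
    temps <- device$clip_low + 0.5 + stats::rnorm(nw, 0, device$stream_noise_sd)
    on_body <- rep(FALSE, nw)
  }
  temps <- pmin(pmax(temps, device$clip_low), device$clip_high)
  start <- wake - (nw + 1) * 60  # last on-body minute sits just before wake
  minute_stream(
    participant_id = cycle$participant_id,
    night_date = night_date,
    timestamp = start + 60 * seq_len(length(temps)),
    temp_c = temps,
    on_body = on_body
  )
}

#' Simulate a full study cohort with ground truth
#'
#' Draws per-participant cycle parameters from the configured ranges,
#' generates each participant's daily oral series and one overnight armband
#' stream per cycle day, and records the ground truth (ovulatory status and
#' ovulation day). Whether the band was worn on a given night is sampled
#' independently of oral missingness with the same per-day probability.
#' All randomness derives from `config$seed`, so the same configuration
#' reproduces the cohort exactly.
#'
#' @param config A [cohort_config()].
#' @param streams If `FALSE`, generate only the daily cycles and ground
#'   truth, skipping the minute streams (useful for large property checks on
#'   the ground truth alone).
#' @return An object of class `bbt_cohort`: a list with `participants` (each
#'   a list of `cycle`, `streams`, `worn`, `placement`), a `truth` tibble
#'   (`participant_id`, `ovulatory`, `ovulation_day`) and the `config`.
#' @export
generate_cohort <- function(config, streams = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  pr <- config$params_range
  participants <- vector("list", config$n_participants)
  truth_rows <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    control <- stats::runif(1) < config$fraction_control
    ovulatory <- !control && stats::runif(1) < config$fraction_ovulatory
    len <- sample(pr$cycle_length[1]:pr$cycle_length[2], 1)
    lut <- sample(pr$luteal_length[1]:pr$luteal_length[2], 1)
    fever_days <- integer(0)
    if (stats::runif(1) < pr$fever_prob) {
      onset <- sample(seq_len(len - 1L), 1)
      fever_days <- onset:min(onset + sample(0:1, 1), len)
    }
    params <- cycle_params(
      cycle_length = len,
      ovulatory = ovulatory,
      luteal_length = lut,
      follicular_mean = stats::rnorm(1, pr$follicular_mean, pr$follicular_sd),
      shift_magnitude = stats::runif(1, pr$shift_magnitude[1], pr$shift_magnitude[2]),
      nadir_depth = stats::runif(1, pr$nadir_depth[1], pr$nadir_depth[2]),
      daily_noise_sd = pr$daily_noise_sd,
      missing_prob = pr$missing_prob,
      fever_days = fever_days,
      fever_delta = pr$fever_delta
    )
    cycle <- generate_cycle(params, seed = NULL, participant_id = pid,
                            start_date = as.Date("2015-06-01") + (p - 1L) * 3L)
    placement <- stats::rnorm(1, 0, pr$placement_sd)
    worn <- stats::runif(len) >= pr$missing_prob
    night_streams <- if (streams) {
      lapply(seq_len(len), function(d) {
        generate_overnight_stream(cycle, d, config$device,
                                  worn = worn[d], placement = placement)
      })
    } else {
      list()
    }
    participants[[p]] <- list(cycle = cycle, streams = night_streams,
                              worn = worn, placement = placement,
                              control = control)
    truth_rows[[p]] <- tibble::tibble(
      participant_id = pid,
      ovulatory = ovulatory,
      ovulation_day = params$ovulation_day,
      control = control
    )
  }
  structure(
    list(
      participants = participants,
      truth = dplyr::bind_rows(truth_rows),
      config = config
    ),
    class = "bbt_cohort"
  )
}

#' @export
print.bbt_cohort <- function(x, ...) {
  cat(sprintf(
    "<bbt_cohort> %d participants (%d ovulatory, %d controls), seed %d\n",
    nrow(x$truth), sum(x$truth$ovulatory), sum(x$truth$control),
    x$config$seed
  ))
  invisible(x)
}

#' Write a simulated cohort to the project's CSV formats
#'
#' Emits `daily.csv` (oral logs), `minutes.csv` (armband streams) and
#' `truth.csv` (ground truth) under `dir`, each with a `# seed:` comment
#' header recording provenance.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bbt_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cohort$config$seed
  series <- lapply(cohort$participants, `[[`, "cycle")
  write_daily_csv(series, file.path(dir, "daily.csv"), seed = seed)
  streams <- unlist(lapply(cohort$participants, `[[`, "streams"),
                    recursive = FALSE)
  write_minute_csv(streams, file.path(dir, "minutes.csv"), seed = seed)
  truth_path <- file.path(dir, "truth.csv")
  con <- file(truth_path, "w")
  writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(cohort$truth, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(dir)
}
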