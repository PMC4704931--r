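#' One participant's daily temperature series for one menstrual cycle
#'
#' The cycle coordinate system starts at menses: cycle day 1 is the first day
#' of menstrual bleeding and the cycle runs through the day before the next
#' menses. Temperatures may be missing (`NA`); they are never imputed.
#'
#' @param participant_id Participant identifier.
#' @param temp_c Numeric vector of daily temperatures in degrees C (`NA` for
#'   missing days), one per cycle day.
#' @param device Device label: `"oral"` or one of
#'   `"armband-10"`, `"armband-30"`, `"armband-60"`, `"armband-90"`,
#'   `"armband-120"` (pre-waking interval means).
#' @param start_date Calendar date of cycle day 1.
#' @param illness Logical vector flagging fever/illness days.
#' @param irregular_wake Logical vector flagging irregular wakening times.
#' @param next_menses_known Whether the following menses was observed, i.e.
#'   whether `length(temp_c)` is the true cycle length. Needed to anchor the
#'   expected ovulation day.
#' @param truth Optional ground-truth list for simulated cycles
#'   (`ovulatory`, `ovulation_day`, `true_temp`).
#' @return An object of class `cycle_series`: a list with `participant_id`,
#'   `device`, `cycle_length`, `next_menses_known` and a `data` tibble with
#'   columns `cycle_day`, `date`, `temp_c`, `illness`, `irregular_wake`.
#' @export
cycle_series <- function(participant_id,
                         temp_c,
                         device = "oral",
                         start_date = as.Date("2015-06-01"),
                         illness = rep(FALSE, length(temp_c)),
                         irregular_wake = rep(FALSE, length(temp_c)),
                         next_menses_known = TRUE,
                         truth = NULL) {
  n <- length(temp_c)
  if (n < 1) stop("a cycle needs at least one day", call. = FALSE)
  device <- match.arg(device, c("oral", paste0("armband-", c(10, 30, 60, 90, 120))))
  stopifnot(length(illness) == n, length(irregular_wake) == n)
  ok <- is.na(temp_c) | (temp_c >= 25 & temp_c <= 43)
  if (!all(ok)) {
    stop("temperatures outside sanity bounds [25, 43] on day(s) ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      device = device,
      cycle_length = n,
      next_menses_known = isTRUE(next_menses_known),
      data = tibble::tibble(
        cycle_day = seq_len(n),
        date = start_date + seq_len(n) - 1L,
        temp_c = as.numeric(temp_c),
        illness = as.logical(illness),
        irregular_wake = as.logical(irregular_wake)
      ),
      truth = truth
    ),
    class = "cycle_series"
  )
}

#' @export
print.cycle_series <- function(x, ...) {
  cat(sprintf(
    "<cycle_series> participant %s, device %s, %d days (%d observed)\n",
    x$participant_id, x$device, x$cycle_length, sum(!is.na(x$data$temp_c))
  ))
  invisible(x)
}

# Temperatures usable for ovulation criteria: observed, fever days excluded.
usable_temps <- function(series) {
  t <- series$data$temp_c
  t[series$data$illness] <- NA_real_
  t
}

#' One night's minute-resolution skin-temperature stream
#'
#' @param participant_id Participant identifier.
#' @param night_date Calendar date of the evening the device went on (the
#'   night spans into the following morning).
#' @param timestamp POSIXct vector, strictly increasing, 1-minute resolution.
#' @param temp_c Numeric vector of skin temperatures, degrees C.
#' @param on_body Logical vector; `TRUE` while the armband is worn.
#' @param wake_time Optional explicit wake timestamp (e.g. from an external
#'   sleep-staging source); when absent, [detect_waking_time()] infers it
#'   from the on-body flag.
#' @return An object of class `minute_stream`.
#' @export
minute_stream <- function(participant_id,
                          night_date,
                          timestamp,
                          temp_c,
                          on_body,
                          wake_time = NULL) {
  n <- length(timestamp)
  stopifnot(length(temp_c) == n, length(on_body) == n)
  if (n > 1 && any(diff(as.numeric(timestamp)) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      night_date = as.Date(night_date),
      wake_time = wake_time,
      data = tibble::tibble(
        timestamp = timestamp,
        temp_c = as.numeric(temp_c),
        on_body = as.logical(on_body)
      )
    ),
    class = "minute_stream"
  )
}

#' @export
print.minute_stream <- function(x, ...) {
  cat(sprintf(
    "<minute_stream> participant %s, night of %s, %d minutes (%d on-body)\n",
    x$participant_id, format(x$night_date), nrow(x$data), sum(x$data$on_body)
  ))
  invisible(x)
}
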