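# CSV formats
#
# daily-log CSV:     participant_id,date,cycle_day,device,temp_c,illness,irregular_wake
# minute-stream CSV: participant_id,timestamp,temp_c,on_body
#
# Dialect is strict: comma separators, period decimal, ISO-8601 dates
# (YYYY-MM-DD) and timestamps (YYYY-MM-DDTHH:MM:SS), mandatory header, no
# quoting. Lines starting with '#' before the header are provenance comments
# (e.g. the generator seed) and are skipped.

DEVICE_LABELS <- c("oral", paste0("armband-", c(10, 30, 60, 90, 120)))

read_csv_strict <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  n_comment <- 0L
  while (n_comment < length(lines) && startsWith(lines[n_comment + 1L], "#")) {
    n_comment <- n_comment + 1L
  }
  body <- lines[(n_comment + 1L):length(lines)]
  if (!length(body) || !nzchar(body[1])) stop("missing header row in ", path, call. = FALSE)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (!identical(header, columns)) {
    stop("header mismatch in ", path, ": expected '",
         paste(columns, collapse = ","), "', found '", body[1], "'",
         call. = FALSE)
  }
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  fields <- strsplit(rows, ",", fixed = TRUE)
  nf <- lengths(fields)
  # trailing empty field is dropped by strsplit; restore it
  short <- nf == length(columns) - 1L & endsWith(rows, ",")
  fields[short] <- lapply(fields[short], function(f) c(f, ""))
  nf[short] <- length(columns)
  bad <- which(nf != length(columns))
  if (length(bad)) {
    stop("malformed row (expected ", length(columns), " fields) at line ",
         bad[1] + n_comment + 1L, " of ", path, ": '", rows[bad[1]], "'",
         call. = FALSE)
  }
  out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(out) <- columns
  attr(out, "line_numbers") <- seq_along(rows) + n_comment + 1L
  out
}

parse_numeric_field <- function(x, lines, path, field, lo = -Inf, hi = Inf) {
  out <- rep(NA_real_, length(x))
  present <- nzchar(x) & x != "NA"
  ok <- grepl("^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", x[present])
  if (!all(ok)) {
    i <- which(present)[which(!ok)[1]]
    stop("cannot parse ", field, " '", x[i], "' at line ", lines[i], " of ",
         path, " (period-decimal numbers required)", call. = FALSE)
  }
  out[present] <- as.numeric(x[present])
  viol <- present & (out < lo | out > hi)
  if (any(viol)) {
    i <- which(viol)[1]
    stop(field, " ", x[i], " outside [", lo, ", ", hi, "] at line ",
         lines[i], " of ", path, call. = FALSE)
  }
  out
}

parse_logical_field <- function(x, lines, path, field) {
  ok <- x %in% c("TRUE", "FALSE")
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop("cannot parse ", field, " '", x[i], "' at line ", lines[i], " of ",
         path, " (TRUE/FALSE required)", call. = FALSE)
  }
  x == "TRUE"
}

#' Read a daily temperature log CSV
#'
#' Parses the daily-log format (see the package README for the schema),
#' validates every row, and groups rows into one [cycle_series()] per
#' participant-device pair. Malformed rows are rejected with their file line
#' number; missing temperatures (empty field) are preserved as `NA`.
#'
#' @param path Path to the CSV file.
#' @return A named list of [cycle_series()], keyed `participant:device`.
#' @export
read_daily_csv <- function(path) {
  cols <- c("participant_id", "date", "cycle_day", "device", "temp_c",
            "illness", "irregular_wake")
  raw <- read_csv_strict(path, cols)
  lines <- attr(raw, "line_numbers")
  bad_date <- !grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", raw$date)
  if (any(bad_date)) {
    i <- which(bad_date)[1]
    stop("cannot parse date '", raw$date[i], "' at line ", lines[i], " of ",
         path, " (ISO-8601 required)", call. = FALSE)
  }
  bad_dev <- !(raw$device %in% DEVICE_LABELS)
  if (any(bad_dev)) {
    i <- which(bad_dev)[1]
    stop("unknown device label '", raw$device[i], "' at line ", lines[i],
         " of ", path, call. = FALSE)
  }
  day <- parse_numeric_field(raw$cycle_day, lines, path, "cycle_day", lo = 1)
  temp <- parse_numeric_field(raw$temp_c, lines, path, "temp_c", lo = 25, hi = 43)
  illness <- parse_logical_field(raw$illness, lines, path, "illness")
  irregular <- parse_logical_field(raw$irregular_wake, lines, path, "irregular_wake")

  key <- paste(raw$participant_id, raw$device, sep = ":")
  dup <- duplicated(paste(key, day))
  if (any(dup)) {
    i <- which(dup)[1]
    stop("duplicate (participant, cycle_day, device) at line ", lines[i],
         " of ", path, call. = FALSE)
  }
  out <- list()
  for (k in unique(key)) {
    sel <- which(key == k)
    sel <- sel[order(day[sel])]
    days <- as.integer(day[sel])
    len <- max(days)
    temps <- rep(NA_real_, len)
    ill <- rep(FALSE, len)
    irr <- rep(FALSE, len)
    temps[days] <- temp[sel]
    ill[days] <- illness[sel]
    irr[days] <- irregular[sel]
    start <- as.Date(raw$date[sel[1]]) - (days[1] - 1L)
    out[[k]] <- cycle_series(
      participant_id = raw$participant_id[sel[1]],
      temp_c = temps,
      device = raw$device[sel[1]],
      start_date = start,
      illness = ill,
      irregular_wake = irr
    )
  }
  out
}

#' Write daily temperature logs to CSV
#'
#' @param series A [cycle_series()] or list of them.
#' @param path Output path.
#' @param seed Optional integer recorded in a `# seed:` comment line.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(series, path, seed = NULL) {
  if (inherits(series, "cycle_series")) series <- list(series)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  writeLines("participant_id,date,cycle_day,device,temp_c,illness,irregular_wake", con)
  for (s in series) {
    d <- s$data
    temp <- ifelse(is.na(d$temp_c), "", as.character(d$temp_c))
    writeLines(paste(s$participant_id, format(d$date), d$cycle_day, s$device,
                     temp, d$illness, d$irregular_wake, sep = ","), con)
  }
  invisible(path)
}

#' Read a minute-resolution skin-temperature stream CSV
#'
#' Groups rows into one [minute_stream()] per participant-night; the night is
#' the calendar date 12 hours before each timestamp, so an overnight episode
#' spanning midnight stays together.
#'
#' @param path Path to the CSV file.
#' @return A named list of [minute_stream()], keyed `participant:night`.
#' @export
read_minute_csv <- function(path) {
  cols <- c("participant_id", "timestamp", "temp_c", "on_body")
  raw <- read_csv_strict(path, cols)
  lines <- attr(raw, "line_numbers")
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) {
    i <- which(is.na(ts))[1]
    stop("cannot parse timestamp '", raw$timestamp[i], "' at line ", lines[i],
         " of ", path, call. = FALSE)
  }
  temp <- parse_numeric_field(raw$temp_c, lines, path, "temp_c")
  on_body <- parse_logical_field(raw$on_body, lines, path, "on_body")
  night <- as.Date(ts - 12 * 3600, tz = "UTC")
  key <- paste(raw$participant_id, format(night), sep = ":")
  out <- list()
  for (k in unique(key)) {
    sel <- which(key == k)
    sel <- sel[order(ts[sel])]
    out[[k]] <- minute_stream(
      participant_id = raw$participant_id[sel[1]],
      night_date = night[sel[1]],
      timestamp = ts[sel],
      temp_c = temp[sel],
      on_body = on_body[sel]
    )
  }
  out
}

#' Write minute streams to CSV
#'
#' @param streams A [minute_stream()] or list of them.
#' @param path Output path.
#' @param seed Optional integer recorded in a `# seed:` comment line.
#' @return `path`, invisibly.
#' @export
write_minute_csv <- function(streams, path, seed = NULL) {
  if (inherits(streams, "minute_stream")) streams <- list(streams)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  writeLines("participant_id,timestamp,temp_c,on_body", con)
  for (s in streams) {
    d <- s$data
    writeLines(paste(s$participant_id,
                     format(d$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                     as.character(d$temp_c), d$on_body, sep = ","), con)
  }
  invisible(path)
}

#' Detect the waking time of an overnight stream
#'
#' Under the study protocol the participant removes the armband immediately
#' on waking, so the wake time is the timestamp of the last on-body minute.
#' If the stream carries an explicit `wake_time` (e.g. supplied by external
#' software), that takes precedence. A night with more than one wear episode
#' is unusual wear behaviour: the last on-body minute of the final episode is
#' used, with a warning.
#'
#' @param stream A [minute_stream()].
#' @return The wake timestamp, or `NA` (with class POSIXct) for a non-wear
#'   night.
#' @export
detect_waking_time <- function(stream) {
  stopifnot(inherits(stream, "minute_stream"))
  if (!is.null(stream$wake_time)) return(stream$wake_time)
  on <- stream$data$on_body
  if (!any(on)) {
    return(as.POSIXct(NA, tz = "UTC"))
  }
  runs <- rle(on)
  if (sum(runs$values) > 1) {
    warning("multiple wear episodes in one night; using the final one",
            call. = FALSE)
  }
  stream$data$timestamp[max(which(on))]
}

#' Mean skin temperature over a pre-waking interval
#'
#' Averages on-body temperatures over the half-open window
#' `[wake - interval, wake)`, the waking minute itself excluded. Off-body
#' samples inside the window are ignored; if fewer than half of the window's
#' minutes are on-body the value is reported missing rather than computed
#' from thin coverage.
#'
#' @param stream A [minute_stream()].
#' @param interval_minutes Window length: one of 10, 30, 60, 90, 120.
#' @return The mean temperature in degrees C, or `NA`.
#' @export
prewaking_mean <- function(stream, interval_minutes) {
  if (!interval_minutes %in% c(10, 30, 60, 90, 120)) {
    stop("`interval_minutes` must be one of 10, 30, 60, 90, 120", call. = FALSE)
  }
  wake <- detect_waking_time(stream)
  if (is.na(wake)) return(NA_real_)
  d <- stream$data
  in_window <- d$timestamp >= wake - interval_minutes * 60 & d$timestamp < wake
  usable <- in_window & d$on_body
  if (sum(usable) < interval_minutes / 2) return(NA_real_)
  mean(d$temp_c[usable])
}

#' Merge oral logs and armband pre-waking means into a daily basal table
#'
#' One row per participant-day with the oral temperature and the five
#' pre-waking interval means of the matching night's stream. Streams are
#' matched on (participant, night date); streams with no matching daily-log
#' row are reported via a warning and an `orphans` attribute. The result is
#' sorted by participant and cycle day, so input order is irrelevant.
#'
#' @param series A list of oral [cycle_series()].
#' @param streams A list of [minute_stream()].
#' @return A tibble with columns `participant_id`, `cycle_day`, `date`,
#'   `oral`, `armband_10` ... `armband_120`, `illness`, `irregular_wake`.
#' @export
daily_basal_table <- function(series, streams) {
  if (inherits(series, "cycle_series")) series <- list(series)
  intervals <- c(10, 30, 60, 90, 120)
  stream_key <- vapply(streams, function(s) {
    paste(s$participant_id, format(s$night_date), sep = ":")
  }, character(1))
  names(streams) <- stream_key
  used <- character(0)
  rows <- lapply(series, function(s) {
    d <- s$data
    arm <- matrix(NA_real_, nrow = nrow(d), ncol = length(intervals))
    for (i in seq_len(nrow(d))) {
      k <- paste(s$participant_id, format(d$date[i]), sep = ":")
      if (!is.null(streams[[k]])) {
        used <<- c(used, k)
        for (j in seq_along(intervals)) {
          arm[i, j] <- prewaking_mean(streams[[k]], intervals[j])
        }
      }
    }
    colnames(arm) <- paste0("armband_", intervals)
    tibble::tibble(
      participant_id = s$participant_id,
      cycle_day = d$cycle_day,
      date = d$date,
      oral = d$temp_c,
      tibble::as_tibble(arm),
      illness = d$illness,
      irregular_wake = d$irregular_wake
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        .data$participant_id, .data$cycle_day)
  orphans <- setdiff(stream_key, used)
  if (length(orphans)) {
    warning(length(orphans), " stream(s) have no matching daily-log row: ",
            paste(utils::head(orphans, 5), collapse = ", "),
            if (length(orphans) > 5) ", ..." else "", call. = FALSE)
  }
  attr(out, "orphans") <- orphans
  out
}

#' Extract an armband pre-waking cycle series from a daily basal table
#'
#' Builds the [cycle_series()] a classifier consumes for the armband arm of
#' the comparison: daily values are the chosen pre-waking interval means,
#' with illness and irregular-wake flags carried over from the oral log.
#'
#' @param basal_table A [daily_basal_table()] result.
#' @param participant_id Participant to extract.
#' @param interval_minutes Pre-waking interval (default 60).
#' @return A [cycle_series()] with device `armband-<interval>`.
#' @export
armband_series <- function(basal_table, participant_id, interval_minutes = 60) {
  rows <- basal_table[basal_table$participant_id == participant_id, ]
  if (!nrow(rows)) stop("participant not found: ", participant_id, call. = FALSE)
  col <- paste0("armband_", interval_minutes)
  if (!col %in% names(basal_table)) {
    stop("no column ", col, " in basal table", call. = FALSE)
  }
  cycle_series(
    participant_id = participant_id,
    temp_c = rows[[col]],
    device = paste0("armband-", interval_minutes),
    start_date = rows$date[1],
    illness = rows$illness,
    irregular_wake = rows$irregular_wake
  )
}
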