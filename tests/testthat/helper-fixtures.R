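# Shared fixture builders. Everything is constructed in code; nothing on disk.

# A noise-free archetypal cycle: follicular plateau, optional nadir, sustained
# luteal shift. Returned as a cycle_series with ground truth attached.
clean_cycle <- function(len = 28, luteal = 14, f = 36.3, shift = 0.4,
                        nadir = 0.2, ovulatory = TRUE, id = "P01") {
  p <- cycle_params(
    cycle_length = len, ovulatory = ovulatory, luteal_length = luteal,
    follicular_mean = f, shift_magnitude = shift, nadir_depth = nadir,
    daily_noise_sd = 0, missing_prob = 0
  )
  generate_cycle(p, seed = 1, participant_id = id)
}

# A minute stream built directly from a temperature vector: minute timestamps
# starting at 23:00, on-body for the given minutes.
manual_stream <- function(temp_c, on_body = rep(TRUE, length(temp_c)),
                          id = "P01", night = as.Date("2015-06-01")) {
  start <- as.POSIXct(paste(format(night), "23:00:00"), tz = "UTC")
  minute_stream(
    participant_id = id, night_date = night,
    timestamp = start + 60 * (seq_along(temp_c) - 1),
    temp_c = temp_c, on_body = on_body
  )
}

# Independent brute-force Cohen's kappa: expand the table into the n
# individual rating pairs and compute observed/expected agreement by
# counting, never touching the package's marginal formula.
kappa_bruteforce <- function(tab) {
  tab <- as.matrix(tab)
  k <- nrow(tab)
  a <- integer(0); b <- integer(0)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      a <- c(a, rep(i, tab[i, j]))
      b <- c(b, rep(j, tab[i, j]))
    }
  }
  n <- length(a)
  p_o <- sum(a == b) / n
  p_e <- 0
  for (c in seq_len(k)) p_e <- p_e + (sum(a == c) / n) * (sum(b == c) / n)
  if (p_e >= 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

# Independent exhaustive scan for the three-over-six shift: for every
# candidate day in the window, rebuild the set of previous observed days from
# scratch and test the plateau condition directly.
biphasic_bruteforce <- function(temps, lo, hi, threshold = 0.2) {
  n <- length(temps)
  found <- NA_integer_
  evaluable <- FALSE
  for (d in seq(max(1, lo), min(n - 2, hi))) {
    prev_days <- c()
    for (j in seq_len(d - 1)) if (!is.na(temps[j])) prev_days <- c(prev_days, j)
    if (length(prev_days) < 6) next
    last6 <- prev_days[(length(prev_days) - 5):length(prev_days)]
    plateau <- temps[c(d, d + 1, d + 2)]
    if (any(is.na(plateau))) next
    evaluable <- TRUE
    coverline <- sum(temps[last6]) / 6
    ok <- TRUE
    for (v in plateau) if (!(v - coverline > threshold + 1e-6)) ok <- FALSE
    if (ok && is.na(found)) found <- d
  }
  list(shift_day = found, undetermined = !evaluable && is.na(found))
}

# A random daily series mixing flat and shifted shapes with noise and
# missingness, for oracle-equivalence sweeps.
random_cycle_temps <- function(len = 28) {
  f <- runif(1, 36.0, 36.5)
  t <- rep(f, len)
  if (runif(1) < 0.6) {
    sd_day <- sample(10:(len - 3), 1)
    t[sd_day:len] <- t[sd_day:len] + runif(1, 0.1, 0.6)
  }
  t <- t + rnorm(len, 0, runif(1, 0, 0.15))
  t[runif(len) < 0.1] <- NA
  t
}
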