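#' Exclude participants with insufficient temperature data
#'
#' Participants contributing fewer than `min_days` observed oral
#' temperatures cannot support a method comparison and are excluded, with
#' the rule and count recorded in an exclusion log.
#'
#' @param series A list of oral [cycle_series()].
#' @param min_days Minimum observed oral temperatures to retain a
#'   participant.
#' @return A list with `kept` (the retained series) and `log` (a tibble of
#'   excluded participants with their observed-day counts and the rule
#'   applied).
#' @export
exclusion_filter <- function(series, min_days = 17L) {
  if (inherits(series, "cycle_series")) series <- list(series)
  n_obs <- vapply(series, function(s) sum(!is.na(s$data$temp_c)), integer(1))
  keep <- n_obs >= min_days
  log <- tibble::tibble(
    participant_id = vapply(series[!keep], `[[`, character(1), "participant_id"),
    observed_days = n_obs[!keep],
    rule = sprintf("fewer than %d observed oral temperatures", min_days)
  )
  list(kept = series[keep], log = log)
}

#' Run the full device-comparison study
#'
#' Orchestrates the end-to-end analysis: obtain a cohort (simulated from a
#' [cohort_config()], or read from the daily-log and minute-stream CSVs),
#' exclude participants with insufficient data, reduce each night's stream
#' to pre-waking interval means, classify every participant's cycle by the
#' visual criteria and by the quantitative mean temperature method on both
#' the oral series and the armband series, and assemble the agreement
#' report: per-interval Spearman and Bland-Altman comparisons of the raw
#' temperatures, the counts of calls per method, and Cohen's kappa for the
#' four method-pair comparisons. All days from retained participants enter
#' the continuous comparison; the classifiers handle fever days internally.
#'
#' @param config A [cohort_config()] (simulation mode); ignored when CSV
#'   paths are given.
#' @param daily_csv,minute_csv Paths to input CSVs (data mode); both or
#'   neither.
#' @param interval_minutes Pre-waking interval used for the armband
#'   classification arm (the continuous comparison always covers all five).
#' @param min_observed_days Exclusion threshold for [exclusion_filter()].
#' @return An object of class `study_report`: a list with `calls` (tibble of
#'   per-participant categories by method), `counts` (method x category),
#'   `agreement` (four `agreement_result`s with their contingency tables),
#'   `continuous` (per-interval Spearman + Bland-Altman and the
#'   inter-interval rho matrix), `exclusions`, `truth` (simulation mode
#'   only) and `provenance` (seed and config hash).
#' @export
run_study <- function(config = cohort_config(),
                      daily_csv = NULL,
                      minute_csv = NULL,
                      interval_minutes = 60,
                      min_observed_days = 17L) {
  if (xor(is.null(daily_csv), is.null(minute_csv))) {
    stop("data mode needs both `daily_csv` and `minute_csv`", call. = FALSE)
  }
  if (!is.null(daily_csv)) {
    all_series <- read_daily_csv(daily_csv)
    series <- unname(Filter(function(s) s$device == "oral", all_series))
    streams <- unname(read_minute_csv(minute_csv))
    truth <- NULL
    provenance <- list(mode = "data", daily_csv = daily_csv,
                       minute_csv = minute_csv)
  } else {
    stopifnot(inherits(config, "cohort_config"))
    cohort <- generate_cohort(config)
    series <- lapply(cohort$participants, `[[`, "cycle")
    streams <- unlist(lapply(cohort$participants, `[[`, "streams"),
                      recursive = FALSE)
    truth <- cohort$truth
    provenance <- list(mode = "simulation", seed = config$seed,
                       config_hash = rlang::hash(config))
  }

  excl <- exclusion_filter(series, min_days = min_observed_days)
  if (!length(excl$kept)) {
    stop("no analyzable participants after exclusion (",
         nrow(excl$log), " excluded)", call. = FALSE)
  }
  kept_ids <- vapply(excl$kept, `[[`, character(1), "participant_id")
  basal <- daily_basal_table(excl$kept, streams)

  methods <- c("visual_oral", "visual_armband", "mtm_oral", "mtm_armband")
  call_objs <- lapply(excl$kept, function(s) {
    arm <- armband_series(basal, s$participant_id, interval_minutes)
    list(
      visual_oral = classify_visual(s, min_observed_days = min_observed_days),
      visual_armband = classify_visual(arm, min_observed_days = min_observed_days),
      mtm_oral = classify_mtm(s, min_observed_days = min_observed_days),
      mtm_armband = classify_mtm(arm, min_observed_days = min_observed_days)
    )
  })
  calls <- tibble::tibble(participant_id = kept_ids)
  for (m in methods) {
    calls[[m]] <- vapply(call_objs, function(x) x[[m]]$category, character(1))
  }
  counts <- t(vapply(methods, function(m) {
    table(factor(calls[[m]], levels = CALL_CATEGORIES))
  }, integer(3)))

  comparisons <- list(
    quantitative_devices = c("mtm_armband", "mtm_oral"),
    visual_devices = c("visual_armband", "visual_oral"),
    armband_methods = c("mtm_armband", "visual_armband"),
    oral_methods = c("mtm_oral", "visual_oral")
  )
  agreement <- lapply(comparisons, function(pair) {
    tab <- contingency_table(calls[[pair[1]]], calls[[pair[2]]])
    # a degenerate single-category comparison leaves kappa NA; the report
    # prints it as undefined, no need to propagate the warning per pair
    res <- suppressWarnings(cohens_kappa(tab))
    res$table <- tab
    res$raters <- pair
    res
  })

  intervals <- c(10, 30, 60, 90, 120)
  cols <- paste0("armband_", intervals)
  continuous <- lapply(seq_along(intervals), function(j) {
    list(
      interval = intervals[j],
      spearman = spearman_cor(basal$oral, basal[[cols[j]]]),
      bland_altman = bland_altman(basal$oral, basal[[cols[j]]])
    )
  })
  names(continuous) <- cols
  rho_between <- diag(1, length(intervals))
  dimnames(rho_between) <- list(cols, cols)
  for (i in seq_along(cols)) {
    for (j in seq_along(cols)) {
      if (i < j) {
        r <- spearman_cor(basal[[cols[i]]], basal[[cols[j]]])$rho
        rho_between[i, j] <- rho_between[j, i] <- r
      }
    }
  }

  structure(
    list(
      calls = calls,
      call_objects = call_objs,
      counts = counts,
      agreement = agreement,
      continuous = continuous,
      rho_between_intervals = rho_between,
      basal_table = basal,
      exclusions = excl$log,
      truth = truth,
      interval_minutes = interval_minutes,
      provenance = provenance
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("== BBT device-comparison study report ==\n")
  if (identical(x$provenance$mode, "simulation")) {
    cat(sprintf("simulated cohort, seed %d, config %s\n",
                x$provenance$seed, x$provenance$config_hash))
  } else {
    cat("data mode:", x$provenance$daily_csv, "\n")
  }
  cat(sprintf("%d analyzable participants (%d excluded)\n\n",
              nrow(x$calls), nrow(x$exclusions)))
  cat("Calls per method (ovulatory / anovulatory / inconclusive):\n")
  for (m in rownames(x$counts)) {
    cat(sprintf("  %-15s %2d / %2d / %2d\n", m,
                x$counts[m, 1], x$counts[m, 2], x$counts[m, 3]))
  }
  cat("\nAgreement between methods:\n")
  for (nm in names(x$agreement)) {
    a <- x$agreement[[nm]]
    cat(sprintf("  %-22s kappa %s, agreement %.2f%% (%s)\n", nm,
                ifelse(is.na(a$kappa), "undefined", sprintf("%.4f", a$kappa)),
                a$overall_pct, ifelse(is.na(a$interpretation), "-", a$interpretation)))
  }
  cat("\nOral vs armband temperatures (pooled participant-days):\n")
  for (c in x$continuous) {
    cat(sprintf("  %3d min: rho %.3f, bias %.3f C, LoA [%.2f, %.2f], slope %.3f (n=%d)\n",
                c$interval, c$spearman$rho, c$bland_altman$bias,
                c$bland_altman$loa_low, c$bland_altman$loa_high,
                c$bland_altman$prop_bias_slope, c$bland_altman$n))
  }
  rb <- x$rho_between_intervals[upper.tri(x$rho_between_intervals)]
  cat(sprintf("Inter-interval rho range: %.3f-%.3f\n", min(rb), max(rb)))
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Writes the report's numeric summaries (counts, kappas, agreement
#' percentages, per-interval correlation and Bland-Altman results,
#' exclusions, provenance) as JSON for downstream consumption.
#'
#' @param report A [run_study()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  out <- list(
    provenance = report$provenance,
    n_analyzable = nrow(report$calls),
    exclusions = report$exclusions,
    counts = as.data.frame.matrix(report$counts),
    agreement = lapply(report$agreement, function(a) {
      list(kappa = a$kappa, overall_pct = a$overall_pct,
           per_category_pct = as.list(a$per_category_pct),
           interpretation = a$interpretation,
           table = unclass(as.data.frame.matrix(a$table)))
    }),
    continuous = lapply(report$continuous, function(c) {
      list(interval = c$interval, rho = c$spearman$rho,
           p_value = c$spearman$p_value,
           bias = c$bland_altman$bias, sd_diff = c$bland_altman$sd_diff,
           loa_low = c$bland_altman$loa_low, loa_high = c$bland_altman$loa_high,
           prop_bias_slope = c$bland_altman$prop_bias_slope,
           n = c$bland_altman$n)
    }),
    rho_between_intervals = report$rho_between_intervals
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
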