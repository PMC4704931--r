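# Agreement statistics between measurement methods.
#
# Continuous comparisons (thermometer vs armband temperatures) use Spearman
# rank correlation and Bland-Altman analysis; categorical comparisons
# (ovulation calls) use Cohen's kappa on a 3x3 contingency table with the
# convention that per-category agreement is the concordant count in that
# category divided by all pairs, so the per-category values sum to the
# overall agreement.

CALL_CATEGORIES <- c("ovulatory", "anovulatory", "inconclusive")

#' Spearman rank correlation between paired temperatures
#'
#' Pairs with any missing member are dropped listwise; ties receive average
#' ranks and the p-value is two-sided (asymptotic). With fewer than three
#' complete pairs the correlation is meaningless and an error is raised;
#' zero variance in either vector leaves rho undefined (`NA`), signalled
#' distinctly from zero correlation.
#'
#' @param x,y Paired numeric vectors.
#' @return A list with `rho`, `p_value` and `n` (complete pairs).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: Spearman's rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Bland-Altman agreement between two measurement methods
#'
#' Computes the paired differences `x - y` against the pair means
#' `(x + y)/2`: the bias (mean difference), the SD of differences, 95%
#' limits of agreement (bias +/- 1.96 SD) and the proportional-bias slope
#' (least-squares slope of difference on mean; a negative slope means the
#' methods diverge more at lower temperatures).
#'
#' @param x,y Paired numeric vectors (`x` is the reference method).
#' @return A list with `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `prop_bias_slope` and `n`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) stop("fewer than 2 complete pairs", call. = FALSE)
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  slope <- if (stats::var(m) > 0) {
    unname(stats::coef(stats::lm(d ~ m))[2])
  } else {
    NA_real_
  }
  list(
    bias = bias,
    sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff,
    loa_high = bias + 1.96 * sd_diff,
    prop_bias_slope = slope,
    n = n
  )
}

#' Cross-tabulate two raters' ovulation calls
#'
#' @param calls_a,calls_b Equal-length vectors (or lists of
#'   [ovulation_call()]) of categories, aligned by participant.
#' @return A 3x3 contingency table (rows: rater A) over the categories
#'   ovulatory, anovulatory, inconclusive.
#' @export
contingency_table <- function(calls_a, calls_b) {
  to_cat <- function(calls) {
    v <- vapply(calls, function(x) {
      if (inherits(x, "ovulation_call")) x$category else as.character(x)
    }, character(1))
    factor(v, levels = CALL_CATEGORIES)
  }
  a <- to_cat(calls_a)
  b <- to_cat(calls_b)
  if (length(a) != length(b)) stop("call lists differ in length", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("unknown call category", call. = FALSE)
  table(a, b, dnn = c("rater_a", "rater_b"))
}

#' Cohen's kappa and agreement percentages for a contingency table
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, where `p_o`
#' is the observed agreement (diagonal sum over `n`) and `p_e` the agreement
#' expected from the marginals. Per-category agreement is the concordant
#' count in that category divided by `n`, so the per-category percentages
#' sum to the overall percentage. When both raters call a single identical
#' category throughout, `p_e = 1` and kappa is undefined (`NA`), which is
#' signalled distinctly from `kappa = 0`.
#'
#' @param tab A square contingency table or matrix of counts (such as
#'   [contingency_table()] produces).
#' @return An object of class `agreement_result`: a list with `kappa`,
#'   `overall_pct`, `per_category_pct`, `interpretation`, `p_o`, `p_e`, `n`.
#' @export
cohens_kappa <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("contingency table must be square", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(tab)
  if (n < 1) stop("empty contingency table", call. = FALSE)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (p_e >= 1) {
    warning("expected agreement is 1: kappa undefined", call. = FALSE)
    NA_real_
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  per_cat <- 100 * diag(tab) / n
  if (!is.null(rownames(tab))) names(per_cat) <- rownames(tab)
  structure(
    list(
      kappa = kappa,
      overall_pct = 100 * p_o,
      per_category_pct = per_cat,
      interpretation = interpret_kappa(kappa),
      p_o = p_o,
      p_e = p_e,
      n = n
    ),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> kappa %s (%s), agreement %.2f%% of n=%d\n",
              ifelse(is.na(x$kappa), "undefined", sprintf("%.4f", x$kappa)),
              ifelse(is.na(x$interpretation), "-", x$interpretation),
              x$overall_pct, x$n))
  if (!is.null(names(x$per_category_pct))) {
    cat("  per category:",
        paste(sprintf("%s %.2f%%", names(x$per_category_pct),
                      x$per_category_pct), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cohen's kappa directly from two call lists
#'
#' Builds the [contingency_table()] of two aligned call lists and delegates
#' to [cohens_kappa()].
#'
#' @inheritParams contingency_table
#' @return An `agreement_result`, as from [cohens_kappa()].
#' @export
kappa_from_calls <- function(calls_a, calls_b) {
  cohens_kappa(contingency_table(calls_a, calls_b))
}

#' Interpretation band for a kappa value
#'
#' Kappa above .75 indicates excellent agreement; between .4 and .75
#' inclusive, fair to good; below .4, moderate to poor.
#'
#' @param kappa A kappa value (or `NA`).
#' @return `"excellent"`, `"fair-to-good"`, `"moderate-to-poor"`, or `NA`
#'   when kappa is undefined.
#' @export
interpret_kappa <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa > 0.75) return("excellent")
  if (kappa >= 0.4) return("fair-to-good")
  "moderate-to-poor"
}
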