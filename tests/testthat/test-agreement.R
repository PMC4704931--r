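test_that("Spearman's rho hits the exact values on monotone pairs", {
  x <- c(36.1, 36.3, 36.5, 36.7, 36.9)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
})

test_that("Spearman's rho matches a rank-then-Pearson oracle with ties", {
  x <- c(36.4, 36.2, 36.2, 36.8, 36.5, 36.1, 36.9, 36.3, 36.5, 36.6)
  y <- c(34.1, 33.9, 34.6, 35.2, 34.6, 33.5, 35.0, 34.0, 34.3, 34.6)
  oracle <- cor(rank(x), rank(y))  # average ranks, then product-moment
  expect_equal(spearman_cor(x, y)$rho, oracle)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rnorm(30, 36.4, 0.3)
  y <- x + rnorm(30, 0, 0.2)
  base <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x - 36), y)$rho, base)
  expect_equal(spearman_cor(x, y^3)$rho, base)
})

test_that("Spearman signals degenerate inputs", {
  expect_error(spearman_cor(c(1, 2), c(1, 2)), "fewer than 3")
  expect_warning(r <- spearman_cor(rep(36.4, 5), 1:5), "zero variance")
  expect_true(is.na(r$rho))
  # missing pairs are dropped listwise
  x <- c(1, 2, 3, 4, NA)
  y <- c(2, 4, 6, NA, 10)
  expect_equal(spearman_cor(x, y)$n, 3)
})

test_that("Bland-Altman recovers exact bias, limits and slope", {
  x <- c(36.2, 36.4, 36.6, 36.8)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(same$prop_bias_slope, 0)

  offset <- bland_altman(x, x - 1.8)
  expect_equal(offset$bias, 1.8)
  expect_equal(offset$prop_bias_slope, 0)
  expect_equal(offset$loa_low, 1.8)
  expect_equal(offset$loa_high, 1.8)
})

test_that("Bland-Altman bias is exactly mean(x) - mean(y); order is irrelevant", {
  set.seed(13)
  x <- rnorm(50, 36.4, 0.3)
  y <- rnorm(50, 34.6, 1.2)
  res <- bland_altman(x, y)
  expect_equal(res$bias, mean(x) - mean(y))
  expect_equal(res$loa_low, res$bias - 1.96 * res$sd_diff)
  perm <- sample(50)
  res2 <- bland_altman(x[perm], y[perm])
  expect_equal(res2$bias, res$bias)
  expect_equal(res2$sd_diff, res$sd_diff)
  expect_equal(res2$prop_bias_slope, res$prop_bias_slope)
  expect_error(bland_altman(36.4, 34.6), "fewer than 2")
})

test_that("kappa is 1 exactly when all disagreement cells are empty", {
  perfect <- diag(c(4, 8, 3))
  expect_equal(cohens_kappa(perfect)$kappa, 1)
  almost <- perfect; almost[1, 2] <- 1
  expect_lt(cohens_kappa(almost)$kappa, 1)
})

test_that("kappa matches the brute-force pair-expansion computation", {
  set.seed(17)
  for (i in 1:50) {
    tab <- matrix(rpois(9, 3), 3, 3)
    if (sum(tab) == 0) tab[1, 1] <- 1
    mine <- cohens_kappa(tab)$kappa
    expect_equal(mine, kappa_bruteforce(tab), tolerance = 1e-12)
  }
})

test_that("kappa agrees with an independent library implementation", {
  skip_if_not_installed("e1071")
  set.seed(23)
  for (i in 1:20) {
    tab <- matrix(rpois(9, 4), 3, 3)
    if (sum(tab) == 0) tab[2, 2] <- 5
    expect_equal(cohens_kappa(tab)$kappa,
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("degenerate identical-constant raters give undefined kappa, not zero", {
  tab <- matrix(0, 3, 3); tab[2, 2] <- 15
  expect_warning(res <- cohens_kappa(tab), "undefined")
  expect_true(is.na(res$kappa))
  expect_equal(res$overall_pct, 100)
})

test_that("per-category agreements sum to the overall agreement", {
  set.seed(29)
  for (i in 1:20) {
    tab <- matrix(rpois(9, 3), 3, 3) + diag(3)
    res <- cohens_kappa(tab)
    expect_equal(sum(res$per_category_pct), res$overall_pct)
  }
})

test_that("kappa from call lists equals kappa on the induced table", {
  a <- c("ovulatory", "anovulatory", "anovulatory", "inconclusive", "ovulatory")
  b <- c("ovulatory", "anovulatory", "ovulatory", "inconclusive", "anovulatory")
  res <- kappa_from_calls(a, b)
  expect_equal(res$kappa, cohens_kappa(contingency_table(a, b))$kappa)
  expect_equal(kappa_from_calls(a, a)$kappa, 1)
  expect_error(kappa_from_calls(a, b[1:3]), "length")
})

test_that("independent random calls give kappa near zero", {
  set.seed(31)
  cats <- c("ovulatory", "anovulatory", "inconclusive")
  a <- sample(cats, 10000, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  b <- sample(cats, 10000, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  expect_lt(abs(kappa_from_calls(a, b)$kappa), 0.05)
})

test_that("interpretation bands follow the study's thresholds at the boundaries", {
  expect_equal(interpret_kappa(0.0816), "moderate-to-poor")
  expect_equal(interpret_kappa(0.4915), "fair-to-good")
  expect_equal(interpret_kappa(0.4), "fair-to-good")
  expect_equal(interpret_kappa(0.75), "fair-to-good")
  expect_equal(interpret_kappa(0.76), "excellent")
  expect_equal(interpret_kappa(0.39), "moderate-to-poor")
  expect_true(is.na(interpret_kappa(NA_real_)))
})
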