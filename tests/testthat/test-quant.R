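test_that("standard-curve fitting reproduces exact and doubling data", {
  concs <- 10^seq(0, -7)
  d <- data.frame(conc = concs)
  for (k in 1:3) d[[paste0("ct", k)]] <- -3.1136 * log10(concs) + 3.6102
  fit <- fit_standard_curve(d)
  expect_equal(fit$slope, -3.1136, tolerance = 1e-10)
  expect_equal(fit$intercept, 3.6102, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(coef(fit), c(intercept = 3.6102, slope = -3.1136),
               tolerance = 1e-10)

  # perfect doubling: slope -1/log10(2) gives 100% efficiency
  d2 <- data.frame(conc = concs, ct = (-1 / log10(2)) * log10(concs) + 20)
  fit2 <- fit_standard_curve(d2)
  expect_equal(fit2$efficiency, 1, tolerance = 1e-10)

  expect_error(fit_standard_curve(data.frame(conc = c(1, 0.1, -1),
                                             ct = c(1, 2, 3))), "positive")
  expect_error(fit_standard_curve(data.frame(conc = c(1, 0.1),
                                             ct = c(1, 2))), "3 distinct")
})

test_that("slope estimation is consistent with closed-form OLS and unbiased", {
  concs <- 10^seq(-1, -8)
  x <- log10(concs)
  true_slope <- -3.25; true_int <- 4.4
  ols_slope <- function(xx, yy) {
    sum((xx - mean(xx)) * (yy - mean(yy))) / sum((xx - mean(xx))^2)
  }
  slopes <- numeric(400)
  for (s in seq_along(slopes)) {
    set.seed(s)
    ct <- matrix(true_slope * x + true_int, 8, 3) + matrix(rnorm(24, 0, 0.2), 8, 3)
    d <- data.frame(conc = concs, ct1 = ct[, 1], ct2 = ct[, 2], ct3 = ct[, 3])
    fit <- fit_standard_curve(d)
    # the fit is exactly OLS of mean Ct on log10(conc)
    expect_equal(fit$slope, ols_slope(x, rowMeans(ct)), tolerance = 1e-10)
    slopes[s] <- fit$slope
  }
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - true_slope), 3 * mc_se)
})

test_that("efficiency follows the closed form", {
  expect_equal(round(100 * efficiency_from_slope(-3.1136), 2), 109.49)
  expect_equal(efficiency_from_slope(-1 / log10(2)), 1, tolerance = 1e-12)
  # high-precision reference value for 10^(1/3.45) - 1
  expect_equal(efficiency_from_slope(-3.45), 0.9491940296, tolerance = 1e-9)
  expect_error(efficiency_from_slope(3.1), "slope")
})

test_that("curve inversion is exact and flags the reliable window", {
  curve <- standard_curve(-3.1136, 3.6102)
  expect_equal(as.numeric(ct_to_concentration(curve, curve$intercept,
                                              flag_window = FALSE)), 1)
  # forward-then-inverse identity across the printed dilution span
  for (conc in c(1.44, 1.44e-3, 1.44e-6)) {
    back <- ct_to_concentration(curve, predict(curve, conc), flag_window = FALSE)
    expect_equal(as.numeric(back), conc, tolerance = 1e-12)
  }
  # a Ct beyond the reliable window is flagged but still converted
  ct_far <- predict(curve, 1.44e-9)
  expect_gt(ct_far, curve$ct_max)
  conc <- ct_to_concentration(curve, c(15, ct_far))
  expect_equal(attr(conc, "flagged"), c(FALSE, TRUE))
  expect_equal(as.numeric(conc[2]), 1.44e-9, tolerance = 1e-12)
})

test_that("mass-mole conversion tracks length and strandedness", {
  expect_equal(ng_to_amol(0, 1000), 0)
  expect_equal(ng_to_amol(1, 1000, "ds"), 1e9 / (660 * 1000))
  expect_equal(ng_to_amol(1, 1000, "ss"), 1e9 / (330 * 1000))
  # halving the length doubles the moles at fixed mass
  expect_equal(ng_to_amol(1, 500), 2 * ng_to_amol(1, 1000))
  # round trip with the inverse
  expect_equal(amol_to_ng(ng_to_amol(2.5, 873), 873), 2.5, tolerance = 1e-12)
})

test_that("replicate outlier handling follows the median rule", {
  expect_equal(remove_outliers(c(20.0, 20.1, 20.2)), rep(TRUE, 3))
  expect_equal(remove_outliers(c(20.0, 20.1, 25.0)), c(TRUE, TRUE, FALSE))
  set.seed(41)
  x <- rnorm(3, 20, 5)
  expect_equal(remove_outliers(x, Inf), rep(TRUE, 3))
  # two discordant wells: neither can be called the outlier
  expect_equal(remove_outliers(c(20, 25)), c(TRUE, TRUE))
})

test_that("normalization is a plain ratio", {
  expect_equal(normalize_amount(2, 2), 1)
  expect_equal(normalize_amount(0, 3), 0)
  expect_equal(normalize_amount(5 * 1.3, 2), 5 * normalize_amount(1.3, 2))
  expect_error(normalize_amount(1, 0), "reference")
})

test_that("stability ratios behave for identical genes and match the delta method", {
  reps <- data.frame(
    gene = rep(c("g1", "g2"), each = 3),
    sample = "s1", replicate = rep(1:3, 2),
    amount = rep(c(2.2, 2.4, 2.1), 2)
  )
  st <- stability_ratios(reps)
  expect_equal(st$mean_ratio, c(1, 1))
  expect_equal(st$sd_ratio, c(0, 0))

  # lognormal replicate noise: sd of the ratio approaches the delta-method
  # value (A/B) * sqrt(sa^2 + sb^2) at large replicate counts
  set.seed(42)
  n <- 1e5; A <- 5; B <- 2; sa <- 0.05; sb <- 0.08
  sim <- data.frame(
    gene = rep(c("a", "b"), each = n),
    sample = "s1", replicate = rep(seq_len(n), 2),
    amount = c(A * exp(rnorm(n, 0, sa)), B * exp(rnorm(n, 0, sb)))
  )
  st2 <- stability_ratios(sim)
  ab <- st2[st2$numerator == "a" & st2$denominator == "b", ]
  pred_sd <- (A / B) * sqrt(sa^2 + sb^2)
  expect_lt(abs(ab$sd_ratio - pred_sd) / pred_sd, 0.02)
  # reciprocal product within replicate-noise tolerance
  ba <- st2[st2$numerator == "b" & st2$denominator == "a", ]
  expect_lt(abs(ab$mean_ratio * ba$mean_ratio - 1), 0.05)
})

test_that("contribution percentages are scale-free and sum to 100", {
  eq <- data.frame(sample = "s", family = paste0("f", 1:5), amount = 3)
  expect_equal(contribution_report(eq)$percent, rep(20, 5))

  set.seed(43)
  amt <- data.frame(sample = rep(c("a", "b"), each = 4),
                    family = rep(paste0("f", 1:4), 2),
                    amount = runif(8, 0.1, 9))
  rep1 <- contribution_report(amt)
  amt2 <- amt; amt2$amount <- amt2$amount * 37.5
  expect_equal(contribution_report(amt2)$percent, rep1$percent)
  sums <- tapply(rep1$percent, rep1$sample, sum)
  expect_equal(as.numeric(sums), c(100, 100))
})

test_that("subgroup shares and member coverage reproduce reported ratios", {
  expect_equal(round(subgroup_share(12.29, 35.02), 2), 35.09)
  expect_equal(round(subgroup_share(7.45, 15.84), 2), 47.03)
  expect_equal(subgroup_share(4, 4), 100)
  flagged <- subgroup_share(5, 4)
  expect_true(isTRUE(attr(flagged, "flagged")))

  expect_equal(round(member_coverage(c(0.08, 4.58), 5.16), 2), 90.31)
  expect_equal(round(member_coverage(c(0.18, 5.73), 8.72), 2), 67.78)
  expect_equal(member_coverage(numeric(0), 5), 0)
})

test_that("amounts survive the full Ct pipeline exactly at zero noise", {
  curve <- standard_curve(-3.4, 3.8)
  lengths <- c(g1 = 800, g2 = 1200, ref = 1000)
  amol <- c(g1 = 0.4, g2 = 2.5, ref = 1.0)
  ct_of <- function(set) predict(curve, amol_to_ng(amol[[set]], lengths[[set]]))
  ct_table <- data.frame(
    primer_set = rep(names(amol), 2),
    sample = rep(c("s1", "s2"), each = 3),
    ct1 = rep(vapply(names(amol), ct_of, numeric(1)), 2)
  )
  ct_table$ct2 <- ct_table$ct1
  ct_table$ct3 <- ct_table$ct1
  q <- run_quantify(ct_table, curve, lengths, reference = "ref")
  expect_equal(q$amount_amol, unname(amol[q$primer_set]), tolerance = 1e-9)
  expect_equal(q$normalized[q$primer_set == "g2"], c(2.5, 2.5),
               tolerance = 1e-9)
  expect_false(any(q$ct_flagged))
})
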