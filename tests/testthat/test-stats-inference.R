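# Statistical machinery: textbook-formula oracles, hand-computed tables,
# paper-table arithmetic and invariance properties.

test_that("pooled t-test matches the textbook formula", {
  x1 <- c(1, 2, 3); x2 <- c(4, 5, 6)
  res <- two_sample_ttest(x1, x2)
  # independent recomputation from first principles
  sp2 <- (2 * var(x1) + 2 * var(x2)) / 4
  t_exp <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_exp, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_exp), df = 4), tolerance = 1e-12)

  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # shift invariance
  sh <- two_sample_ttest(x1 + 17, x2 + 17)
  expect_equal(sh$statistic, res$statistic, tolerance = 1e-12)

  # degenerate zero-variance branches
  expect_equal(two_sample_ttest(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(two_sample_ttest(c(2, 2), c(3, 3))$p_value, 0)
})

test_that("chi-squared statistic equals sum (O-E)^2/E on the gender table", {
  tab <- matrix(c(46, 15, 18, 17), 2, 2)
  res <- chi_squared_2x2(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$statistic, 5.75, tolerance = 0.01)
  # transposition symmetry
  expect_equal(chi_squared_2x2(t(tab))$statistic, res$statistic)
  # independent (outer-product) table
  ind <- outer(c(2, 3), c(4, 8))
  expect_equal(chi_squared_2x2(ind)$statistic, 0, tolerance = 1e-12)
  expect_equal(chi_squared_2x2(ind)$p_value, 1)
  expect_error(chi_squared_2x2(matrix(c(0, 0, 3, 4), 2, 2)), "marginal")
})

test_that("auc equals the exhaustive pairwise count, ties at one half", {
  expect_equal(auc_mann_whitney(c(3, 2, 1, 2.5), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_mann_whitney(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_mann_whitney(rep(3, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  set.seed(42)
  for (rep in 1:50) {
    n1 <- sample(2:6, 1); n0 <- sample(2:6, 1)
    s <- round(rnorm(n1 + n0), 1)        # rounding forces ties
    y <- c(rep(TRUE, n1), rep(FALSE, n0))
    brute <- mean(outer(s[y], s[!y], function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(auc_mann_whitney(s, y), brute, tolerance = 1e-12)
    # tie-free scores: trapezoidal area under the empirical roc
    s2 <- s + seq_along(s) * 1e-6
    rc <- roc_curve(s2, y)
    trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
    expect_equal(auc_mann_whitney(s2, y), trap, tolerance = 1e-9)
  }
})

test_that("operating point maximises youden and reports the printed lr arithmetic", {
  expect_equal(likelihood_ratio_pos(0.97, 0.79), 4.619, tolerance = 1e-3)
  expect_equal(inv_likelihood_ratio_neg(0.97, 0.79), 26.33, tolerance = 1e-2)
  expect_equal(likelihood_ratio_pos(0.939, 0.871), 7.279, tolerance = 1e-3)
  expect_equal(inv_likelihood_ratio_neg(0.939, 0.871), 14.28, tolerance = 5e-3)
  expect_equal(likelihood_ratio_pos(0.909, 0.823), 5.136, tolerance = 1e-3)
  expect_equal(likelihood_ratio_pos(0.909, 0.726), 3.318, tolerance = 1e-3)
  expect_equal(likelihood_ratio_pos(0.5, 0.5), 1.0)

  set.seed(9)
  s <- rnorm(60); y <- c(rep(TRUE, 25), rep(FALSE, 35))
  s[y] <- s[y] + 1.2
  d <- optimise_operating_point(s, y)
  # exhaustive check over all thresholds
  js <- sapply(unique(s), function(t) {
    mean(s[y] >= t) + mean(s[!y] < t) - 1
  })
  expect_equal(d$youden, max(js), tolerance = 1e-12)
  expect_equal(d$lr_plus, d$sensitivity / (1 - d$specificity))
  expect_equal(d$accuracy, mean((s >= d$optimal_threshold) == y))
  # monotone-transform invariance of the chosen classification
  d2 <- optimise_operating_point(exp(s), y)
  expect_equal(d2$sensitivity, d$sensitivity)
  expect_equal(d2$specificity, d$specificity)
  expect_equal(d2$auc, d$auc)
})

test_that("stepwise logistic recovers the 2x2 cross-product odds ratio", {
  # IPH-like binary predictor: 19/61 exposed among cases, 1/35 in controls
  y <- c(rep(TRUE, 61), rep(FALSE, 35))
  x <- c(rep(1, 19), rep(0, 42), rep(1, 1), rep(0, 34))
  d <- data.frame(y = y, x = x)
  fit <- stepwise_logistic(d, "y", "x")
  expect_identical(fit$selected, "x")
  expect_equal(fit$odds_ratios$or, (19 * 34) / (42 * 1), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_true(fit$odds_ratios$ci_lower <= fit$odds_ratios$or)
  expect_true(fit$odds_ratios$ci_upper >= fit$odds_ratios$or)

  # an irrelevant duplicated-information column leaves the selected OR alone
  d$z <- rnorm(96, sd = 0.01)
  fit2 <- stepwise_logistic(d, "y", c("x", "z"))
  expect_equal(fit2$odds_ratios$or[fit2$odds_ratios$variable == "x"],
               (19 * 34) / (42 * 1), tolerance = 1e-4)
  expect_error(stepwise_logistic(data.frame(y = y, k = 1), "y", "k"),
               "constant")
})

test_that("stepwise selection stays empty under a pure-noise null", {
  # a candidate survives only if its removal LRT p stays < 0.05, so with two
  # null candidates the selection should be empty in about 0.95^2 = 90% of
  # repetitions
  set.seed(101)
  empty <- 0
  for (rep in 1:30) {
    d <- as.data.frame(matrix(rnorm(500 * 2), 500, 2))
    d$y <- rep(c(TRUE, FALSE), 250)
    fit <- stepwise_logistic(d, "y", paste0("V", 1:2))
    if (length(fit$selected) == 0) empty <- empty + 1
  }
  expect_gte(empty, 24)
})

test_that("feature selection gates on both p-value and symmetric auc", {
  set.seed(55)
  y <- c(rep(TRUE, 48), rep(FALSE, 48))
  strong <- rnorm(96) + 1.5 * y           # passes both
  weak <- rnorm(96) + 0.3 * y             # significant-ish but low auc
  inverted <- rnorm(96) - 1.5 * y         # auc < 0.5, symmetric gate applies
  noise <- rnorm(96)
  f <- data.frame(strong = strong, weak = weak, inverted = inverted,
                  noise = noise)
  sel <- select_radiomic_features(f, y)
  expect_true("strong" %in% sel)
  expect_true("inverted" %in% sel)
  expect_false("noise" %in% sel)
  expect_identical(select_radiomic_features(f["noise"], y), character(0))
  # BH adjustment only ever shrinks the selection
  sel_bh <- select_radiomic_features(f, y, p_adjust = "BH")
  expect_true(all(sel_bh %in% sel))
})

test_that("delong test is degenerate-safe, antisymmetric and matches pROC", {
  set.seed(77)
  y <- c(rep(TRUE, 40), rep(FALSE, 60))
  s1 <- rnorm(100) + y
  s2 <- 0.7 * s1 + rnorm(100, sd = 0.8)

  same <- delong_test(s1, s1, y)
  expect_equal(same$z, 0); expect_equal(same$p_value, 1)

  dl <- delong_test(s1, s2, y)
  # label swap maps aucs to their complements, |z| unchanged
  sw <- delong_test(s1, s2, !y)
  expect_equal(sw$auc1, 1 - dl$auc1, tolerance = 1e-12)
  expect_equal(sw$auc2, 1 - dl$auc2, tolerance = 1e-12)
  expect_equal(abs(sw$z), abs(dl$z), tolerance = 1e-12)
  # monotone-transform invariance
  tr <- delong_test(exp(s1), s2^3 + 2 * s2, y)
  expect_equal(tr$z, dl$z, tolerance = 1e-12)

  skip_if_not_installed("pROC")
  r1 <- pROC::roc(y, s1, quiet = TRUE, direction = "<")
  r2 <- pROC::roc(y, s2, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(r1, r2, method = "delong")
  expect_equal(dl$p_value, ref$p.value, tolerance = 1e-9)
  v1 <- delong_auc_variance(s1, y)
  expect_equal(v1, pROC::var(r1, method = "delong"), tolerance = 1e-9)
})
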