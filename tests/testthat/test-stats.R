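test_that("paired t matches the textbook formula on hand data", {
  res <- paired_t(c(1, 2, 3, 4))
  expect_equal(res$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(round(res$t, 3), 3.873)
  expect_equal(res$df, 3)
  expect_equal(res$cohen_d, 2.5 / sd(1:4))
  expect_equal(res$cohen_d, abs(res$t) / sqrt(res$n))
  # 95% CI = mean +/- t_{.975,3} * SE
  se <- sd(1:4) / 2
  expect_equal(res$ci_low, 2.5 - qt(0.975, 3) * se)
  expect_equal(res$ci_high, 2.5 + qt(0.975, 3) * se)
})

test_that("paired t on two conditions uses a - b and pairwise completion", {
  a <- c(10, 12, 14, 16, NA)
  b <- c(9, 13, 12, 15, 99)
  res <- paired_t(a, b, variable = "demo")
  expect_equal(res$n, 4)
  expect_equal(res$df, 3)
  expect_equal(res$mean_diff, mean(c(1, -1, 2, 1)))
  expect_equal(sign(res$t), sign(res$mean_diff))
  expect_identical(res$variable, "demo")
})

test_that("zero-variance differences are a degenerate-input error", {
  expect_error(paired_t(c(2, 2, 2)), "zero variance")
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero variance")
})

test_that("Welch test reproduces a by-hand Satterthwaite computation", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 6)
  res <- welch_t(x, y)
  vx <- var(x) / 3
  vy <- var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 / (vx^2 / 2 + vy^2 / 2)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand))

  # equal variances, equal n: df collapses to n1 + n2 - 2
  res2 <- welch_t(c(1, 2, 3), c(11, 12, 13))
  expect_equal(res2$df, 4)
  res3 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res3$t, 0)
  expect_equal(res3$p, 1)
})

test_that("correlation intervals follow the Fisher-z transform", {
  ci <- fisher_z_ci(0.48, 123)
  expect_equal(round(ci$ci_low, 2), 0.33)
  expect_equal(round(ci$ci_high, 2), 0.61)
  z <- atanh(0.48)
  expect_equal(ci$ci_low, tanh(z - qnorm(0.975) / sqrt(120)))

  x <- c(1, 2, 4, 5, 7, 9)
  y <- c(2, 3, 3, 6, 8, 8)
  res <- pearson_r_ci(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle)
  expect_equal(res$df, 4)

  lin <- pearson_r_ci(1:10, 2 * (1:10) + 3)
  expect_equal(lin$r, 1)
  expect_error(pearson_r_ci(1:4, rep(1, 4)), "zero variance")
})

test_that("Fisher exact p values match hypergeometric enumeration", {
  expect_equal(signif(fisher_exact_2x2(1, 9, 11, 3)$p, 4), 0.002759)
  # independent enumeration over all tables with the observed margins
  p_obs <- dhyper(1, 10, 14, 12)
  p_enum <- sum(dhyper(0:10, 10, 14, 12)[dhyper(0:10, 10, 14, 12) <=
                                           p_obs + 1e-12])
  expect_equal(fisher_exact_2x2(1, 9, 11, 3)$p, p_enum)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p, 1)
  expect_equal(fisher_exact_2x2(0, 0, 3, 4)$p, 1)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "All-zero")
  expect_error(fisher_exact_2x2(1.5, 2, 3, 4), "integer")
})

test_that("JZS Bayes factor agrees with an independent quadrature oracle", {
  for (t in c(0, 1, 2, 4, 6.61)) {
    for (n in c(25, 121, 123)) {
      expect_equal(jzs_bf10(t, n), bf10_trapezoid_oracle(t, n),
                   tolerance = 1e-3)
    }
  }
})

test_that("JZS Bayes factor is symmetric, monotone in |t|, and < 1 at t = 0", {
  expect_equal(jzs_bf10(2.5, 40), jzs_bf10(-2.5, 40))
  for (n in c(5, 50, 123)) {
    expect_lt(jzs_bf10(0, n), 1)
    bfs <- jzs_bf10(c(0, 0.5, 1, 2, 3, 5), n)
    expect_true(all(diff(bfs) > 0))
  }
  expect_error(jzs_bf10(1, 1), ">= 2")
  expect_error(jzs_bf10(Inf, 10), "finite")
})

test_that("evidence bands follow the conventional cut points", {
  expect_identical(bf_evidence(242.35), "very strong (H1)")
  expect_identical(bf_evidence(15), "strong (H1)")
  expect_identical(bf_evidence(5), "moderate (H1)")
  expect_identical(bf_evidence(1), "anecdotal (H1)")
  expect_identical(bf_evidence(0.5), "anecdotal (H0)")
  expect_identical(bf_evidence(0.11), "moderate (H0)")
  expect_identical(bf_evidence(0.05), "strong (H0)")
  expect_identical(bf_evidence(0.01), "very strong (H0)")
  # boundary values land in the stronger band
  expect_identical(bf_evidence(30), "very strong (H1)")
  expect_identical(bf_evidence(3), "moderate (H1)")
  expect_identical(bf_evidence(1 / 30), "very strong (H0)")
  expect_identical(bf_evidence(1 / 10), "strong (H0)")
  expect_error(bf_evidence(0), "positive")
})
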