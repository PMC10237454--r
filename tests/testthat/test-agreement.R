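test_that("pearson_validity matches the covariance formula and bands", {
  a <- c(0.31, 0.45, 0.52, 0.40, 0.66)
  b <- c(0.35, 0.41, 0.60, 0.38, 0.71)
  res <- pearson_validity(paired_table(a, b))
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_stat <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res$p_value, 2 * pt(-abs(t_stat), df = 3), tolerance = 1e-12)

  ident <- pearson_validity(paired_table(a, a))
  expect_equal(ident$r, 1)
  expect_equal(ident$band, "very high")

  expect_equal(correlation_band(0.906), "very high")
  expect_equal(correlation_band(0.672), "moderate")
  expect_equal(correlation_band(0.49), "low")
  expect_equal(correlation_band(0.75), "high")
  expect_error(pearson_validity(paired_table(rep(1, 5), a)), "zero variance")
})

test_that("pearson is invariant to positive affine rescaling", {
  set.seed(3)
  a <- rnorm(15); b <- 0.6 * a + rnorm(15, sd = 0.5)
  r0 <- pearson_validity(paired_table(a, b))$r
  expect_equal(pearson_validity(paired_table(3 * a + 7, b))$r, r0,
               tolerance = 1e-12)
  expect_equal(pearson_validity(paired_table(a, 0.1 * b - 2))$r, r0,
               tolerance = 1e-12)
})

test_that("ICC(3,2) matches the explicit hand-ANOVA oracle", {
  # fixed 6x2 table
  s1 <- c(0.92, 1.10, 1.25, 0.85, 1.02, 1.18)
  s2 <- c(0.95, 1.05, 1.30, 0.88, 0.99, 1.22)
  res <- icc_3_2(paired_table(s1, s2))
  oracle <- hand_icc3k(s1, s2)
  expect_equal(res$icc, oracle$icc, tolerance = 1e-10)
  f0 <- oracle$msr / oracle$mse
  expect_equal(res$p_value, pf(f0, 5, 5, lower.tail = FALSE),
               tolerance = 1e-10)
  # and on random tables
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    a <- rnorm(n, 1, 0.3)
    b <- a + rnorm(n, 0, 0.15)
    expect_equal(icc_3_2(paired_table(a, b))$icc, hand_icc3k(a, b)$icc,
                 tolerance = 1e-10)
  }
})

test_that("ICC consistency semantics and bands behave as defined", {
  a <- c(0.9, 1.1, 1.3, 0.8, 1.05, 1.2)
  perfect <- icc_3_2(paired_table(a, a))
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$band, "excellent")
  # a constant session offset does not hurt consistency
  offset <- icc_3_2(paired_table(a, a + 0.2))
  expect_equal(offset$icc, 1, tolerance = 1e-12)
  # ...but it does hurt absolute agreement
  agr <- icc_3_2(paired_table(a, a + 0.2), type = "agreement")
  expect_lt(agr$icc, 1)
  expect_true(agr$ci_low <= agr$icc && agr$icc <= agr$ci_high)
  expect_error(icc_3_2(paired_table(rep(1, 6), rep(1, 6))), "undefined icc")

  expect_equal(icc_band(0.95), "excellent")
  expect_equal(icc_band(0.72), "good")
  expect_equal(icc_band(0.55), "moderate")
  expect_equal(icc_band(0.3), "poor")
})

test_that("ICC confidence interval brackets the estimate and is calibrated", {
  set.seed(101)
  a <- rnorm(10, 1, 0.2); b <- a + rnorm(10, 0, 0.1)
  res <- icc_3_2(paired_table(a, b))
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
  expect_true(res$ci_high <= 1)
})

test_that("bland_altman computes LOA and flags outliers", {
  a <- c(1.0, 1.1, 0.9, 1.2, 1.05)
  same <- bland_altman(paired_table(a, a))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$n_outside, 0L)

  set.seed(9)
  b <- a <- rnorm(20, 1, 0.1)
  b <- b + rnorm(20, 0, 0.05)
  res <- bland_altman(paired_table(a, b))
  d <- a - b
  expect_equal(res$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(res$sd_diff, sd(d), tolerance = 1e-12)
  expect_equal(res$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(res$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(res$n_outside, sum(d < res$loa_low | d > res$loa_high))
  # one outlier out of 20 subjects is the 5% case
  if (res$n_outside == 1) expect_equal(res$pct_outside, 5)
})

test_that("recovered correlation is unbiased at the Fisher-z level", {
  for (rho in c(0.5, 0.7, 0.9)) {
    rs <- vapply(1:1000, function(i) {
      tab <- simulate_paired(rho, n = 20, seed = 1000 + i)
      pearson_validity(tab)$r
    }, 0)
    # E[r] for bivariate normal: back-transformed Fisher expectation
    expected <- tanh(atanh(rho) + rho / (2 * (20 - 1)))
    expect_lt(abs(mean(rs) - expected), 0.03)
  }
})
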