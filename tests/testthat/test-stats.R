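test_that("Bonferroni adjustment is family alpha over m", {
  expect_identical(bonferroni_alpha(0.05, 10), 0.005)
  expect_identical(bonferroni_alpha(0.05, 1), 0.05)
  expect_identical(bonferroni_alpha(0.01, 4), 0.0025)
  expect_error(bonferroni_alpha(0.05, 0), "m")
  expect_error(bonferroni_alpha(1.2, 3), "family_alpha")
})

test_that("group comparison matches the pooled-t hand computation", {
  # g1 = (1,2,3,4), g2 = (3,4,5,6): sp^2 = 5/3, t = -2/sqrt(5/6), df = 6
  f <- data.frame(v = c(1, 2, 3, 4, 3, 4, 5, 6))
  res <- compare_groups(f, rep(c("a", "b"), each = 4))
  expect_identical(res$test, "pooled t")
  expect_equal(res$t, -2.190890, tolerance = 1e-5)
  expect_equal(res$p, 0.070988, tolerance = 1e-5)
  expect_equal(res$cohens_d, -1.549193, tolerance = 1e-5)
})

test_that("identical groups give t = 0, d = 0, p = 1", {
  f <- data.frame(v = rep(c(1.1, 2.2, 3.3, 4.4), 2))
  res <- compare_groups(f, rep(c("a", "b"), each = 4))
  expect_identical(res$t, 0)
  expect_identical(res$p, 1)
  expect_identical(res$cohens_d, 0)
  expect_false(res$significant)
})

test_that("comparison is antisymmetric in group order and column order", {
  set.seed(7)
  f <- data.frame(u = rnorm(40), v = rnorm(40, 1))
  g <- rep(c("a", "b"), each = 20)
  r1 <- compare_groups(f, g)
  g2 <- factor(g, levels = c("b", "a"))
  r2 <- compare_groups(f, g2)
  expect_equal(r2$t, -r1$t, tolerance = 1e-12)
  expect_equal(r2$cohens_d, -r1$cohens_d, tolerance = 1e-12)
  expect_equal(r2$p, r1$p, tolerance = 1e-12)
  r3 <- compare_groups(f[, c("v", "u")], g)
  expect_equal(r3[r3$feature == "u", ]$t, r1[r1$feature == "u", ]$t)
})

test_that("unequal variances trigger Welch across seeds", {
  picks <- vapply(1:10, function(s) {
    set.seed(s)
    f <- data.frame(v = c(rnorm(123, 0.231, 0.689), rnorm(112, -0.802, 1.371)))
    compare_groups(f, rep(c("y", "o"), c(123, 112)))$test
  }, "")
  expect_gte(sum(picks == "Welch t"), 9)
})

test_that("logistic fit satisfies its arithmetic identities", {
  set.seed(5)
  n <- 150
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(0.4 * X$a - 0.8 * X$b))
  fit <- fit_logistic(X, y)
  with(fit$table, {
    expect_equal(odds_ratio, exp(coef), tolerance = 1e-12)
    expect_equal(wald_chi2, (coef / se)^2, tolerance = 1e-12)
    expect_true(all(ci_low < odds_ratio & odds_ratio < ci_high))
  })
  expect_true(fit$accuracy >= 0 && fit$accuracy <= 1)

  # flipping the labels negates every coefficient and inverts the ORs
  flip <- fit_logistic(X, 1 - y)
  expect_equal(flip$table$coef, -fit$table$coef, tolerance = 1e-6)
  expect_equal(flip$table$odds_ratio, 1 / fit$table$odds_ratio,
               tolerance = 1e-6)
})

test_that("a balanced 2x2 table recovers the closed-form odds ratio", {
  # cross-product ratio (20*20)/(10*10) = 4
  x <- rep(c(0, 1), each = 30)
  y <- c(rep(1, 10), rep(0, 20), rep(1, 20), rep(0, 10))
  fit <- fit_logistic(data.frame(x = x), y, hl_groups = 2L)
  expect_equal(fit$table$coef, log(4), tolerance = 1e-6)
})

test_that("degenerate logistic designs are rejected", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(0:1, each = 20)
  expect_error(fit_logistic(data.frame(x = x), y), "separation")
  expect_error(fit_logistic(data.frame(x = rep(1, 40)), y), "constant")
  expect_error(fit_logistic(data.frame(x = rnorm(10)), rep(1, 10)),
               "both classes")
})

test_that("Hosmer-Lemeshow preconditions and calibration behave", {
  expect_error(hosmer_lemeshow(runif(15), rbinom(15, 1, 0.5), 10),
               "at least")
  expect_error(hosmer_lemeshow(c(0, runif(39)), rbinom(40, 1, 0.5), 2),
               "strictly")

  # quick type-I check on fitted models (the full-rate simulation lives in
  # the acceptance suite)
  set.seed(31)
  rej <- vapply(1:60, function(i) {
    x <- rnorm(400)
    y <- rbinom(400, 1, plogis(-0.3 + 0.8 * x))
    p_hat <- fitted(glm(y ~ x, family = binomial()))
    hosmer_lemeshow(p_hat, y)$p < 0.05
  }, TRUE)
  expect_lt(mean(rej), 0.17)

  # grossly miscalibrated probabilities are caught
  set.seed(32)
  x <- rnorm(1000)
  y <- rbinom(1000, 1, plogis(x))
  p_hat <- fitted(glm(y ~ x, family = binomial()))
  expect_lt(hosmer_lemeshow(1 - p_hat, y)$p, 0.001)
})

test_that("Pearson correlation, p-value and power match the closed forms", {
  r1 <- pearson_with_power(1:10, 2 * (1:10) + 1)
  expect_equal(r1$r, 1, tolerance = 1e-12)

  r2 <- pearson_with_power(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r2$r, 0.8, tolerance = 1e-12)
  expect_equal(r2$p, 0.104088, tolerance = 1e-5)

  # r = 0.5 at n = 84: Fisher-z power about 0.9986
  set.seed(2)
  x <- rnorm(84)
  y <- 0.5 / sqrt(1 - 0.25) * x + rnorm(84)
  r_obs <- cor(x, y)
  pw <- pearson_with_power(x, y)
  manual <- pnorm(abs(atanh(r_obs)) * sqrt(81) - qnorm(0.975)) +
    pnorm(-abs(atanh(r_obs)) * sqrt(81) - qnorm(0.975))
  expect_equal(pw$power, manual, tolerance = 1e-12)
  expect_equal(pnorm(atanh(0.5) * sqrt(81) - qnorm(0.975)), 0.998576,
               tolerance = 1e-4)

  expect_error(pearson_with_power(1:3, 1:3), "n >= 4")
  expect_error(pearson_with_power(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("null Pearson p-values are uniform", {
  set.seed(77)
  ps <- vapply(1:2000, function(i)
    pearson_with_power(rnorm(20), rnorm(20))$p, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("adjusted models give unit VIF for orthogonal predictors", {
  n <- 64
  d <- data.frame(
    f = rep(c(-1, 1), each = n / 2),
    age = rep(c(-1, 1), times = n / 2),
    bmi = rep(c(-1, 1, 1, -1), n / 4),
    sbp = rep(c(-1, 1, -1, 1, 1, -1, 1, -1), n / 8),
    diabetes = rep(c(0, 1, 1, 0, 1, 0, 0, 1), n / 8))
  set.seed(3)
  d$bapwv <- 1400 + 50 * d$f + 30 * d$age + rnorm(n, 0, 10)
  fit <- fit_adjusted(d, "bapwv", "f", covariates = c("age", "bmi", "sbp"),
                      binary = character(0))
  expect_true(all(abs(fit$table$vif - 1) < 1e-9))
  expect_gt(fit$adj_r2, 0.9)
  expect_lte(fit$adj_r2, 1)

  d$dup <- d$f
  expect_error(fit_adjusted(d, "bapwv", "f", covariates = c("age", "dup")),
               "collinear")
})

test_that("adjusted models recover known standardized effects", {
  set.seed(11)
  n <- 400
  age <- rnorm(n); bmi <- rnorm(n); sbp <- rnorm(n)
  diabetes <- rbinom(n, 1, 0.2)
  f <- -0.5 * age + sqrt(1 - 0.25) * rnorm(n)   # correlated with age
  bapwv <- 0.6 * age + 0.2 * sbp + 0.1 * bmi + 0.3 * diabetes - 0.25 * f +
    rnorm(n, 0, 0.6)
  d <- data.frame(age, bmi, sbp, diabetes, f, bapwv)
  fit <- fit_adjusted(d, "bapwv", "f")
  row_f <- fit$table[fit$table$predictor == "f", ]
  expect_lt(abs(row_f$beta - (-0.25 * sd(f) / sd(bapwv))), 3 * row_f$se)
  expect_true(all(fit$table$vif >= 1))
  expect_true(all(fit$table$vif < 5))
})
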