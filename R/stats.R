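# The statistics pipeline: Bonferroni-controlled group comparison
# (Kolmogorov-Smirnov normality, Levene's test choosing pooled vs Welch t,
# Cohen's d), exploratory logistic regression with odds ratios and
# Hosmer-Lemeshow calibration, Pearson correlation with post-hoc power,
# and covariate-adjusted linear models with variance inflation factors.

#' Bonferroni-adjusted significance level
#'
#' @param family_alpha family-wise error rate, in (0, 1).
#' @param m number of tests (>= 1).
#' @return `family_alpha / m` (0.05 over ten features gives 0.005).
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  if (!(family_alpha > 0 && family_alpha < 1))
    stop("family_alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  family_alpha / m
}

.cohens_d <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(x1) - mean(x2)) / sp
}

#' Compare feature distributions between two groups
#'
#' For each feature column: Kolmogorov-Smirnov normality per group,
#' Levene's test (centred at the mean) for variance homogeneity deciding
#' pooled vs Welch t at p < 0.05, the two-sided t-test, pooled-SD Cohen's
#' d, and a significance flag at the Bonferroni-adjusted level
#' `family_alpha / ncol(features)`. Group 1 minus group 2 throughout, so
#' swapping groups negates t and d.
#'
#' @param features data.frame of numeric feature columns.
#' @param groups two-level factor/vector of length `nrow(features)`.
#' @param family_alpha family-wise error rate (default 0.05).
#' @return data.frame with one row per feature: group means/SDs, normality
#'   p-values, Levene p, test used, t, p, Cohen's d, significance flag.
#' @export
compare_groups <- function(features, groups, family_alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  lv <- levels(groups)
  if (min(table(groups)) < 3L) stop("each group needs n >= 3")
  alpha_adj <- bonferroni_alpha(family_alpha, ncol(features))
  rows <- lapply(names(features), function(fn) {
    x1 <- features[[fn]][groups == lv[1]]
    x2 <- features[[fn]][groups == lv[2]]
    ks_p <- function(x) {
      if (sd(x) == 0) return(NA_real_)
      suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
    }
    degenerate <- sd(x1) == 0 || sd(x2) == 0
    lev_p <- if (degenerate) 0 else
      car::leveneTest(c(x1, x2), factor(rep(lv, c(length(x1), length(x2)))),
                      center = mean)[1, "Pr(>F)"]
    pooled <- !degenerate && lev_p >= 0.05
    tt <- if (identical(x1, x2) || (degenerate && mean(x1) == mean(x2)))
      list(statistic = c(t = 0), p.value = 1)
    else t.test(x1, x2, var.equal = pooled)
    data.frame(feature = fn, mean1 = mean(x1), sd1 = sd(x1),
               mean2 = mean(x2), sd2 = sd(x2),
               normality_p1 = ks_p(x1), normality_p2 = ks_p(x2),
               levene_p = lev_p,
               test = if (pooled) "pooled t" else "Welch t",
               t = unname(tt$statistic), p = tt$p.value,
               cohens_d = .cohens_d(x1, x2),
               significant = tt$p.value < alpha_adj,
               alpha_adjusted = alpha_adj, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# two-sided normal quantile used for all 95% intervals
.z95 <- 1.959964

#' Binary logistic regression with odds ratios and calibration
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' [stats::glm()]), Wald chi-square `(coef/SE)^2`, odds ratios
#' `exp(coef)` with 95% CI `exp(coef -/+ 1.959964 SE)`, the
#' Hosmer-Lemeshow decile-of-risk calibration test, and apparent
#' (training) accuracy at the 0.5 probability threshold.
#'
#' @param X data.frame or matrix of predictors (no intercept column).
#' @param y binary outcome (0/1 or logical), both classes present.
#' @param hl_groups Hosmer-Lemeshow group count.
#' @return list of class `koro_logistic`: `table` (per-predictor coef, SE,
#'   Wald chi2, p, OR, CI), `intercept`, `hosmer_lemeshow`, `accuracy`,
#'   `fitted`, `model`.
#' @export
fit_logistic <- function(X, y, hl_groups = 10L) {
  X <- as.data.frame(X)
  y <- as.integer(y)
  if (length(unique(y)) != 2L) stop("outcome must contain both classes")
  if (any(vapply(X, function(c) var(as.numeric(c)) == 0, TRUE)))
    stop("constant predictor column")
  df <- cbind(.y = y, X)
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  # |eta| > 25 puts fitted probabilities within 1e-11 of 0/1 at training
  # points, the signature of (quasi-)separation under IRLS
  if (!fit$converged || max(abs(predict(fit, type = "link"))) > 25)
    stop("perfect separation suspected: coefficients diverge")
  if (fit$rank < ncol(X) + 1L) stop("rank-deficient design")
  sm <- summary(fit)$coefficients
  co <- sm[-1, 1]; se <- sm[-1, 2]
  tab <- data.frame(
    predictor = rownames(sm)[-1], coef = co, se = se,
    wald_chi2 = (co / se)^2, p = sm[-1, 4],
    odds_ratio = exp(co),
    ci_low = exp(co - .z95 * se), ci_high = exp(co + .z95 * se),
    row.names = NULL, stringsAsFactors = FALSE)
  fitted_p <- fitted(fit)
  hl <- hosmer_lemeshow(fitted_p, y, hl_groups)
  structure(list(table = tab, intercept = unname(sm[1, 1]),
                 hosmer_lemeshow = hl,
                 accuracy = mean((fitted_p >= 0.5) == (y == 1)),
                 fitted = fitted_p, model = fit),
            class = "koro_logistic")
}

#' Derived logistic columns from a coefficient and its standard error
#'
#' The pure arithmetic layer of [fit_logistic()]: Wald chi-square, odds
#' ratio and 95% CI from `(coef, se)`.
#'
#' @param coef,se coefficient and standard error.
#' @return named list `wald_chi2`, `odds_ratio`, `ci_low`, `ci_high`.
#' @export
logistic_derived <- function(coef, se) {
  list(wald_chi2 = (coef / se)^2, odds_ratio = exp(coef),
       ci_low = exp(coef - .z95 * se), ci_high = exp(coef + .z95 * se))
}

#' Hosmer-Lemeshow calibration test
#'
#' Decile-of-risk grouping of the fitted probabilities (ties kept
#' together), chi-square `sum((O - E)^2 / (E (1 - E/n_g)))` over groups,
#' p-value from the chi-square distribution with `n_groups - 2` degrees of
#' freedom.
#'
#' @param p fitted probabilities in (0, 1).
#' @param y binary outcomes.
#' @param n_groups number of risk groups (default 10).
#' @return list `chi2`, `p`, `n_groups` (groups actually formed).
#' @export
hosmer_lemeshow <- function(p, y, n_groups = 10L) {
  y <- as.integer(y)
  if (length(p) < 2L * n_groups)
    stop("need at least 2 * n_groups observations")
  if (any(p <= 0 | p >= 1)) stop("probabilities must lie strictly in (0, 1)")
  br <- unique(quantile(p, probs = seq(0, 1, length.out = n_groups + 1L)))
  g <- cut(p, breaks = br, include.lowest = TRUE)
  O <- tapply(y, g, sum)
  E <- tapply(p, g, sum)
  n_g <- tapply(y, g, length)
  keep <- !is.na(O)
  O <- O[keep]; E <- E[keep]; n_g <- n_g[keep]
  if (any(E == 0) || any(E == n_g)) stop("risk group with expected count 0")
  chi2 <- sum((O - E)^2 / (E * (1 - E / n_g)))
  df <- length(O) - 2L
  list(chi2 = unname(chi2), p = unname(1 - pchisq(chi2, df)),
       n_groups = length(O))
}

#' Pearson correlation with post-hoc power
#'
#' Product-moment r, two-sided p from the t transform with n - 2 degrees
#' of freedom, and post-hoc power by the Fisher-z normal approximation at
#' the observed r, the stated n and alpha:
#' `power = Phi(|z| sqrt(n-3) - z_{1-alpha/2}) + Phi(-|z| sqrt(n-3) - z_{1-alpha/2})`
#' with `z = atanh(r)`.
#'
#' @param x,y numeric vectors, `n >= 4`, non-degenerate.
#' @param alpha two-sided test level used for the power computation.
#' @return list `r`, `p`, `power`, `n`.
#' @export
pearson_with_power <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 4L) stop("need n >= 4 paired values")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  n <- length(x)
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), n - 2)
  za <- qnorm(1 - alpha / 2)
  zr <- atanh(r) * sqrt(n - 3)
  power <- pnorm(abs(zr) - za) + pnorm(-abs(zr) - za)
  list(r = r, p = p, power = power, n = n)
}

#' Covariate-adjusted linear model with standardized betas and VIF
#'
#' Ordinary least squares of the outcome on one acoustic feature plus
#' covariates. All continuous variables are z-scored (binary covariates
#' left 0/1), so slopes are standardized betas. Per-predictor variance
#' inflation factors come from [car::vif()]; an aliased (perfectly
#' collinear) design raises an error naming the predictor.
#'
#' @param data data.frame containing all variables.
#' @param outcome outcome column name (e.g. measured baPWV).
#' @param feature acoustic feature column name.
#' @param covariates character vector of covariate column names.
#' @param binary names within `covariates` to leave unscaled.
#' @return list of class `koro_adjusted`: `table` (predictor, beta, se, t,
#'   p, vif), `adj_r2`, `outcome`, `feature`, `model`.
#' @export
fit_adjusted <- function(data, outcome, feature,
                         covariates = c("age", "diabetes", "bmi", "sbp"),
                         binary = "diabetes") {
  vars <- c(outcome, feature, covariates)
  missing_v <- setdiff(vars, names(data))
  if (length(missing_v)) stop("missing column(s): ",
                              paste(missing_v, collapse = ", "))
  d <- data[complete.cases(data[vars]), vars]
  if (nrow(d) <= length(vars)) stop("n must exceed number of predictors + 1")
  for (v in vars)
    if (!(v %in% binary)) {
      if (sd(d[[v]]) == 0) stop("zero-variance variable: ", v)
      d[[v]] <- as.numeric(scale(d[[v]]))
    } else d[[v]] <- as.numeric(d[[v]])
  preds <- c(feature, covariates)
  ali <- alias(lm(stats::reformulate(preds, response = outcome), data = d))
  if (!is.null(ali$Complete))
    stop("collinear design: ", paste(rownames(ali$Complete), collapse = ", "))
  fit <- lm(stats::reformulate(preds, response = outcome), data = d)
  sm <- summary(fit)
  vifs <- car::vif(fit)
  tab <- data.frame(predictor = preds,
                    beta = sm$coefficients[preds, 1],
                    se = sm$coefficients[preds, 2],
                    t = sm$coefficients[preds, 3],
                    p = sm$coefficients[preds, 4],
                    vif = vifs[preds],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, adj_r2 = sm$adj.r.squared, outcome = outcome,
                 feature = feature, model = fit),
            class = "koro_adjusted")
}
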