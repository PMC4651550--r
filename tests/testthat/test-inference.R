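test_that("the two-group logistic slope is the log odds ratio", {
  f <- logistic_two_group(16, 80, 14, 36)
  expect_equal(unname(f$coef["slope"]),
               log((14 / 22) / (16 / 64)), tolerance = 1e-12)
  expect_equal(unname(f$se["slope"]),
               sqrt(1 / 16 + 1 / 64 + 1 / 14 + 1 / 22), tolerance = 1e-12)
  # equal proportions in both groups: exactly zero
  expect_equal(unname(logistic_two_group(10, 40, 20, 80)$coef["slope"]), 0)
})

test_that("the closed form agrees with IRLS logistic regression", {
  cases <- list(c(16, 80, 14, 36), c(10, 80, 13, 36), c(3, 23, 14, 36),
                c(7, 19, 22, 31))
  for (cs in cases) {
    f <- logistic_two_group(cs[1], cs[2], cs[3], cs[4])
    y <- c(rep(1, cs[1]), rep(0, cs[2] - cs[1]),
           rep(1, cs[3]), rep(0, cs[4] - cs[3]))
    g <- rep(c(0, 1), c(cs[2], cs[4]))
    glm_fit <- stats::glm(y ~ g, family = stats::binomial())
    expect_lt(abs(unname(f$coef["slope"]) - unname(stats::coef(glm_fit)[2])),
              1e-8)
    expect_lt(abs(unname(f$se["slope"]) -
                    summary(glm_fit)$coefficients[2, 2]), 1e-6)
  }
})

test_that("zero cells are flagged as quasi-separation, not reported silently", {
  f <- logistic_two_group(0, 23, 13, 36, continuity = TRUE)
  expect_true(any(grepl("quasi-separation", f$notes)))
  expect_true(is.infinite(unname(f$coef["slope"])))
  expect_true(any(grepl("continuity-corrected", f$notes)))
  expect_error(logistic_two_group(0, 10, 0, 10), "both groups")
})

test_that("the Wald test holds its nominal size", {
  set.seed(55)
  p0 <- 0.25; n1 <- 80; n2 <- 36
  reject <- 0; done <- 0
  for (r in 1:5000) {
    k1 <- stats::rbinom(1, n1, p0); k2 <- stats::rbinom(1, n2, p0)
    if (k1 %in% c(0, n1) || k2 %in% c(0, n2)) next
    f <- logistic_two_group(k1, n1, k2, n2)
    done <- done + 1
    reject <- reject + (f$p <= 0.05)
  }
  expect_gte(reject / done, 0.03)
  expect_lte(reject / done, 0.07)
})

test_that("summary ANOVA equals the squared pooled t and handles edges", {
  f <- anova_from_summary(32.7, 21.1, 16, 62.6, 20.2, 14)
  t2 <- ((62.6 - 32.7) /
           sqrt((((16 - 1) * 21.1^2 + (14 - 1) * 20.2^2) / 28) *
                  (1 / 16 + 1 / 14)))^2
  expect_equal(f$statistic, t2, tolerance = 1e-12)
  expect_equal(f$df, c(1, 28))
  # identical groups
  f0 <- anova_from_summary(10, 2, 5, 10, 2, 5)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p, 1)
  # zero pooled variance with a difference: explicit infinity
  finf <- anova_from_summary(1, 0, 5, 2, 0, 5)
  expect_true(is.infinite(finf$statistic))
})

test_that("linear regression matches hand least squares", {
  # by hand: Sxx = 2, Sxy = 4 -> slope 2; SSreg = 8, SST = 26/3 -> R2 = 12/13
  f <- linear_regression(c(0, 1, 2), c(0, 1, 4))
  expect_equal(unname(f$coef["slope"]), 2, tolerance = 1e-12)
  expect_equal(f$r2, 12 / 13, tolerance = 1e-12)
  # collinear points (perfect-fit warning from summary.lm is the point)
  expect_equal(suppressWarnings(linear_regression(1:5, 2 * (1:5) + 3))$r2, 1)
  expect_error(linear_regression(rep(1, 5), 1:5), "constant")
})

test_that("a null slope is called null at the 3-SE level", {
  set.seed(77)
  ok <- 0
  for (r in 1:200) {
    x <- stats::rnorm(1000); y <- stats::rnorm(1000)
    f <- linear_regression(x, y)
    ok <- ok + (abs(f$coef["slope"]) <= 3 * f$se["slope"])
  }
  expect_gte(ok / 200, 0.99)
})

test_that("conditional logistic matches grid maximization of the exact likelihood", {
  set.seed(91)
  for (r in 1:3) {
    strata <- do.call(rbind, lapply(1:3, function(s) {
      x <- stats::rnorm(4)
      p <- exp(0.8 * x); p <- p / sum(p)
      data.frame(stratum = s, segment_id = paste0(s, "_", 1:4),
                 used = as.integer(seq_len(4) ==
                                     sample(4, 1, prob = p)), x = x)
    }))
    fit <- conditional_logistic(strata, "x")
    bhat_grid <- grid_max_clogit_1d(strata, "x", -6, 6)
    expect_lt(abs(unname(fit$coef["x"]) - bhat_grid), 1e-6)
    expect_equal(fit$loglik, cond_loglik_1d(unname(fit$coef["x"]),
                                            strata, "x"),
                 tolerance = 1e-8)
    expect_equal(fit$aic, 2 - 2 * fit$loglik, tolerance = 1e-10)
  }
})

test_that("within-stratum constant covariates are unidentifiable", {
  strata <- do.call(rbind, lapply(1:4, function(s)
    data.frame(stratum = s, used = as.integer(seq_len(3) == 1),
               x = s * 1.0)))
  f <- conditional_logistic(strata, "x")
  expect_true(any(grepl("unidentifiable", f$notes)))
  expect_null(f$coef)
})

test_that("matched pairs reduce to logistic regression on differences", {
  set.seed(17)
  n <- 60
  dx <- stats::rnorm(n)
  pick <- stats::rbinom(n, 1, stats::plogis(0.9 * dx))
  strata <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(stratum = i, used = c(pick[i], 1 - pick[i]),
               x = c(dx[i], 0))))
  fit <- conditional_logistic(strata, "x")
  glm_fit <- stats::glm(pick ~ 0 + dx, family = stats::binomial())
  expect_lt(abs(unname(fit$coef["x"]) - unname(stats::coef(glm_fit))), 1e-4)
})

test_that("AIC ranking prefers parsimony on ties and orders by AIC", {
  f1 <- polarland:::new_fit_result("a", coef = c(b = 1), loglik = -10,
                                   aic = 2 * 1 - 2 * (-10), n = 50)
  f2 <- polarland:::new_fit_result("b", coef = c(b = 1, c = 2),
                                   loglik = -10, aic = 2 * 2 - 2 * (-10),
                                   n = 50)
  tab <- aic_compare(list(one = f1, two = f2))
  expect_equal(tab$model[1], "one")
  expect_equal(tab$delta_aic, c(0, 2))
  tab2 <- aic_compare(list(a = f1, b = f1))
  expect_true(all(tab2$delta_aic == 0))
  f3 <- f2; f3$n <- 40
  expect_error(aic_compare(list(a = f1, b = f3)), "different data sizes")
})

test_that("chi-squared contingency matches the direct Pearson formula", {
  # proportional table: exactly zero
  expect_equal(chi2_contingency(matrix(c(10, 20, 30, 60), 2))$statistic, 0)
  f <- chi2_contingency(matrix(c(10, 10, 10, 10), 2))
  expect_equal(f$statistic, 0)
  expect_equal(f$p, 1)
  # direct formula on a 2x2
  tab <- matrix(c(20, 5, 5, 20), 2)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pearson <- sum((tab - exp_tab)^2 / exp_tab)
  f2 <- chi2_contingency(tab)
  expect_lt(abs(f2$statistic - pearson), 1e-10)
  expect_equal(f2$df, 1)
  expect_error(chi2_contingency(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("retreat-driven selection is recovered and beats the wrong model", {
  set.seed(23)
  wins <- 0
  for (r in 1:8) {
    n_seg <- 40
    retreat <- stats::runif(n_seg, 140, 280)
    ret <- 420 - 0.4 * retreat + stats::rnorm(n_seg, 0, 25) # weakly linked
    strata <- do.call(rbind, lapply(1:60, function(s) {
      p <- exp(0.02 * retreat); p <- p / sum(p)
      data.frame(stratum = s, used = as.integer(seq_len(n_seg) ==
                                                  sample(n_seg, 1, prob = p)),
                 retreat_doy = retreat, return_doy = ret)
    }))
    f_r <- conditional_logistic(strata, "retreat_doy")
    f_b <- conditional_logistic(strata, "return_doy")
    wins <- wins + (f_r$aic < f_b$aic)
  }
  expect_gte(wins, 7) # >= 80 percent of replicates
})
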