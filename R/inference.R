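#' Statistical comparisons between study periods
#'
#' Closed-form two-group procedures that work directly from counts and
#' summary statistics (so published tables can be re-analyzed), plus
#' conditional logistic resource selection, AIC ranking and contingency
#' tables. All tests are Wald-type at a 0.05 threshold, with no
#' multiplicity correction.
#'
#' @name inference
NULL

new_fit_result <- function(label, coef = NULL, se = NULL, statistic = NA,
                           stat_name = NA, df = NA, p = NA, r2 = NA,
                           loglik = NA, aic = NA, n = NA, notes = character()) {
  out <- list(label = label, coef = coef, se = se, statistic = statistic,
              stat_name = stat_name, df = df, p = p, r2 = r2,
              loglik = loglik, aic = aic, n = n, notes = notes)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:", x$label, "\n")
  if (!is.null(x$coef)) {
    for (i in seq_along(x$coef))
      cat(sprintf("  %s = %.4g (SE %.4g)\n",
                  names(x$coef)[i] %||% paste0("b", i),
                  x$coef[i], x$se[i]))
  }
  if (!is.na(x$statistic))
    cat(sprintf("  %s(%s) = %.4g, p = %.4g\n", x$stat_name,
                paste(x$df, collapse = ","), x$statistic, x$p))
  if (!is.na(x$r2)) cat(sprintf("  R^2 = %.4g\n", x$r2))
  if (!is.na(x$aic)) cat(sprintf("  loglik = %.4g, AIC = %.4g\n",
                                 x$loglik, x$aic))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Two-group logistic regression from counts
#'
#' The slope of a binary logistic regression with a single two-level
#' predictor is the log odds ratio; its Wald SE has the classical
#' closed form `sqrt(1/k1 + 1/(n1-k1) + 1/k2 + 1/(n2-k2))`. A zero cell
#' makes the MLE infinite (quasi-separation): the estimate is reported as
#' non-finite with a warning note, and a continuity-corrected (half
#' observation added to every cell) estimate is available behind a flag.
#'
#' @param k1,n1 successes and trials in group 1 (reference).
#' @param k2,n2 successes and trials in group 2.
#' @param continuity also report the +0.5 continuity-corrected estimate
#'   when a cell is zero.
#' @return a `fit_result` with the slope (log odds ratio), SE and
#'   two-sided Wald p-value.
#' @export
logistic_two_group <- function(k1, n1, k2, n2, continuity = FALSE) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2, n1 > 0, n2 > 0)
  cells <- c(k1, n1 - k1, k2, n2 - k2)
  if ((k1 == 0 && k2 == 0) || (k1 == n1 && k2 == n2))
    stop("a margin is zero in both groups; the odds ratio is undefined")
  notes <- character()
  if (any(cells == 0)) {
    notes <- "zero cell: quasi-separation, Wald estimate is not finite"
    slope <- log((k2 / (n2 - k2)) / (k1 / (n1 - k1))) # +-Inf
    se <- Inf; p <- NA_real_
    if (continuity) {
      cc <- cells + 0.5
      slope_cc <- log((cc[3] / cc[4]) / (cc[1] / cc[2]))
      se_cc <- sqrt(sum(1 / cc))
      notes <- c(notes, sprintf(
        "continuity-corrected slope %.3f (SE %.3f)", slope_cc, se_cc))
    }
  } else {
    slope <- log((k2 / (n2 - k2)) / (k1 / (n1 - k1)))
    se <- sqrt(1 / k1 + 1 / (n1 - k1) + 1 / k2 + 1 / (n2 - k2))
    p <- 2 * stats::pnorm(-abs(slope / se))
  }
  new_fit_result("two-group logistic (log odds ratio)",
                 coef = c(slope = slope), se = c(slope = se),
                 statistic = (slope / se)^2, stat_name = "Wald chi2",
                 df = 1, p = p, n = n1 + n2, notes = notes)
}

#' One-way two-group ANOVA from summary statistics
#'
#' Pooled-variance F test identical to the square of the equal-variance
#' two-sample t test. When the source reports the mean difference at
#' higher precision than the group means, it can be supplied via `diff`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @param diff optional mean difference overriding `mean2 - mean1`.
#' @return a `fit_result` with the difference, its pooled SE, F on
#'   (1, n1+n2-2) df and the p-value.
#' @export
anova_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, diff = NULL) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- if (is.null(diff)) mean2 - mean1 else diff
  notes <- character()
  if (se == 0 && d != 0) {
    f <- Inf; p <- 0
    notes <- "zero pooled variance with nonzero difference: F is infinite"
  } else if (se == 0) {
    f <- 0; p <- 1
  } else {
    f <- (d / se)^2
    p <- stats::pf(f, 1, n1 + n2 - 2, lower.tail = FALSE)
  }
  new_fit_result("two-group ANOVA from summaries",
                 coef = c(diff = d), se = c(diff = se),
                 statistic = f, stat_name = "F", df = c(1, n1 + n2 - 2),
                 p = p, n = n1 + n2, notes = notes)
}

#' Simple linear regression
#'
#' Least squares via [stats::lm()]; reported as slope, intercept, R^2 and
#' the two-sided slope p-value.
#'
#' @param x,y numeric vectors (>= 3 points, x not constant).
#' @return a `fit_result`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("x is constant; slope is undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  new_fit_result("linear regression",
                 coef = c(intercept = unname(stats::coef(fit)[1]),
                          slope = unname(stats::coef(fit)[2])),
                 se = c(intercept = sm$coefficients[1, 2],
                        slope = sm$coefficients[2, 2]),
                 statistic = sm$coefficients[2, 3]^2, stat_name = "F",
                 df = c(1, fit$df.residual),
                 p = sm$coefficients[2, 4], r2 = sm$r.squared,
                 loglik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit), n = length(x))
}

#' Build use-availability strata for conditional logistic regression
#'
#' One stratum per bear-year: the used coastal segment plus every
#' available segment, with the segment's ice covariate, the period
#' indicator and their interaction.
#'
#' @param used data frame with one row per bear-year: `stratum`,
#'   `segment_id`, `period` (0/1 indicator for the recent period).
#' @param availability data frame of available segments per stratum:
#'   `stratum`, `segment_id`, covariate columns (e.g. `retreat_doy`).
#' @param covariate name of the ice covariate column.
#' @return data frame with `stratum`, `used`, covariate, `period` and the
#'   interaction column `<covariate>:period`.
#' @export
build_strata <- function(used, availability, covariate = "retreat_doy") {
  stopifnot(all(used$stratum %in% availability$stratum))
  out <- do.call(rbind, lapply(seq_len(nrow(used)), function(i) {
    av <- availability[availability$stratum == used$stratum[i], ]
    av$used <- as.integer(av$segment_id == used$segment_id[i])
    if (sum(av$used) != 1)
      stop("stratum ", used$stratum[i],
           " must contain its used segment exactly once")
    av$period <- used$period[i]
    av
  }))
  out$interaction <- out[[covariate]] * out$period
  out
}

#' Conditional logistic regression on use-availability strata
#'
#' Maximizes the stratified conditional likelihood (each stratum
#' contributes the probability of its used record against all its
#' alternatives) via the Cox partial-likelihood equivalence, with Wald SEs
#' from the observed information. Covariates constant within every stratum
#' are unidentifiable and flagged.
#'
#' @param strata data frame with `stratum`, `used` (exactly one 1 per
#'   stratum) and covariate columns.
#' @param covariates character vector of covariate column names.
#' @return a `fit_result` with coefficients, SEs, log-likelihood and AIC.
#' @export
conditional_logistic <- function(strata, covariates) {
  stopifnot(all(c("stratum", "used") %in% names(strata)),
            all(covariates %in% names(strata)))
  per_str <- tapply(strata$used, strata$stratum, sum)
  if (any(per_str != 1))
    stop("every stratum needs exactly one used record")
  # identifiability: a covariate must vary within at least one stratum
  varies <- vapply(covariates, function(v) {
    any(tapply(strata[[v]], strata$stratum,
               function(z) length(unique(z)) > 1))
  }, logical(1))
  if (any(!varies)) {
    return(new_fit_result(
      "conditional logistic regression",
      notes = paste0("unidentifiable (constant within all strata): ",
                     paste(covariates[!varies], collapse = ", "))))
  }
  strata$.time <- 1
  f <- stats::as.formula(paste(
    "survival::Surv(.time, used) ~",
    paste(sprintf("`%s`", covariates), collapse = " + "),
    "+ survival::strata(stratum)"))
  fit <- survival::coxph(f, data = strata, method = "exact")
  sm <- summary(fit)
  k <- length(stats::coef(fit))
  ll <- fit$loglik[2]
  new_fit_result("conditional logistic regression",
                 coef = stats::setNames(stats::coef(fit), covariates),
                 se = stats::setNames(sm$coefficients[, "se(coef)"],
                                      covariates),
                 statistic = sm$waldtest["test"], stat_name = "Wald chi2",
                 df = k, p = sm$waldtest["pvalue"],
                 loglik = ll, aic = 2 * k - 2 * ll,
                 n = length(unique(strata$stratum)))
}

#' Rank fitted models by AIC
#'
#' @param fits named list of `fit_result`s sharing the same data.
#' @return data frame `model`, `loglik`, `k`, `aic`, `delta_aic`, ranked
#'   best first; ties broken by fewer parameters.
#' @export
aic_compare <- function(fits) {
  stopifnot(length(fits) >= 1)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns[!is.na(ns)])) > 1)
    stop("fits were computed on different data sizes")
  tab <- data.frame(
    model = names(fits) %||% paste0("m", seq_along(fits)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    k = vapply(fits, function(f) length(f$coef), numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)))
  tab <- tab[order(tab$aic, tab$k), ]
  tab$delta_aic <- tab$aic - min(tab$aic)
  rownames(tab) <- NULL
  tab
}

#' Pearson chi-squared contingency-table test
#'
#' @param table non-negative integer matrix with positive margins.
#' @return a `fit_result` with the chi-squared statistic on
#'   `(r-1)(c-1)` df (no continuity correction).
#' @export
chi2_contingency <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new_fit_result("Pearson chi-squared contingency test",
                 statistic = unname(ct$statistic), stat_name = "chi2",
                 df = unname(ct$parameter), p = ct$p.value,
                 n = sum(table))
}
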