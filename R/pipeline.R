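#' End-to-end synthetic study pipeline
#'
#' [run_study()] chains every stage — simulate, screen, truncate dropped
#' collars, fit and interpolate movement, classify land use, detect
#' denning, compute ice phenology, and run the between-period statistics —
#' into a single deterministic report. [reproduce_printed_stats()] runs
#' the same inference procedures directly on a table of published counts
#' and summary statistics.
#'
#' @name pipeline
NULL

#' Run the full synthetic study
#'
#' @param config a `sim_config`, or the path of a JSON file whose fields
#'   are [sim_config()] arguments.
#' @param seed optional seed overriding `config$seed`.
#' @return a `study_report` list: per-bear summaries, denning events, ice
#'   phenology tables, and every fitted comparison.
#' @export
run_study <- function(config = sim_config(), seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  study <- simulate_study(config)
  coast <- study$coast

  stages <- lapply(study$tracks, function(tr) {
    tr <- truncate_dropped_collar(tr)
    flt <- filter_track(tr)
    tr2 <- flt$track
    res <- list(track = tr, filtered = tr2, decisions = flt$decisions,
                fit = NULL, path = NULL, summary = NULL, pct = NA_real_)
    fit <- try(fit_ctcrw(tr2), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) return(res)
    res$fit <- fit
    res$path <- predict_daily(fit, min(tr2$fixes$time), max(tr2$fixes$time))
    res$summary <- try(summarize_bear_year(res$path, coast), silent = TRUE)
    if (inherits(res$summary, "try-error")) res$summary <- NULL
    pct <- try(percent_year_on_land(res$path, coast), silent = TRUE)
    if (!inherits(pct, "try-error")) res$pct <- pct
    res
  })

  summaries <- do.call(rbind, lapply(seq_along(stages), function(i) {
    st <- stages[[i]]; tr <- study$tracks[[i]]
    s <- st$summary
    bad <- is.null(s) || isTRUE(s$indeterminate)
    data.frame(
      bear_id = tr$bear_id, period = tr$period, year = tr$truth$year,
      capture_site = tr$capture_site,
      modeled = !is.null(st$fit),
      indeterminate = bad,
      days_on_land = if (bad) NA_real_ else s$days_on_land,
      used_gt7 = if (bad) NA else s$used_gt7,
      used_gt21 = if (bad) NA else s$used_gt21,
      arrival_doy = if (bad) NA_real_ else s$arrival_doy,
      departure_doy = if (bad) NA_real_ else s$departure_doy,
      stayed_into_winter = if (bad) NA else s$stayed_into_winter,
      land_mass = if (bad) NA_character_ else s$land_mass,
      eligible = if (bad) FALSE else s$eligible,
      pct_on_land = st$pct)
  }))

  # denning: provisional robust baseline over all bears, detect, then a
  # clean mean/SD baseline from bears without provisional events
  temps <- lapply(study$tracks, function(tr) tr$temperature)
  base0 <- build_baseline(temps, robust = TRUE)
  # the provisional pass uses a lower threshold because the mixed-cohort
  # MAD is inflated by the denning minority; sustained 35-day runs are
  # still vanishingly unlikely for non-denners
  prov <- vapply(temps, function(tm)
    nrow(detect_denning(tm, base0, k = 1)) > 0, logical(1))
  clean <- temps[!prov]
  baseline <- if (length(clean) >= 3) build_baseline(clean) else base0
  den_events <- lapply(seq_along(study$tracks), function(i) {
    ev <- detect_denning(temps[[i]], baseline)
    if (!nrow(ev)) return(NULL)
    ev <- ev[which.max(ev$duration), ]
    ev$bear_id <- study$tracks[[i]]$bear_id
    ev$period <- study$tracks[[i]]$period
    ev$substrate <- assign_substrate(ev, stages[[i]]$filtered, coast)
    ev
  })
  denning <- do.call(rbind, den_events)
  if (is.null(denning)) {
    summaries$denned <- FALSE
    summaries$den_substrate <- NA_character_
  } else {
    summaries$denned <- summaries$bear_id %in% denning$bear_id
    summaries$den_substrate <- denning$substrate[
      match(summaries$bear_id, denning$bear_id)]
  }

  pheno <- lapply(study$ice, function(stk) segment_phenology(stk, coast))
  shelf <- vapply(study$ice, shelf_ice_fraction, numeric(1))

  el <- summaries[summaries$eligible, ]
  n1 <- sum(el$period == 1); n2 <- sum(el$period == 2)
  k7 <- c(sum(el$used_gt7[el$period == 1]), sum(el$used_gt7[el$period == 2]))
  k21 <- c(sum(el$used_gt21[el$period == 1]), sum(el$used_gt21[el$period == 2]))
  safe <- function(expr) {
    out <- try(expr, silent = TRUE)
    if (inherits(out, "try-error")) NULL else out
  }
  two_group <- function(df, col) {
    g1 <- df[[col]][df$period == 1]; g2 <- df[[col]][df$period == 2]
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    if (length(g1) < 2 || length(g2) < 2) return(NULL)
    anova_from_summary(mean(g1), stats::sd(g1), length(g1),
                       mean(g2), stats::sd(g2), length(g2))
  }
  users <- el[!is.na(el$used_gt7) & el$used_gt7, ]
  nonstay <- users[!is.na(users$departure_doy) &
                     !isTRUE(users$stayed_into_winter), ]
  stats_list <- list(
    logistic_gt7 = safe(logistic_two_group(k7[1], n1, k7[2], n2)),
    logistic_gt21 = safe(logistic_two_group(k21[1], n1, k21[2], n2)),
    anova_days_gt7 = two_group(users, "days_on_land"),
    anova_arrival = two_group(users, "arrival_doy"),
    anova_departure = two_group(nonstay, "departure_doy"),
    anova_pct_locations = two_group(summaries, "pct_on_land"))

  # regression: per-year mean land days of >7-day users vs shelf coverage
  yr <- sort(unique(users$year))
  reg_tab <- data.frame(
    year = yr,
    mean_days = vapply(yr, function(y)
      mean(users$days_on_land[users$year == y]), numeric(1)),
    shelf_frac = shelf[as.character(yr)],
    n_bears = vapply(yr, function(y) sum(users$year == y), numeric(1)))
  stats_list$regression_days_vs_ice <- if (nrow(reg_tab) >= 3 &&
                                           stats::sd(reg_tab$shelf_frac) > 0)
    linear_regression(reg_tab$shelf_frac, reg_tab$mean_days) else NULL

  # resource selection: summering bears (>7 land days, gaps allowed)
  rs <- summaries[!summaries$indeterminate & !is.na(summaries$used_gt7) &
                    summaries$used_gt7, ]
  sel_fits <- safe(fit_selection_models(rs, stages, study, pheno, coast))

  # capture location vs summering location
  chi <- NULL
  su <- summaries[!is.na(summaries$land_mass), ]
  if (nrow(su) >= 5) {
    tab <- table(su$capture_site, su$land_mass)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (all(dim(tab) >= 2)) chi <- safe(chi2_contingency(tab))
  }

  report <- list(config = config, summaries = summaries, denning = denning,
                 phenology = pheno, shelf_fraction = shelf,
                 regression_table = reg_tab,
                 counts = list(n_eligible = c(n1, n2), k_gt7 = k7,
                               k_gt21 = k21,
                               n_excluded_gaps = sum(!summaries$eligible),
                               n_indeterminate = sum(summaries$indeterminate)),
                 stats = stats_list, selection = sel_fits,
                 capture_vs_summering = chi,
                 truth = study$truth)
  class(report) <- "study_report"
  report
}

# conditional-logistic use-availability fits (retreat vs return models)
# for summering bear-years; used segment = nearest to the bear's mean
# on-land position
fit_selection_models <- function(rs, stages, study, pheno, coast) {
  if (nrow(rs) < 3) return(NULL)
  used <- NULL; avail <- NULL
  for (i in seq_len(nrow(rs))) {
    bid <- rs$bear_id[i]
    j <- which(vapply(study$tracks, function(tr) tr$bear_id == bid,
                      logical(1)))
    path <- stages[[j]]$path
    w <- path$time >= AUG1 & path$time <= OCT31 & !path$gap_excluded
    onl <- w & classify_on_land(path$x, path$y, coast)
    if (!any(onl)) next
    cx <- mean(path$x[onl]); cy <- mean(path$y[onl])
    segs <- pheno[[as.character(rs$year[i])]]
    k <- which.min((segs$x - cx)^2 + (segs$y - cy)^2)
    used <- rbind(used, data.frame(
      stratum = bid, segment_id = segs$segment_id[k],
      period = rs$period[i] - 1L))
    av <- segs[, c("segment_id", "retreat_doy", "return_doy")]
    av$stratum <- bid
    avail <- rbind(avail, av)
  }
  if (is.null(used) || nrow(used) < 3) return(NULL)
  st_r <- build_strata(used, avail, covariate = "retreat_doy")
  st_b <- build_strata(used, avail, covariate = "return_doy")
  fit_r <- conditional_logistic(st_r, c("retreat_doy", "interaction"))
  fit_b <- conditional_logistic(st_b, c("return_doy", "interaction"))
  ranking <- try(aic_compare(list(retreat = fit_r, return = fit_b)),
                 silent = TRUE)
  list(retreat = fit_r, return = fit_b,
       aic = if (inherits(ranking, "try-error")) NULL else ranking)
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report (seed", x$config$seed, ")\n")
  n <- x$counts
  cat(sprintf("  eligible bear-years: %d + %d (%d excluded for data gaps)\n",
              n$n_eligible[1], n$n_eligible[2], n$n_excluded_gaps))
  cat(sprintf("  >7-day land use: %d/%d (%.1f%%) vs %d/%d (%.1f%%)\n",
              n$k_gt7[1], n$n_eligible[1],
              100 * n$k_gt7[1] / max(n$n_eligible[1], 1),
              n$k_gt7[2], n$n_eligible[2],
              100 * n$k_gt7[2] / max(n$n_eligible[2], 1)))
  cat(sprintf("  >21-day land use: %d/%d vs %d/%d\n",
              n$k_gt21[1], n$n_eligible[1], n$k_gt21[2], n$n_eligible[2]))
  if (!is.null(x$denning))
    cat("  denning events:", nrow(x$denning), "(",
        sum(x$denning$substrate == "land"), "on land )\n")
  for (nm in names(x$stats)) if (!is.null(x$stats[[nm]])) {
    f <- x$stats[[nm]]
    cat(sprintf("  %s: %s = %.3g (p = %.3g)\n", nm,
                if (!is.na(f$stat_name)) f$stat_name else "est",
                f$statistic, f$p))
  }
  invisible(x)
}

#' Recompute published statistics from a printed-summary table
#'
#' Each row of the table holds the counts or summary statistics a study
#' printed for one comparison; the corresponding closed-form procedure is
#' re-run on them. Expected columns: `label`, `kind` (`logistic` or
#' `anova`), `k1,n1,k2,n2` for logistic rows, `mean1,sd1,sn1,mean2,sd2,sn2`
#' and optional `diff` for ANOVA rows (a printed mean difference, reported
#' at higher precision than the group means, takes precedence).
#'
#' @param table a data frame or the path of a CSV file. The package ships
#'   a ready-made table of the motivating study's printed summaries at
#'   `system.file("extdata", "printed_summaries.csv", package = "polarland")`.
#' @return list of `fit_result`s keyed by label, with a `tidy` data-frame
#'   attribute (`label`, `estimate`, `se`, `statistic`, `p`).
#' @export
reproduce_printed_stats <- function(table) {
  if (is.character(table)) table <- utils::read.csv(table)
  stopifnot(is.data.frame(table))
  if (!nrow(table)) return(structure(list(), tidy = data.frame()))
  stopifnot(all(c("label", "kind") %in% names(table)))
  fits <- list()
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    fits[[r$label]] <- switch(
      as.character(r$kind),
      logistic = logistic_two_group(r$k1, r$n1, r$k2, r$n2,
                                    continuity = TRUE),
      anova = anova_from_summary(r$mean1, r$sd1, r$sn1,
                                 r$mean2, r$sd2, r$sn2,
                                 diff = if (!is.null(r$diff) &&
                                            !is.na(r$diff)) r$diff else NULL),
      stop("unknown row kind: ", r$kind))
  }
  tidy <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(label = nm, estimate = unname(f$coef[1]),
               se = unname(f$se[1]), statistic = f$statistic,
               stat_name = f$stat_name, p = f$p)
  }))
  structure(fits, tidy = tidy)
}
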