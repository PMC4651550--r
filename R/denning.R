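#' Denning detection from collar temperature
#'
#' A denning bear's collar reads warmer than ambient for weeks at a time.
#' Events are detected as sustained exceedances of a weekly baseline built
#' from non-denning bears: a day is elevated when its temperature exceeds
#' the baseline week mean by more than `k` baseline SDs, and a denning
#' event is a run of elevated days of at least `min_days`, tolerating short
#' interruptions, intersecting the winter window (1 Oct - 31 May).
#'
#' @name denning
NULL

#' Build a weekly temperature baseline from non-denning bears
#'
#' @param series list of data frames (`time` in study days, `temp`).
#' @param min_series minimum number of series contributing to every winter
#'   week (default 3).
#' @param robust use per-week median and MAD instead of mean and SD —
#'   useful for a provisional baseline over a mixed cohort in which a
#'   minority of series contain denning bouts.
#' @return data frame `week`, `mean`, `sd`, `n_series`.
#' @export
build_baseline <- function(series, min_series = 3, robust = FALSE) {
  stopifnot(is.list(series), length(series) >= 1)
  if (length(series) < min_series)
    stop("need at least ", min_series, " non-denning series")
  all <- do.call(rbind, lapply(seq_along(series), function(i) {
    s <- series[[i]]
    data.frame(id = i, week = week_of_doy(ordinal_date(s$time)),
               temp = s$temp)
  }))
  agg <- lapply(split(all, all$week), function(d) {
    data.frame(week = d$week[1],
               mean = if (robust) stats::median(d$temp) else mean(d$temp),
               sd = if (robust) stats::mad(d$temp) else stats::sd(d$temp),
               n_series = length(unique(d$id)))
  })
  out <- do.call(rbind, agg)
  winter <- c(week_of_doy(OCT1):53, 1:week_of_doy(151))
  missing <- setdiff(winter, out$week[out$n_series >= min_series])
  if (length(missing))
    stop("winter weeks with < ", min_series, " contributing series: ",
         paste(missing, collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Detect denning events in a collar temperature series
#'
#' @param temps data frame `time` (study days), `temp`.
#' @param baseline weekly baseline from [build_baseline()].
#' @param k exceedance threshold in baseline SDs (default 2).
#' @param min_days minimum event duration in days (default 35).
#' @param max_interruption_days elevated runs separated by at most this
#'   many non-elevated days are merged (default 2).
#' @param window winter window in study days (default 1 Oct - 31 May).
#' @return data frame of events: `start`, `end`, `duration`; zero rows when
#'   none qualify.
#' @export
detect_denning <- function(temps, baseline, k = 2, min_days = 35,
                           max_interruption_days = 2,
                           window = c(OCT1, MAY31_NEXT)) {
  stopifnot(all(c("time", "temp") %in% names(temps)))
  wk <- week_of_doy(ordinal_date(temps$time))
  idx <- match(wk, baseline$week)
  thr <- baseline$mean[idx] + k * baseline$sd[idx]
  elevated <- !is.na(thr) & temps$temp > thr
  # merge runs separated by short interruptions
  r <- rle(elevated)
  short_gap <- !r$values & r$lengths <= max_interruption_days
  inner <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
  r$values[short_gap & inner] <- TRUE
  merged <- inverse.rle(r)
  r2 <- rle(merged)
  ends <- cumsum(r2$lengths); starts <- ends - r2$lengths + 1
  bi <- which(r2$values)
  out <- data.frame(start = numeric(0), end = numeric(0),
                    duration = numeric(0))
  for (b in bi) {
    s <- temps$time[starts[b]]; e <- temps$time[ends[b]]
    # clip to the winter window
    s2 <- max(s, window[1]); e2 <- min(e, window[2])
    if (s2 > e2) next
    if (e2 - s2 + 1 >= min_days)
      out <- rbind(out, data.frame(start = s2, end = e2,
                                   duration = e2 - s2 + 1))
  }
  rownames(out) <- NULL
  out
}

#' Assign den substrate from observed fixes around an event
#'
#' Den structures attenuate transmissions, so interpolated positions are
#' unreliable during denning; substrate is judged from observed fixes only,
#' within a small tolerance around the event boundaries. Land if any such
#' fix classifies on land; ice if fixes exist and none do; unknown without
#' fixes.
#'
#' @param event one event row from [detect_denning()] (`start`, `end`).
#' @param track the bear's `bear_track` (raw or filtered).
#' @param coast a `coast_geometry`.
#' @param tol_days boundary tolerance in days (default 3).
#' @return `"land"`, `"ice"` or `"unknown"`.
#' @export
assign_substrate <- function(event, track, coast, tol_days = 3) {
  fx <- track$fixes
  sel <- fx$time >= event$start - tol_days & fx$time <= event$end + tol_days
  if (!any(sel)) return("unknown")
  if (any(classify_on_land(fx$x[sel], fx$y[sel], coast))) "land" else "ice"
}
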