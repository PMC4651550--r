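#' Per-bear-year land-use metrics
#'
#' Daily predicted positions are classified against the buffered coastline;
#' the summering window is 1 Aug - 31 Oct (92 days). Land days need not be
#' consecutive. Days flagged gap-excluded never count as land days, and a
#' bear-year with any gap-excluded day inside the window is flagged
#' ineligible for between-period comparisons (its habitat use there cannot
#' be determined). Arrival is the start of the longest on-land bout
#' beginning inside the window; departure is the end of the last bout that
#' ends by 31 Dec — a bear still on land on 31 Dec (staying into denning)
#' gets no departure date and is flagged.
#'
#' @param path a `predicted_path` from [predict_daily()].
#' @param coast a `coast_geometry`.
#' @param window `c(first, last)` ordinal dates of the summering window.
#' @return a `bear_year_summary` list.
#' @export
summarize_bear_year <- function(path, coast, window = c(AUG1, OCT31)) {
  stopifnot(inherits(path, "predicted_path"))
  w <- path$time >= window[1] & path$time <= window[2]
  if (!any(w)) stop("path does not cover the summering window")
  covered <- sum(w) == window[2] - window[1] + 1
  usable <- !path$gap_excluded
  if (!any(usable[w])) {
    out <- list(bear_id = attr(path, "bear_id"), period = attr(path, "period"),
                indeterminate = TRUE, eligible = FALSE)
    class(out) <- "bear_year_summary"
    return(out)
  }
  on_land <- rep(FALSE, nrow(path))
  on_land[usable] <- classify_on_land(path$x[usable], path$y[usable], coast)

  days_on_land <- sum(on_land[w & usable])
  eligible <- covered && !any(path$gap_excluded[w])

  # bouts: maximal runs of consecutive on-land days (gap days break runs)
  r <- rle(on_land)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  bi <- which(r$values)
  bouts <- data.frame(start = path$time[starts[bi]],
                      end = path$time[ends[bi]])
  arrival <- NA_real_; departure <- NA_real_; stayed <- FALSE
  if (nrow(bouts)) {
    inw <- bouts$start >= window[1] & bouts$start <= window[2]
    if (any(inw)) {
      main <- bouts[inw, ][which.max(bouts$end[inw] - bouts$start[inw]), ]
      arrival <- main$start
    }
    last_day <- max(path$time[usable])
    done <- bouts$end <= DEC31 & bouts$end < last_day
    stayed <- any(bouts$end >= DEC31) ||
      (nrow(bouts) && bouts$end[nrow(bouts)] == last_day && last_day >= DEC31)
    if (any(done)) departure <- max(bouts$end[done])
  }

  mass <- NA_character_
  li <- which(w & usable & on_land)
  if (length(li)) {
    lab <- nearest_land_mass(path$x[li], path$y[li], coast)
    tab <- table(lab)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) { # tie: earliest visited
      first_seen <- vapply(top, function(m) min(which(lab == m)), 1)
      top <- top[which.min(first_seen)]
    }
    mass <- top
  }
  out <- list(bear_id = attr(path, "bear_id"), period = attr(path, "period"),
              indeterminate = FALSE,
              days_on_land = days_on_land,
              used_gt7 = days_on_land > 7,
              used_gt21 = days_on_land > 21,
              arrival_doy = if (!is.na(arrival)) ordinal_date(arrival) else NA_real_,
              departure_doy = if (!is.na(departure)) ordinal_date(departure) else NA_real_,
              stayed_into_winter = stayed,
              land_mass = mass,
              n_days_with_locations = sum(usable),
              n_gap_days_window = sum(path$gap_excluded[w]),
              eligible = eligible)
  class(out) <- "bear_year_summary"
  out
}

#' @export
print.bear_year_summary <- function(x, ...) {
  if (isTRUE(x$indeterminate)) {
    cat("bear_year_summary", x$bear_id, ": indeterminate (window lost to gaps)\n")
    return(invisible(x))
  }
  cat("bear_year_summary", x$bear_id, "| period", x$period, "|",
      x$days_on_land, "land days (Aug-Oct) |",
      if (x$used_gt21) ">21d" else if (x$used_gt7) ">7d" else "<=7d",
      "| mass:", x$land_mass, "| eligible:", x$eligible, "\n")
  invisible(x)
}

#' Percent of a bear-year's locations on land
#'
#' Requires at least `min_days` non-gap-excluded predicted days, mirroring
#' the rule that annual percentages are only meaningful for near-complete
#' bear-years.
#'
#' @inheritParams summarize_bear_year
#' @param min_days minimum usable days (default 300).
#' @return percentage in [0, 100].
#' @export
percent_year_on_land <- function(path, coast, min_days = 300) {
  stopifnot(inherits(path, "predicted_path"))
  usable <- !path$gap_excluded
  if (sum(usable) < min_days)
    stop("only ", sum(usable), " usable days; need ", min_days)
  on_land <- classify_on_land(path$x[usable], path$y[usable], coast)
  100 * mean(on_land)
}
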