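#' Study calendar helpers
#'
#' The package uses a 365-day study calendar: time is measured in days since
#' 31 December of the bear-year's capture year (so `t = 1` is 1 January and
#' `t = 366` is 1 January of the following year). Leap days are dropped, so
#' an ordinal (Julian) date is always in 1..365. Key analysis windows are
#' expressed as ordinal dates: the summering window is 1 Aug - 31 Oct
#' (213..304, 92 days) and the denning window 1 Oct - 31 May (274..516 in
#' study time).
#'
#' @param t numeric study time in days (may exceed 365 for the second
#'   calendar year of a bear-year).
#' @return `ordinal_date()` returns the day of year in 1..365.
#' @export
ordinal_date <- function(t) ((floor(t) - 1) %% 365) + 1

#' @rdname ordinal_date
#' @export
AUG1 <- 213

#' @rdname ordinal_date
#' @export
OCT31 <- 304

#' @rdname ordinal_date
#' @export
OCT1 <- 274

#' @rdname ordinal_date
#' @export
MAY31_NEXT <- 365 + 151

#' @rdname ordinal_date
#' @export
DEC31 <- 365

# first study-time day of each fixed 7-day week block starting 1 Jan
week_of_doy <- function(doy) pmin((doy - 1) %/% 7 + 1, 53)
week_start_doy <- function(week) (week - 1) * 7 + 1
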