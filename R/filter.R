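#' Screen raw Argos/GPS fixes before movement modeling
#'
#' Standard quality classes (3, 2, 1) and GPS fixes are always retained and
#' class Z always rejected. Auxiliary classes (0, A, B) are retained when
#' corroborated by the temporally adjacent kept fix within the
#' corroboration radius, or when the implied movement rates to both kept
#' neighbors are below the rate limit and the angle at the fix is not
#' extremely acute (an out-and-back spike). The angle threshold is exposed
#' because "not extremely acute" has no canonical value.
#'
#' @param track a `bear_track`.
#' @param max_rate maximum plausible movement rate, km/h (default 10).
#' @param corroboration_radius km (default 10).
#' @param min_turn_angle_deg minimum angle (degrees) at an auxiliary fix
#'   between the segments to its kept neighbors; smaller angles indicate an
#'   implausible spike (default 30).
#' @return list with `track` (kept fixes only) and `decisions`, a data
#'   frame with one row per input fix (`index`, `kept`, `reason`).
#' @export
filter_track <- function(track, max_rate = 10, corroboration_radius = 10,
                         min_turn_angle_deg = 30) {
  stopifnot(inherits(track, "bear_track"))
  fx <- track$fixes
  if (nrow(fx) == 0) stop("track has no fixes")
  cls <- as.character(fx$class)
  known <- c("3", "2", "1", "0", "A", "B", "Z", "GPS")
  if (!all(cls %in% known))
    stop("unknown quality class: ",
         paste(unique(setdiff(cls, known)), collapse = ", "))
  n <- nrow(fx)
  kept <- cls %in% c("3", "2", "1", "GPS")
  reason <- ifelse(kept, "standard_class",
                   ifelse(cls == "Z", "rejected_Z", NA))
  aux <- which(cls %in% c("0", "A", "B"))
  std_kept <- kept # pass-1 kept set, used for the "next" neighbor
  for (i in aux) {
    prev <- which(kept[seq_len(i - 1)])
    prev <- if (length(prev)) max(prev) else NA
    nxt <- if (i < n) which(std_kept[(i + 1):n]) else integer()
    nxt <- if (length(nxt)) i + min(nxt) else NA
    dprev <- if (!is.na(prev))
      sqrt((fx$x[i] - fx$x[prev])^2 + (fx$y[i] - fx$y[prev])^2) else NA
    dnxt <- if (!is.na(nxt))
      sqrt((fx$x[i] - fx$x[nxt])^2 + (fx$y[i] - fx$y[nxt])^2) else NA
    if ((!is.na(dprev) && dprev <= corroboration_radius) ||
        (!is.na(dnxt) && dnxt <= corroboration_radius)) {
      kept[i] <- TRUE; reason[i] <- "corroborated_10km"
      next
    }
    # rate test to each existing kept neighbor (km/h; times are in days)
    rprev <- if (!is.na(prev)) dprev / ((fx$time[i] - fx$time[prev]) * 24) else NA
    rnxt <- if (!is.na(nxt)) dnxt / ((fx$time[nxt] - fx$time[i]) * 24) else NA
    rate_ok <- all(c(rprev, rnxt)[!is.na(c(rprev, rnxt))] < max_rate) &&
      !(is.na(rprev) && is.na(rnxt))
    if (!rate_ok) { reason[i] <- "rate_fail"; next }
    if (!is.na(prev) && !is.na(nxt)) {
      v1 <- c(fx$x[prev] - fx$x[i], fx$y[prev] - fx$y[i])
      v2 <- c(fx$x[nxt] - fx$x[i], fx$y[nxt] - fx$y[i])
      cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      ang <- acos(min(1, max(-1, cosang))) * 180 / pi
      if (ang < min_turn_angle_deg) { reason[i] <- "angle_fail"; next }
    }
    kept[i] <- TRUE; reason[i] <- "rate_angle_pass"
  }
  out <- track
  out$fixes <- fx[kept, , drop = FALSE]
  rownames(out$fixes) <- NULL
  list(track = out,
       decisions = data.frame(index = seq_len(n), kept = kept,
                              reason = reason))
}

#' Remove post-drop data from a track
#'
#' A dropped collar keeps transmitting from a fixed point; drops are
#' detected as the first sustained run of zero daily activity. Fixes and
#' sensor records after the run's first day are removed.
#'
#' @param track a `bear_track` with an activity series.
#' @param min_zero_days minimum run of zero-activity days (default 7).
#' @return the truncated `bear_track` (unchanged when no drop is found).
#' @export
truncate_dropped_collar <- function(track, min_zero_days = 7) {
  stopifnot(inherits(track, "bear_track"))
  act <- track$activity
  if (is.null(act)) stop("track has no activity series")
  z <- rle(act$act == 0)
  ends <- cumsum(z$lengths)
  starts <- ends - z$lengths + 1
  hit <- which(z$values & z$lengths >= min_zero_days)
  if (!length(hit)) return(track)
  drop_t <- act$time[starts[hit[1]]]
  track$fixes <- track$fixes[track$fixes$time < drop_t, , drop = FALSE]
  track$activity <- act[act$time < drop_t, , drop = FALSE]
  if (!is.null(track$temperature))
    track$temperature <-
      track$temperature[track$temperature$time < drop_t, , drop = FALSE]
  track$drop_detected <- drop_t
  track
}
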