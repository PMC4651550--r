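#' Validation of interpolated land-use status
#'
#' Two resampling checks of whether the movement model can be trusted to
#' classify interpolated positions as on land or on ice: withheld-fix
#' cross-validation, and re-prediction of observed on-land midpoints after
#' deleting a 14-day window around them.
#'
#' @name validation
NULL

#' Withheld-fix cross-validation of land/ice classification
#'
#' Withholds `n_withheld` observed fixes, refits the movement model on the
#' rest, predicts positions at the withheld times, and compares the
#' predicted land/ice status with the status of the withheld observations.
#'
#' @param track a filtered `bear_track`.
#' @param coast a `coast_geometry`.
#' @param n_withheld number of withheld fixes (default 5).
#' @param seed RNG seed; the same seed selects the same withheld set.
#' @return list with `rate` (misclassification rate in [0, 1]), `n`, and
#'   the per-fix comparison table.
#' @export
crossvalidate_withheld <- function(track, coast, n_withheld = 5, seed = 1) {
  stopifnot(inherits(track, "bear_track"))
  fx <- track$fixes
  if (nrow(fx) <= n_withheld + 10)
    stop("track too short to withhold ", n_withheld, " fixes")
  set.seed(seed)
  # interior fixes only, so withheld times stay interpolations
  cand <- 2:(nrow(fx) - 1)
  wh <- sort(sample(cand, n_withheld))
  tr2 <- track
  tr2$fixes <- fx[-wh, , drop = FALSE]
  fit <- fit_ctcrw(tr2)
  pred <- ctcrw_smooth_at(fit, fx$time[wh])
  obs_land <- classify_on_land(fx$x[wh], fx$y[wh], coast)
  pred_land <- classify_on_land(pred$x, pred$y, coast)
  comp <- data.frame(time = fx$time[wh], obs_land = obs_land,
                     pred_land = pred_land,
                     misclassified = obs_land != pred_land)
  list(rate = mean(comp$misclassified), n = n_withheld, comparison = comp)
}

#' Gap-midpoint validation of on-land prediction
#'
#' For each observed on-land fix that has another observation at least
#' `half_gap` days before and after it (the midpoint of a 14-day series),
#' all fixes within the window around it are removed, the model refitted,
#' and the midpoint re-predicted; reported is the proportion of
#' re-predicted midpoints that still classify on land, with its SE.
#'
#' @param tracks list of filtered `bear_track`s.
#' @param coast a `coast_geometry`.
#' @param half_gap half-window in days (default 7).
#' @param max_per_track cap on qualifying midpoints evaluated per track.
#' @param require_on_land only observed on-land fixes qualify as midpoints
#'   (the definition used for land-use validation); set FALSE to audit
#'   every midpoint regardless of its observed status, in which case the
#'   reported proportion is of predictions agreeing with the observed
#'   status rather than of predictions on land.
#' @return list with `proportion`, `se`, `n`, and the per-midpoint table;
#'   `n = 0` with NA proportion when no midpoint qualifies.
#' @export
validate_gap_midpoints <- function(tracks, coast, half_gap = 7,
                                   max_per_track = 5,
                                   require_on_land = TRUE) {
  rows <- list()
  for (track in tracks) {
    fx <- track$fixes
    if (nrow(fx) < 15) next
    on_land <- classify_on_land(fx$x, fx$y, coast)
    qual <- which((on_land | !require_on_land) &
                    fx$time - min(fx$time) >= half_gap &
                    max(fx$time) - fx$time >= half_gap)
    # need an observation at or beyond half_gap on both sides
    qual <- qual[vapply(qual, function(i) {
      any(fx$time <= fx$time[i] - half_gap) &&
        any(fx$time >= fx$time[i] + half_gap)
    }, logical(1))]
    if (!length(qual)) next
    if (length(qual) > max_per_track)
      qual <- qual[round(seq(1, length(qual), length.out = max_per_track))]
    for (i in qual) {
      keep <- fx$time <= fx$time[i] - half_gap |
        fx$time >= fx$time[i] + half_gap
      if (sum(keep) < 10 || diff(range(fx$time[keep])) < 20) next
      tr2 <- track
      tr2$fixes <- fx[keep, , drop = FALSE]
      fit <- try(fit_ctcrw(tr2), silent = TRUE)
      if (inherits(fit, "try-error") || !fit$converged) next
      pred <- ctcrw_smooth_at(fit, fx$time[i])
      rows[[length(rows) + 1]] <-
        data.frame(bear_id = track$bear_id, time = fx$time[i],
                   pred_on_land = classify_on_land(pred$x, pred$y, coast))
    }
  }
  if (!length(rows))
    return(list(proportion = NA_real_, se = NA_real_, n = 0L,
                results = data.frame()))
  res <- do.call(rbind, rows)
  p <- mean(res$pred_on_land)
  list(proportion = p, se = sqrt(p * (1 - p) / nrow(res)),
       n = nrow(res), results = res)
}
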