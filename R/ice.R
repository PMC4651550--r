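#' Sea-ice phenology metrics from daily concentration grids
#'
#' Weekly mean concentration grids (fixed 7-day blocks from 1 Jan, final
#' short block included), pack-ice identification as the largest contiguous
#' area at >= 15% concentration, per-coastal-segment retreat and return
#' dates against a 50-km distance rule, and shelf coverage fractions. A
#' week is dated by its first day. The never-retreats sentinel is
#' `(365, 1)`.
#'
#' @name ice_phenology
NULL

#' Weekly mean concentration grids
#'
#' @param stack an `ice_stack`.
#' @return list with `week_start` (ordinal date of each block's first day)
#'   and `grids` (list of matrices, per-cell mean over the block's
#'   available days; missing days are ignored).
#' @export
weekly_mean <- function(stack) {
  stopifnot(inherits(stack, "ice_stack"))
  wk <- week_of_doy(stack$dates)
  weeks <- sort(unique(wk))
  grids <- lapply(weeks, function(w) {
    sel <- which(wk == w)
    if (!length(sel)) stop("empty week ", w)
    g <- stack$conc[, , sel, drop = FALSE]
    apply(g, c(1, 2), mean, na.rm = TRUE)
  })
  list(week_start = week_start_doy(weeks), grids = grids)
}

#' Largest contiguous pack-ice component of a grid
#'
#' Flood-fill connected-component labeling of cells at or above the
#' concentration threshold (land cells excluded), returning the largest
#' component. Contiguity is 8-connected by default so diagonally touching
#' pack ice is not split.
#'
#' @param grid concentration matrix.
#' @param land_mask logical matrix of land cells (optional).
#' @param threshold concentration threshold (default 0.15).
#' @param connectivity 8 (default) or 4.
#' @return logical matrix marking the largest component; all-FALSE when no
#'   cell reaches the threshold.
#' @export
pack_ice_component <- function(grid, land_mask = NULL, threshold = 0.15,
                               connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  ice <- !is.na(grid) & grid >= threshold
  if (!is.null(land_mask)) ice <- ice & !land_mask
  lab <- label_components(ice, connectivity)
  if (max(lab) == 0) return(ice & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# integer component labels by iterative flood fill (stack-based)
label_components <- function(mask, connectivity = 8) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  if (connectivity == 8) {
    dx <- c(-1, 0, 1, -1, 1, -1, 0, 1); dy <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  } else {
    dx <- c(0, 0, -1, 1); dy <- c(-1, 1, 0, 0)
  }
  cur <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- matrix(c(i, j), 1, 2)
    lab[i, j] <- cur
    while (nrow(stack)) {
      c0 <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (k in seq_along(dx)) {
        ii <- c0[1] + dx[k]; jj <- c0[2] + dy[k]
        if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack <- rbind(stack, c(ii, jj))
        }
      }
    }
  }
  lab
}

#' Coastal segments of an ice stack
#'
#' Water cells 8-adjacent to land, one 25-km segment per cell, labeled
#' with the nearest land mass.
#'
#' @param stack an `ice_stack`.
#' @param coast a `coast_geometry` for the labels.
#' @return data frame `ix`, `iy`, `x`, `y`, `label`.
#' @export
coastal_segments <- function(stack, coast) {
  land <- stack$land_mask
  nx <- nrow(land); ny <- ncol(land)
  near_land <- matrix(FALSE, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    near_land[xs - dx, ys - dy] <- near_land[xs - dx, ys - dy] |
      land[xs, ys]
  }
  sel <- which(near_land & !land, arr.ind = TRUE)
  out <- data.frame(ix = sel[, 1], iy = sel[, 2],
                    x = stack$x_centers[sel[, 1]],
                    y = stack$y_centers[sel[, 2]])
  out$label <- nearest_land_mass(out$x, out$y, coast)
  out$segment_id <- sprintf("s%03d", seq_len(nrow(out)))
  out
}

#' Ice retreat and return dates for one coastal segment
#'
#' Retreat is the first ordinal date (the start of the first weekly block)
#' at which the minimum center-to-center distance from the segment cell to
#' any pack-ice cell exceeds `distance_km`; return is the first date after
#' retreat at which that distance is again within `distance_km`. Sentinel
#' `(365, 1)` when the pack never leaves; return 365 when it never comes
#' back.
#'
#' @param seg_x,seg_y segment cell center (km).
#' @param weekly output of [weekly_mean()].
#' @param stack the `ice_stack` (for masks and cell centers).
#' @param distance_km distance rule (default 50).
#' @param threshold concentration threshold (default 0.15).
#' @return named numeric `c(retreat_doy, return_doy)`.
#' @export
retreat_return_dates <- function(seg_x, seg_y, weekly, stack,
                                 distance_km = 50, threshold = 0.15) {
  beyond <- vapply(weekly$grids, function(g) {
    comp <- pack_ice_component(g, stack$land_mask, threshold)
    idx <- which(comp, arr.ind = TRUE)
    if (!nrow(idx)) return(TRUE)
    d2 <- (stack$x_centers[idx[, 1]] - seg_x)^2 +
      (stack$y_centers[idx[, 2]] - seg_y)^2
    min(d2) > distance_km^2
  }, logical(1))
  ri <- which(beyond)[1]
  if (is.na(ri)) return(c(retreat_doy = 365, return_doy = 1))
  bi <- which(!beyond & seq_along(beyond) > ri)[1]
  c(retreat_doy = weekly$week_start[ri],
    return_doy = if (is.na(bi)) 365 else weekly$week_start[bi])
}

#' Retreat/return dates for every coastal segment of a stack
#'
#' @param stack an `ice_stack`.
#' @param coast a `coast_geometry`.
#' @param distance_km,threshold see [retreat_return_dates()].
#' @return the [coastal_segments()] table with `retreat_doy` and
#'   `return_doy` columns.
#' @export
segment_phenology <- function(stack, coast, distance_km = 50,
                              threshold = 0.15) {
  segs <- coastal_segments(stack, coast)
  weekly <- weekly_mean(stack)
  comps <- lapply(weekly$grids, function(g)
    which(pack_ice_component(g, stack$land_mask, threshold), arr.ind = TRUE))
  dates <- t(vapply(seq_len(nrow(segs)), function(i) {
    beyond <- vapply(comps, function(idx) {
      if (!nrow(idx)) return(TRUE)
      d2 <- (stack$x_centers[idx[, 1]] - segs$x[i])^2 +
        (stack$y_centers[idx[, 2]] - segs$y[i])^2
      min(d2) > distance_km^2
    }, logical(1))
    ri <- which(beyond)[1]
    if (is.na(ri)) return(c(365, 1))
    bi <- which(!beyond & seq_along(beyond) > ri)[1]
    c(weekly$week_start[ri],
      if (is.na(bi)) 365 else weekly$week_start[bi])
  }, numeric(2)))
  segs$retreat_doy <- dates[, 1]
  segs$return_doy <- dates[, 2]
  segs
}

#' Mean daily shelf ice coverage over a window
#'
#' @param stack an `ice_stack`.
#' @param window `c(first, last)` ordinal dates (default 1 Aug - 31 Oct).
#' @param threshold concentration threshold (default 0.15).
#' @return mean over window days of the fraction of shelf cells at or
#'   above the threshold.
#' @export
shelf_ice_fraction <- function(stack, window = c(AUG1, OCT31),
                               threshold = 0.15) {
  stopifnot(inherits(stack, "ice_stack"))
  shelf <- which(stack$shelf_mask)
  if (!length(shelf)) stop("shelf mask is empty")
  days <- which(stack$dates >= window[1] & stack$dates <= window[2])
  fr <- vapply(days, function(t) {
    g <- stack$conc[, , t]
    mean(g[shelf] >= threshold, na.rm = TRUE)
  }, numeric(1))
  mean(fr)
}
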