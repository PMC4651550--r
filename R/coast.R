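#' Coastline geometry in the planar study projection
#'
#' All analysis happens in a locally equal-distance projected plane with km
#' units; land masses are closed polygons with field labels (mainland coasts
#' and offshore islands). A point counts as "on land" when it lies inside a
#' polygon or within the coastal buffer (5 km by default) of its boundary —
#' the buffer absorbs unresolved barrier islands and location error.
#'
#' @param polygons named list of two-column matrices (x, y in km), one
#'   closed polygon per land mass. The closing vertex may be omitted.
#' @param buffer_km buffer distance in km (default 5).
#' @param shelf_max_y northern limit (km) of the continental-shelf band used
#'   for ice-coverage fractions.
#' @return a `coast_geometry` object.
#' @export
make_coast <- function(polygons, buffer_km = 5, shelf_max_y = 300) {
  stopifnot(length(polygons) > 0, !is.null(names(polygons)))
  polys <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2, nrow(p) >= 3)
    # drop explicit closing vertex; edges close implicitly
    if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    unname(p)
  })
  out <- list(polygons = polys, buffer_km = buffer_km, shelf_max_y = shelf_max_y)
  class(out) <- "coast_geometry"
  out
}

#' @export
print.coast_geometry <- function(x, ...) {
  cat("coast_geometry:", length(x$polygons), "land masses (",
      paste(names(x$polygons), collapse = ", "), "), buffer",
      x$buffer_km, "km\n")
  invisible(x)
}

# even-odd ray-casting point-in-polygon; poly is an open ring matrix
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# minimum distance from points to a polygon boundary (segments)
dist_to_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}

#' Classify points as on land
#'
#' A point is on land when it falls inside a land polygon or within the
#' coastal buffer of its boundary (planar distance).
#'
#' @param x,y coordinates in km (vectors of equal length).
#' @param coast a `coast_geometry`.
#' @param buffer_km buffer override in km; defaults to the coast's buffer.
#' @return logical vector.
#' @export
classify_on_land <- function(x, y, coast, buffer_km = coast$buffer_km) {
  stopifnot(inherits(coast, "coast_geometry"), length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  on <- rep(FALSE, length(x))
  for (poly in coast$polygons) {
    on <- on | point_in_polygon(x, y, poly)
    if (buffer_km > 0) on <- on | (dist_to_polygon(x, y, poly) <= buffer_km)
  }
  on
}

#' Label the land mass nearest to / containing each point
#'
#' @inheritParams classify_on_land
#' @return character vector of land-mass names (the nearest polygon,
#'   whether or not the point is on land).
#' @export
nearest_land_mass <- function(x, y, coast) {
  stopifnot(inherits(coast, "coast_geometry"))
  d <- sapply(coast$polygons, function(poly) {
    dd <- dist_to_polygon(x, y, poly)
    dd[point_in_polygon(x, y, poly)] <- 0
    dd
  })
  d <- matrix(d, nrow = length(x))
  names(coast$polygons)[apply(d, 1, which.min)]
}
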