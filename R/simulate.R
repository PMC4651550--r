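#' Synthetic telemetry, sensor and ice inputs with known truth
#'
#' The generator emulates the inputs of a two-period collaring study:
#' spring-captured bears tracked into the following winter, Argos/GPS fixes
#' with class-dependent error and transmission gaps, collar temperature and
#' activity streams, and daily sea-ice concentration rasters whose >=15%
#' margin leaves southern coasts early and northern islands late. Every
#' object is a deterministic function of the configuration and its seed.
#'
#' @name synthetic_data
NULL

# Argos quality class -> prescribed measurement SD (metres). Class Z fixes
# are invalid and carry no prescribed accuracy.
ERROR_SD_M <- c("3" = 150, "2" = 350, "1" = 1000, "0" = 1500,
                "A" = 5000, "B" = 10000, "GPS" = 30)

#' Error SD for Argos quality classes
#'
#' @param class character vector of class labels (3, 2, 1, 0, A, B, GPS).
#' @return SD in metres; class Z returns NA (always rejected upstream).
#' @export
argos_error_sd <- function(class) {
  out <- ERROR_SD_M[as.character(class)]
  out[as.character(class) == "Z"] <- NA_real_
  if (any(is.na(out) & as.character(class) != "Z"))
    stop("unknown Argos quality class: ",
         paste(setdiff(class, c(names(ERROR_SD_M), "Z")), collapse = ", "))
  unname(out)
}

#' Construct a bear track
#'
#' @param bear_id identifier.
#' @param period period label (1 or 2).
#' @param fixes data frame with `time` (study days, strictly increasing),
#'   `x`, `y` (km), `class`; `error_sd` (m) is filled from the class map if
#'   absent.
#' @param temperature optional data frame `time`, `temp` (daily collar C).
#' @param activity optional data frame `time`, `act` (daily activity count).
#' @param capture_site optional label.
#' @param truth optional generator ground-truth list.
#' @return a `bear_track`.
#' @export
make_track <- function(bear_id, period, fixes, temperature = NULL,
                       activity = NULL, capture_site = NA_character_,
                       truth = NULL) {
  stopifnot(all(c("time", "x", "y", "class") %in% names(fixes)))
  if (nrow(fixes) && any(diff(fixes$time) <= 0))
    stop("fix times must be strictly increasing")
  if (is.null(fixes$error_sd)) fixes$error_sd <- argos_error_sd(fixes$class)
  out <- list(bear_id = bear_id, period = period, fixes = fixes,
              temperature = temperature, activity = activity,
              capture_site = capture_site, truth = truth)
  class(out) <- "bear_track"
  out
}

#' @export
print.bear_track <- function(x, ...) {
  cat("bear_track", x$bear_id, "| period", x$period, "|",
      nrow(x$fixes), "fixes over",
      round(diff(range(x$fixes$time)), 1), "days\n")
  invisible(x)
}

#' Simulate an exact integrated-OU (CTCRW) track
#'
#' Samples the true (position, velocity) state at the supplied times using
#' the exact matrix-exponential discretization of the integrated
#' Ornstein-Uhlenbeck process — the same transition the Kalman filter in
#' [fit_ctcrw()] assumes — then adds isotropic Gaussian measurement error.
#' Used for likelihood-oracle and parameter-recovery validation.
#'
#' @param beta,sigma process parameters (1/day, km/day^1.5); both > 0.
#' @param times strictly increasing observation times (days).
#' @param error_sd_m measurement SD in metres (scalar or per fix).
#' @param start,vel0 initial position and velocity (km, km/day).
#' @param bear_id,period passed to the returned track.
#' @return a `bear_track` whose `truth$daily` holds the true positions at
#'   `times`; fixes carry class `GPS` but the supplied `error_sd`.
#' @export
simulate_ctcrw_track <- function(beta, sigma, times, error_sd_m = 30,
                                 start = c(0, 0), vel0 = c(0, 0),
                                 bear_id = "sim", period = 2) {
  if (beta <= 0 || sigma < 0) stop("beta must be > 0 and sigma >= 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  n <- length(times)
  p <- matrix(0, n, 2); v <- matrix(0, n, 2)
  p[1, ] <- start; v[1, ] <- vel0
  if (n > 1) for (i in 2:n) {
    d <- ctcrw_discretize(beta, max(sigma, 1e-12), times[i] - times[i - 1])
    # chol of [[q_pp, q_pv], [q_pv, q_vv]]
    l11 <- sqrt(max(d$q_pp, 0))
    l21 <- if (l11 > 0) d$q_pv / l11 else 0
    l22 <- sqrt(max(d$q_vv - l21^2, 0))
    for (ax in 1:2) {
      z <- stats::rnorm(2)
      p[i, ax] <- p[i - 1, ax] + d$t_pv * v[i - 1, ax] + l11 * z[1]
      v[i, ax] <- d$t_vv * v[i - 1, ax] + l21 * z[1] + l22 * z[2]
    }
  }
  err <- rep_len(error_sd_m, n) / 1000
  fixes <- data.frame(time = times,
                      x = p[, 1] + stats::rnorm(n, 0, err),
                      y = p[, 2] + stats::rnorm(n, 0, err),
                      class = "GPS", error_sd = err * 1000)
  make_track(bear_id, period, fixes,
             truth = list(daily = data.frame(time = times,
                                             x = p[, 1], y = p[, 2]),
                          beta = beta, sigma = sigma))
}

# stationary OU positional deviation sampled exactly on an irregular grid
ou_deviation <- function(times, sd, tau) {
  n <- length(times)
  d <- matrix(0, n, 2)
  d[1, ] <- stats::rnorm(2, 0, sd)
  if (n > 1) for (i in 2:n) {
    a <- exp(-(times[i] - times[i - 1]) / tau)
    s <- sd * sqrt(1 - a^2)
    d[i, ] <- a * d[i - 1, ] + stats::rnorm(2, 0, s)
  }
  d
}

# Ice-edge trajectory: northern extent (km) of the high-concentration core
# as a function of ordinal date, built so the 15% contour (which sits
# off_km south of the core edge) crosses 50 km off a coast at latitude
# `lat` exactly on the profile's `doy`. Piecewise linear: full winter
# cover, retreat through the profile points, plateau, return, full cover.
ice_edge_fun <- function(retreat, ret, off_km = 25.1) {
  ro <- order(retreat$doy)
  rdoy <- retreat$doy[ro]; redge <- retreat$lat[ro] + 50 + off_km
  bo <- order(ret$doy)
  # the pack cannot return from farther north than it retreated
  bdoy <- ret$doy[bo]
  bedge <- pmin(ret$lat[bo] + 50 + off_km, max(retreat$lat) + 50 + off_km)
  edge_min <- min(retreat$lat) - 400
  stopifnot(min(bdoy) > max(rdoy)) # return starts after retreat completes
  tt <- c(min(rdoy) - 30, rdoy, bdoy, max(bdoy) + 30)
  ee <- c(edge_min, redge, bedge, edge_min)
  keep <- !duplicated(tt)
  stats::approxfun(tt[keep], ee[keep], rule = 2)
}

#' Generate a daily sea-ice concentration stack for one year
#'
#' Concentration is a meridional logistic front around a seasonal ice-edge
#' trajectory: full cover in winter, poleward retreat past the configured
#' per-latitude dates, and southward return in autumn, plus small clipped
#' Gaussian noise. Coasts whose latitude lies above the retreat profile
#' never lose ice within 50 km (the sentinel case).
#'
#' @param config a `sim_config`.
#' @param year calendar-year index (element of `config$years_by_period`).
#' @return an `ice_stack`: daily concentration array (nx x ny x 365) in
#'   [0,1], land and shelf masks, cell centers, and the year's true
#'   date-profile shift.
#' @export
generate_ice_stack <- function(config, year) {
  period <- if (year %in% config$years_by_period[[1]]) 1L else 2L
  set.seed((config$seed + 104729L * as.integer(year)) %% 2147483647L)
  shift <- stats::rnorm(1, 0, config$ice_year_jitter_sd)
  retreat <- config$ice_retreat_profile_by_period[[period]]
  ret <- config$ice_return_profile_by_period[[period]]
  retreat$doy <- retreat$doy + shift
  ret$doy <- ret$doy + shift
  edge <- ice_edge_fun(retreat, ret)
  nx <- config$grid_nx; ny <- config$grid_ny; ck <- config$grid_cell_km
  xc <- (seq_len(nx) - 0.5) * ck
  yc <- (seq_len(ny) - 0.5) * ck
  coast <- default_coast(config)
  cells <- expand.grid(x = xc, y = yc)
  land <- matrix(classify_on_land(cells$x, cells$y, coast, buffer_km = 0),
                 nx, ny)
  shelf <- matrix(cells$y <= config$shelf_max_y, nx, ny) & !land
  conc <- array(0, c(nx, ny, 365))
  for (t in 1:365) {
    prof <- 0.95 * stats::plogis((yc - edge(t)) / 15)
    conc[, , t] <- matrix(rep(prof, each = nx), nx, ny) +
      stats::rnorm(nx * ny, 0, 0.02)
  }
  conc[conc < 0] <- 0; conc[conc > 1] <- 1
  out <- list(dates = 1:365, conc = conc, land_mask = land,
              shelf_mask = shelf, x_centers = xc, y_centers = yc,
              cell_km = ck, year = year, period = period,
              shift = shift, edge = edge)
  class(out) <- "ice_stack"
  out
}

#' @export
print.ice_stack <- function(x, ...) {
  cat("ice_stack year", x$year, "| grid", length(x$x_centers), "x",
      length(x$y_centers), "@", x$cell_km, "km |", length(x$dates),
      "days\n")
  invisible(x)
}

#' Generate a collar temperature series
#'
#' Seasonal baseline (annual cosine, warm in July, cold in January) plus
#' Gaussian noise; during a denning interval the mean is elevated by the
#' configured offset. Called inside [generate_track()]; exported so the
#' denning detector can be validated in isolation.
#'
#' @param config a `sim_config`.
#' @param denning_interval `c(start, end)` in study days, or NULL.
#' @param times study days of the series (default full bear-year).
#' @return data frame `time`, `temp`.
#' @export
generate_temperature <- function(config, denning_interval = NULL,
                                 times = 95:520) {
  base <- -5 + 15 * cos(2 * pi * (ordinal_date(times) - 196) / 365)
  off <- rep(0, length(times))
  if (!is.null(denning_interval)) {
    stopifnot(length(denning_interval) == 2)
    off[times >= denning_interval[1] & times <= denning_interval[2]] <-
      config$den_temp_offset
  }
  data.frame(time = times,
             temp = base + off + stats::rnorm(length(times),
                                              0, config$temp_noise_sd))
}

# interior target point of a rectangular land mass, >= 10 km from shore
land_target <- function(coast, mass) {
  poly <- coast$polygons[[mass]]
  cx <- mean(range(poly[, 1])); cy <- mean(range(poly[, 2]))
  jx <- min(15, (diff(range(poly[, 1])) / 2 - 12))
  jy <- min(15, (diff(range(poly[, 2])) / 2 - 12))
  c(cx + stats::runif(1, -max(jx, 0), max(jx, 0)),
    cy + stats::runif(1, -max(jy, 0), max(jy, 0)))
}

#' Generate one synthetic bear-year track
#'
#' Draws the bear-year's behavior (summer land use, land mass, arrival and
#' duration, denning and den substrate) from the configured period-level
#' probabilities, builds a behavioral waypoint path (with the ice edge as
#' the offshore attractor), adds a stationary Ornstein-Uhlenbeck positional
#' deviation, and samples fixes on the period's schedule with quality-class
#' error, dropout, occasional long outages, denning attenuation and
#' possible collar drop. Sensor series (temperature, activity) are daily.
#'
#' @param config a `sim_config`.
#' @param bear_index 1-based index; indices `1..n_bears_period1` belong to
#'   the early period, the rest to the recent period.
#' @param coast optional `coast_geometry` (defaults to [default_coast()]).
#' @return a `bear_track` with a `truth` list (true daily path, behavior
#'   flags, true window land days, denning interval and substrate).
#' @export
generate_track <- function(config, bear_index, coast = default_coast(config)) {
  stopifnot(inherits(config, "sim_config"),
            bear_index >= 1,
            bear_index <= config$n_bears_period1 + config$n_bears_period2)
  set.seed((config$seed + 1000003L * as.integer(bear_index)) %% 2147483647L)
  p <- if (bear_index <= config$n_bears_period1) 1L else 2L
  year <- if (length(config$years_by_period[[p]]) == 1)
    config$years_by_period[[p]] else sample(config$years_by_period[[p]], 1)
  # ice edge of the bear's year (same deterministic shift as its stack)
  set.seed((config$seed + 104729L * as.integer(year)) %% 2147483647L)
  shift <- stats::rnorm(1, 0, config$ice_year_jitter_sd)
  set.seed((config$seed + 1000003L * as.integer(bear_index) + 17L) %%
             2147483647L)
  retreat <- config$ice_retreat_profile_by_period[[p]]
  ret <- config$ice_return_profile_by_period[[p]]
  retreat$doy <- retreat$doy + shift; ret$doy <- ret$doy + shift
  edge <- ice_edge_fun(retreat, ret)
  offshore_y <- function(t) pmin(pmax(edge(ordinal_date(t)) + 120, 150), 950)

  t0 <- round(stats::rnorm(1, 100, 8)); t0 <- min(max(t0, 85), 115)
  t_end <- 430
  capture_site <- if (p == 1)
    sample(c("wrangel", "alaska", "st_lawrence", "chukotka"), 1,
           prob = c(74, 34, 13, 4) / 125) else "alaska"
  cap <- switch(capture_site,
                wrangel = c(stats::runif(1, 380, 500), stats::runif(1, 900, 990)),
                alaska = c(stats::runif(1, 550, 950), stats::runif(1, 150, 350)),
                st_lawrence = c(stats::runif(1, 600, 800), stats::runif(1, 120, 250)),
                chukotka = c(stats::runif(1, 100, 350), stats::runif(1, 150, 300)))

  land_user <- stats::runif(1) < config$p_land_user_by_period[p]
  denner <- stats::runif(1) < config$denning_prob_by_period[p]
  den_on_land <- denner && stats::runif(1) < config$den_on_land_prob_by_period[p]
  den_int <- NULL
  if (denner) {
    ds <- round(stats::rnorm(1, config$den_start_mean, config$den_start_sd))
    dl <- round(stats::rnorm(1, config$den_length_mean, config$den_length_sd))
    ds <- min(max(ds, OCT1 + 5), 365)
    den_int <- c(ds, min(ds + max(dl, 60), MAY31_NEXT))
  }

  wp_t <- t0; wp_x <- cap[1]; wp_y <- cap[2]
  add_wp <- function(t, x, y) {
    wp_t <<- c(wp_t, t); wp_x <<- c(wp_x, x); wp_y <<- c(wp_y, y)
  }
  drift_x <- cap[1]
  mass <- NA_character_; arrival <- NA; departure <- NA; target <- NULL
  if (land_user) {
    probs <- config$land_mass_probs_by_period[[p]]
    mass <- sample(names(probs), 1, prob = probs)
    target <- land_target(coast, mass)
    arrival <- round(stats::rnorm(1, config$arrival_doy_mean_by_period[p],
                                  config$arrival_doy_sd_by_period[p]))
    arrival <- min(max(arrival, 195), 290)
    dur <- round(stats::rnorm(1, config$mean_days_on_land_by_period[p],
                              config$sd_days_on_land_by_period[p]))
    dur <- min(max(dur, 8), 130)
    departure <- min(arrival + dur - 1, 360)
    # offshore drift toward the land mass, then the onshore residence
    for (t in seq(t0 + 20, arrival - 15, by = 25)) {
      drift_x <- drift_x + (target[1] - drift_x) * 0.4
      add_wp(t, drift_x, min(offshore_y(t), wp_y[length(wp_y)] + 180))
    }
    approach_y <- if (mass %in% c("wrangel", "herald"))
      min(coast$polygons[[mass]][, 2]) - 60 else
        max(coast$polygons[[mass]][, 2]) + 60
    add_wp(arrival - 8, target[1], approach_y)
    add_wp(arrival + 0.2, target[1], target[2])
    add_wp(departure - 0.2, target[1], target[2])
  } else {
    for (t in seq(t0 + 25, 330, by = 30)) {
      drift_x <- drift_x + stats::rnorm(1, 0, 25)
      drift_x <- min(max(drift_x, 100), 900)
      add_wp(t, drift_x, offshore_y(t))
    }
  }
  if (denner && den_on_land) {
    den_mass <- if (land_user && stats::runif(1) < 0.8) mass else
      sample(c("wrangel", "herald", "chukotka", "alaska"), 1,
             prob = c(0.56, 0.07, 0.17, 0.20))
    den_site <- land_target(coast, den_mass)
    if (land_user && den_int[1] - departure < 20) {
      # stays onshore into denning
      add_wp(den_int[1], den_site[1], den_site[2])
    } else {
      off_t <- if (land_user) departure + 4 else min(335, den_int[1] - 8)
      off_y <- if (den_mass %in% c("wrangel", "herald"))
        min(coast$polygons[[den_mass]][, 2]) - 80 else
          max(coast$polygons[[den_mass]][, 2]) + 80
      add_wp(off_t, den_site[1] + stats::rnorm(1, 0, 20), off_y)
      add_wp(den_int[1], den_site[1], den_site[2])
    }
    add_wp(t_end, den_site[1], den_site[2])
  } else if (denner) {
    # ice den: stationary on the pack; a summering bear must have left
    # land before an ice den can begin
    if (land_user && den_int[1] < departure + 8) {
      den_int[1] <- departure + 8
      den_int[2] <- max(den_int[2], den_int[1] + 60)
    }
    if (land_user) {
      t_off <- departure + 4
      off_y <- if (mass %in% c("wrangel", "herald"))
        min(950, offshore_y(t_off)) else 160
      add_wp(t_off, target[1], off_y)
    }
    den_site <- c(min(max(drift_x, 150), 850), 900)
    add_wp(den_int[1], den_site[1], den_site[2])
    add_wp(min(den_int[2], t_end), den_site[1], den_site[2])
    if (den_int[2] < t_end) add_wp(t_end, den_site[1], offshore_y(t_end))
  } else {
    if (land_user) {
      t_off <- departure + 4
      off_y <- if (mass %in% c("wrangel", "herald"))
        min(950, offshore_y(t_off)) else 160
      add_wp(t_off, target[1], off_y)
    }
    add_wp(t_end, min(max(drift_x, 150), 850), offshore_y(t_end))
  }
  o <- order(wp_t)
  wp_t <- wp_t[o]; wp_x <- wp_x[o]; wp_y <- wp_y[o]
  keep <- !duplicated(wp_t)
  mean_path <- list(x = stats::approxfun(wp_t[keep], wp_x[keep], rule = 2),
                    y = stats::approxfun(wp_t[keep], wp_y[keep], rule = 2))

  # fix schedule with dropout, outage, denning attenuation
  interval <- config$fix_interval_days_by_period[p]
  ft <- seq(t0, t_end, by = interval)
  ft <- ft[stats::runif(length(ft)) >= config$dropout_prob]
  if (stats::runif(1) < config$outage_prob) {
    os <- stats::runif(1, t0 + 30, 380)
    ol <- stats::runif(1, config$outage_range[1], config$outage_range[2])
    ft <- ft[ft < os | ft > os + ol]
  }
  if (denner)
    ft <- ft[!(ft >= den_int[1] & ft <= den_int[2]) |
               stats::runif(length(ft)) < 0.3]
  if (length(ft) < 12) ft <- seq(t0, t_end, by = interval * 2)

  days <- seq(t0, t_end)
  grid <- sort(unique(c(days, ft)))
  dev <- ou_deviation(grid, config$dev_sd, config$dev_tau)
  tx <- mean_path$x(grid) + dev[, 1]
  ty <- mean_path$y(grid) + dev[, 2]

  drop_day <- NA_real_
  if (stats::runif(1) < config$collar_drop_prob)
    drop_day <- round(stats::runif(1, t0 + 60, 400))

  fi <- match(ft, grid)
  cls <- if (p == 1)
    sample(names(config$argos_class_mix_period1), length(ft), replace = TRUE,
           prob = config$argos_class_mix_period1) else
             rep("GPS", length(ft))
  esd <- argos_error_sd(cls)
  esd_gen <- ifelse(is.na(esd), 30000, esd) / 1000 # km, Z fixes are junk
  fx <- tx[fi] + stats::rnorm(length(ft), 0, esd_gen)
  fy <- ty[fi] + stats::rnorm(length(ft), 0, esd_gen)
  if (!is.na(drop_day)) {
    frozen <- ft > drop_day
    if (any(frozen)) {
      at_drop_i <- which.min(abs(grid - drop_day))
      fx[frozen] <- tx[at_drop_i] + stats::rnorm(sum(frozen), 0, 0.05)
      fy[frozen] <- ty[at_drop_i] + stats::rnorm(sum(frozen), 0, 0.05)
    }
  }
  fixes <- data.frame(time = ft, x = fx, y = fy, class = cls, error_sd = esd)

  temp <- generate_temperature(config, den_int, times = t0:520)
  act_t <- t0:t_end
  act <- stats::rpois(length(act_t), 40) + 1L
  if (!is.na(drop_day)) act[act_t > drop_day] <- 0L
  activity <- data.frame(time = act_t, act = act)

  di <- match(days, grid)
  truth_daily <- data.frame(time = days, x = tx[di], y = ty[di])
  w <- truth_daily$time >= AUG1 & truth_daily$time <= OCT31
  land_days <- sum(classify_on_land(truth_daily$x[w], truth_daily$y[w], coast))

  if (isTRUE(getOption("polarland.debug_wp")))
    print(data.frame(t = wp_t, x = wp_x, y = wp_y))
  make_track(sprintf("B%03d", bear_index), p, fixes,
             temperature = temp, activity = activity,
             capture_site = capture_site,
             truth = list(daily = truth_daily, land_user = land_user,
                          land_mass = mass, arrival = arrival,
                          departure = departure,
                          days_on_land_window = land_days,
                          denner = denner, den_on_land = den_on_land,
                          den_interval = den_int, drop_day = drop_day,
                          year = year))
}

#' Generate a complete synthetic study
#'
#' All bear-years of both periods plus one ice stack per calendar year and
#' the shared coastline, with a per-bear ground-truth table. Reproducible
#' bit-for-bit from `(config, config$seed)`.
#'
#' @param config a `sim_config`.
#' @return a `synthetic_study` list: `config`, `coast`, `tracks`, `ice`
#'   (list keyed by year), `truth` (data frame).
#' @export
simulate_study <- function(config = sim_config()) {
  coast <- default_coast(config)
  n <- config$n_bears_period1 + config$n_bears_period2
  tracks <- lapply(seq_len(n), function(i) generate_track(config, i, coast))
  years <- sort(unique(vapply(tracks, function(tr) tr$truth$year, 1)))
  ice <- lapply(years, function(y) generate_ice_stack(config, y))
  names(ice) <- years
  truth <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(bear_id = tr$bear_id, period = tr$period,
               year = tr$truth$year, capture_site = tr$capture_site,
               land_user = tr$truth$land_user,
               land_mass = tr$truth$land_mass %||% NA_character_,
               days_on_land = tr$truth$days_on_land_window,
               denner = tr$truth$denner,
               den_on_land = tr$truth$den_on_land,
               den_start = if (is.null(tr$truth$den_interval)) NA_real_ else
                 tr$truth$den_interval[1],
               den_end = if (is.null(tr$truth$den_interval)) NA_real_ else
                 tr$truth$den_interval[2],
               drop_day = tr$truth$drop_day)
  }))
  out <- list(config = config, coast = coast, tracks = tracks, ice = ice,
              truth = truth)
  class(out) <- "synthetic_study"
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", length(x$tracks), "bear-years,",
      length(x$ice), "ice years, seed", x$config$seed, "\n")
  invisible(x)
}
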