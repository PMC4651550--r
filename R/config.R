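#' Synthetic study configuration
#'
#' Bundles every parameter of the synthetic data generator. The defaults
#' describe a two-period collaring study in a planar, km-unit projection:
#' an early period with Argos fixes every 3 days and a recent period with
#' daily GPS fixes, land-use probabilities of 0.20 and 0.389, onshore
#' durations of 32.7 +/- 21.1 and 62.6 +/- 20.2 days, onshore arrival around
#' ordinal dates 261 and 241, and a sea-ice edge that leaves southern coasts
#' around day 150 and the northern islands 126 days later. Cohort sizes
#' default to 25 and 15 bear-years, a scale at which a full study runs in a
#' few minutes.
#'
#' @param seed integer master seed; every generated object is a pure
#'   function of `(config, seed)`.
#' @param n_bears_period1,n_bears_period2 bear-years per period.
#' @param ctcrw_beta velocity autocorrelation decay (1/day) used by the
#'   exact movement simulator and as the scale of path deviations.
#' @param ctcrw_sigma velocity diffusion (km/day^1.5).
#' @param fix_interval_days_by_period target days between fixes, per period.
#' @param argos_class_mix_period1 named probabilities over Argos classes
#'   for the early period (recent-period collars report GPS).
#' @param p_land_user_by_period probability a bear-year summers on land.
#' @param mean_days_on_land_by_period,sd_days_on_land_by_period onshore
#'   duration distribution (days) for land-using bears.
#' @param arrival_doy_mean_by_period,arrival_doy_sd_by_period onshore
#'   arrival date distribution (ordinal date).
#' @param land_mass_probs_by_period list of two named probability vectors
#'   over land masses for summering bears.
#' @param denning_prob_by_period probability a bear-year dens.
#' @param den_on_land_prob_by_period probability a den is on land (vs ice).
#' @param den_start_mean,den_start_sd,den_length_mean,den_length_sd denning
#'   interval distribution (study days / days).
#' @param den_temp_offset collar-temperature elevation during denning (C).
#' @param temp_noise_sd daily collar-temperature noise SD (C).
#' @param dropout_prob per-fix transmission failure probability.
#' @param outage_prob,outage_range probability of one long transmission
#'   outage per track and its length range (days), long enough to exercise
#'   the 14-day gap-exclusion rule.
#' @param collar_drop_prob probability the collar drops mid-deployment.
#' @param dev_sd,dev_tau stationary SD (km) and timescale (days) of the
#'   Ornstein-Uhlenbeck positional deviation around the behavioral path.
#' @param ice_retreat_profile_by_period,ice_return_profile_by_period lists
#'   (one per period) with `lat` (km) and `doy` giving the ordinal date the
#'   >=15% ice margin crosses 50 km off a coast at that latitude, on the way
#'   out and back. Coasts north of the profile's latitude range never lose
#'   ice (sentinel dates 365/1). The recent period's defaults retreat ~30
#'   days earlier in the north and ~7 days earlier in the south.
#' @param years_by_period calendar-year indices belonging to each period;
#'   each year gets its own jittered ice stack so across-year regressions
#'   have a spread of ice conditions.
#' @param ice_year_jitter_sd SD (days) of the per-year shift applied to the
#'   ice date profiles.
#' @param grid_cell_km raster cell size (km; default 25).
#' @param grid_nx,grid_ny raster dimensions.
#' @param shelf_max_y northern shelf limit (km).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(
    seed = 1L,
    n_bears_period1 = 25L,
    n_bears_period2 = 15L,
    ctcrw_beta = 0.5,
    ctcrw_sigma = 2,
    fix_interval_days_by_period = c(3, 1),
    argos_class_mix_period1 = c("3" = 0.12, "2" = 0.15, "1" = 0.20,
                                "0" = 0.20, "A" = 0.18, "B" = 0.12,
                                "Z" = 0.03),
    p_land_user_by_period = c(0.20, 0.389),
    mean_days_on_land_by_period = c(32.7, 62.6),
    sd_days_on_land_by_period = c(21.1, 20.2),
    arrival_doy_mean_by_period = c(261, 241),
    arrival_doy_sd_by_period = c(22.7, 20.2),
    land_mass_probs_by_period = list(
      c(wrangel = 0.69, herald = 0.08, alaska = 0.08, chukotka = 0.15),
      c(wrangel = 0.89, herald = 0.06, alaska = 0.05, chukotka = 0.00)),
    denning_prob_by_period = c(0.35, 0.381),
    den_on_land_prob_by_period = c(0.923, 0.84),
    den_start_mean = 335, den_start_sd = 10,
    den_length_mean = 120, den_length_sd = 15,
    den_temp_offset = 12,
    temp_noise_sd = 3,
    dropout_prob = 0.10,
    outage_prob = 0.25,
    outage_range = c(10, 20),
    collar_drop_prob = 0.05,
    dev_sd = 3, dev_tau = 1,
    ice_retreat_profile_by_period = list(
      list(lat = c(0, 1200), doy = c(150, 276)),
      list(lat = c(0, 1200), doy = c(143, 246))),
    ice_return_profile_by_period = list(
      list(lat = c(0, 1200), doy = c(350, 300)),
      list(lat = c(0, 1200), doy = c(356, 310))),
    years_by_period = list(1:6, 7:10),
    ice_year_jitter_sd = 6,
    grid_cell_km = 25,
    grid_nx = 40L,
    grid_ny = 52L,
    shelf_max_y = 900) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_land_user_by_period, cfg$denning_prob_by_period,
             cfg$den_on_land_prob_by_period, cfg$dropout_prob,
             cfg$outage_prob, cfg$collar_drop_prob,
             cfg$argos_class_mix_period1,
             unlist(cfg$land_mass_probs_by_period))
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$ctcrw_beta > 0, cfg$ctcrw_sigma > 0,
            cfg$n_bears_period1 >= 0, cfg$n_bears_period2 >= 0,
            abs(sum(cfg$argos_class_mix_period1) - 1) < 1e-8,
            all(cfg$fix_interval_days_by_period > 0),
            cfg$grid_cell_km > 0)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_bears_period1, "+",
      x$n_bears_period2, "bear-years |",
      "p(land) =", paste(x$p_land_user_by_period, collapse = "/"), "\n")
  invisible(x)
}

#' Default study-area coastline
#'
#' Four land masses in the planar study projection: two southern mainland
#' coasts (`chukotka` west of the strait, `alaska` east of it) and two
#' northern islands (`wrangel`, `herald`). Units are km; the southern coast
#' sits at y = 75 and the islands around y = 1020-1110.
#'
#' @param config a `sim_config` (for the shelf limit).
#' @return a `coast_geometry`.
#' @export
default_coast <- function(config = sim_config()) {
  make_coast(list(
    chukotka = cbind(c(-50, 485, 485, -50), c(-200, -200, 75, 75)),
    alaska   = cbind(c(515, 1050, 1050, 515), c(-200, -200, 75, 75)),
    wrangel  = cbind(c(380, 500, 500, 380), c(1020, 1020, 1100, 1100)),
    herald   = cbind(c(600, 650, 650, 600), c(1060, 1060, 1110, 1110))
  ), buffer_km = 5, shelf_max_y = config$shelf_max_y)
}
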