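test_that("identical seeds reproduce identical tracks and studies", {
  cfg <- small_config(seed = 21)
  t1 <- generate_track(cfg, 2)
  t2 <- generate_track(cfg, 2)
  expect_identical(t1$fixes, t2$fixes)
  expect_identical(t1$truth$daily, t2$truth$daily)
  expect_identical(t1$temperature, t2$temperature)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$tracks[[5]]$fixes, s2$tracks[[5]]$fixes)
  expect_identical(s1$ice[[1]]$conc[, , 200], s2$ice[[1]]$conc[, , 200])
})

test_that("degenerate diffusion with zero initial velocity stays put", {
  set.seed(1)
  tr <- simulate_ctcrw_track(0.5, 0, times = seq(0, 30, by = 1),
                             error_sd_m = 0, start = c(10, -5))
  expect_true(all(abs(tr$truth$daily$x - 10) < 1e-9))
  expect_true(all(abs(tr$truth$daily$y + 5) < 1e-9))
})

test_that("quality classes carry the prescribed accuracies", {
  expect_equal(argos_error_sd(c("3", "2", "1", "0")),
               c(150, 350, 1000, 1500))
  expect_equal(argos_error_sd(c("A", "B", "GPS")), c(5000, 10000, 30))
  expect_true(is.na(argos_error_sd("Z")))
  expect_error(argos_error_sd("Q"), "unknown")
  cfg <- small_config(seed = 9)
  tr <- generate_track(cfg, 1)
  ok <- tr$fixes$class != "Z"
  expect_equal(tr$fixes$error_sd[ok], argos_error_sd(tr$fixes$class[ok]))
})

test_that("observation error is calibrated to the class SD at large n", {
  set.seed(4)
  for (case in list(c(5000, 5), c(150, 5))) {
    tr <- simulate_ctcrw_track(0.5, 2, times = seq(0.1, 1000, length.out = 10000),
                               error_sd_m = case[1])
    err_km <- c(tr$fixes$x - tr$truth$daily$x, tr$fixes$y - tr$truth$daily$y)
    expect_lt(abs(stats::sd(err_km) * 1000 - case[1]) / case[1], 0.05)
  }
})

test_that("track timestamps are strictly increasing and truth aligns", {
  cfg <- small_config(seed = 2)
  for (i in c(1, 4, 9, 12)) {
    tr <- generate_track(cfg, i)
    expect_true(all(diff(tr$fixes$time) > 0))
    expect_true(all(diff(tr$truth$daily$time) == 1))
    expect_s3_class(tr, "bear_track")
  }
})

test_that("generated ice recovers the configured retreat dates (day-scan oracle)", {
  cfg <- sim_config(seed = 31, ice_year_jitter_sd = 0)
  stk <- generate_ice_stack(cfg, 1)
  coast <- default_coast(cfg)
  segs <- coastal_segments(stk, coast)
  prof <- cfg$ice_retreat_profile_by_period[[1]]
  conf_date <- function(lat) stats::approx(prof$lat, prof$doy, lat,
                                           rule = 2)$y
  # one southern segment, one Wrangel segment
  s_south <- segs[which.min(segs$y), ]
  s_north <- segs[segs$label == "wrangel", ][1, ]
  for (s in list(s_south, s_north)) {
    got <- retreat_scan_oracle(s$x, s$y, stk)[1]
    expect_lt(abs(got - conf_date(s$y)), 7.5)
  }
  # two coasts whose configured dates differ by ~100 days
  d_s <- retreat_scan_oracle(s_south$x, s_south$y, stk)[1]
  d_n <- retreat_scan_oracle(s_north$x, s_north$y, stk)[1]
  expect_lt(abs((d_n - d_s) - (conf_date(s_north$y) - conf_date(s_south$y))),
            7.5)
})

test_that("a coast the profile never reaches keeps ice within 50 km all year", {
  cfg <- sim_config(seed = 32, ice_year_jitter_sd = 0,
                    ice_retreat_profile_by_period = list(
                      list(lat = c(0, 800), doy = c(150, 240)),
                      list(lat = c(0, 800), doy = c(143, 230))))
  stk <- generate_ice_stack(cfg, 1)
  coast <- default_coast(cfg)
  segs <- coastal_segments(stk, coast)
  wr <- segs[segs$label == "wrangel", ][1, ]
  expect_equal(unname(retreat_scan_oracle(wr$x, wr$y, stk)), c(365, 1))
  ph <- segment_phenology(stk, coast)
  expect_true(all(ph$retreat_doy[ph$label %in% c("wrangel", "herald")] == 365))
  expect_true(all(ph$return_doy[ph$label %in% c("wrangel", "herald")] == 1))
})

test_that("temperature series carry the denning signature and nothing else", {
  cfg <- sim_config(seed = 5)
  set.seed(11)
  tm0 <- generate_temperature(cfg, NULL)
  base <- -5 + 15 * cos(2 * pi * (ordinal_date(tm0$time) - 196) / 365)
  expect_lt(max(abs(tm0$temp - base)), 5 * cfg$temp_noise_sd)
  # 60-day elevated bout: detector recovers >= 90% overlap
  set.seed(12)
  den <- c(340, 399)
  tm1 <- generate_temperature(cfg, den)
  nond <- replicate(5, generate_temperature(cfg), simplify = FALSE)
  bl <- build_baseline(nond)
  ev <- detect_denning(tm1, bl)
  expect_equal(nrow(ev), 1)
  overlap <- min(ev$end, den[2]) - max(ev$start, den[1]) + 1
  expect_gte(overlap / (den[2] - den[1] + 1), 0.9)
  # zero offset: nothing to find
  cfg0 <- sim_config(seed = 5, den_temp_offset = 0)
  set.seed(12)
  tm2 <- generate_temperature(cfg0, den)
  expect_equal(nrow(detect_denning(tm2, bl)), 0)
})

test_that("the configured land-use probability is realized in truth", {
  study <- cached("study_default_seed101",
                  simulate_study(sim_config(seed = 101)))
  tr <- study$truth
  for (p in 1:2) {
    n <- sum(tr$period == p)
    k <- sum(tr$days_on_land[tr$period == p] > 7)
    pcfg <- study$config$p_land_user_by_period[p]
    ci <- stats::qbinom(c(0.025, 0.975), n, pcfg)
    expect_gte(k, ci[1])
    expect_lte(k, ci[2])
  }
})
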