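test_that("weekly means reduce to per-cell block averages", {
  # constant field: weekly mean identical
  stk <- hand_stack(function(x, y, t) 0.4, days = 1:21)
  wm <- weekly_mean(stk)
  expect_equal(wm$week_start, c(1, 8, 15))
  expect_true(all(abs(wm$grids[[2]] - 0.4) < 1e-12))
  # alternating 0.1/0.3: mean 0.2
  stk2 <- hand_stack(function(x, y, t) ifelse(t %% 2 == 1, 0.1, 0.3),
                     days = 1:14)
  expect_true(all(abs(weekly_mean(stk2)$grids[[1]] - (4 * 0.1 + 3 * 0.3) / 7)
                  < 1e-12))
  # random stack: equals brute-force per-cell mean
  set.seed(6)
  stk3 <- hand_stack(function(x, y, t) 0, days = 1:28)
  stk3$conc <- array(stats::runif(8 * 12 * 28), c(8, 12, 28))
  wm3 <- weekly_mean(stk3)
  for (w in 1:4) {
    bf <- apply(stk3$conc[, , ((w - 1) * 7 + 1):(w * 7)], c(1, 2), mean)
    expect_lt(max(abs(wm3$grids[[w]] - bf)), 1e-12)
  }
  # the final short block is its own week
  stk4 <- hand_stack(function(x, y, t) 0.5, days = 1:365)
  wm4 <- weekly_mean(stk4)
  expect_equal(length(wm4$grids), 53)
  expect_equal(wm4$week_start[53], 365)
})

test_that("the largest contiguous component is selected", {
  g <- matrix(0, 6, 6)
  g[1:2, 1:3] <- 0.5            # 6-cell blob
  expect_equal(sum(pack_ice_component(g)), 6)
  expect_true(all(which(pack_ice_component(g)) ==
                    which(g >= 0.15)))
  # two components of 5 and 3 cells: the 5-cell one wins
  g2 <- matrix(0, 6, 6)
  g2[1, 1:5] <- 0.2
  g2[5:6, c(5, 6)] <- c(0.9, 0.9, 0.9, 0) # 3 cells
  comp <- pack_ice_component(g2)
  expect_equal(sum(comp), 5)
  expect_true(all(comp[1, 1:5]))
  # all below threshold: empty
  expect_equal(sum(pack_ice_component(matrix(0.1, 4, 4))), 0)
  # diagonal touching: one component under 8-connectivity, two under 4
  g3 <- matrix(0, 4, 4)
  g3[1, 1] <- 0.5; g3[2, 2] <- 0.5
  expect_equal(sum(pack_ice_component(g3, connectivity = 8)), 2)
  expect_equal(sum(pack_ice_component(g3, connectivity = 4)), 1)
})

test_that("flood-fill components equal brute-force transitive closure", {
  set.seed(13)
  for (r in 1:60) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    g <- matrix(stats::runif(nx * ny), nx, ny)
    for (conn in c(8, 4)) {
      comp <- pack_ice_component(g, threshold = 0.5, connectivity = conn)
      oracle <- components_by_closure(g >= 0.5, connectivity = conn)
      if (!length(oracle)) {
        expect_equal(sum(comp), 0)
        next
      }
      sizes <- vapply(oracle, nrow, 1L)
      expect_equal(sum(comp), max(sizes))
      # the selected cells are exactly one of the maximal components
      sel <- which(comp, arr.ind = TRUE)
      match_one <- any(vapply(oracle[sizes == max(sizes)], function(o)
        nrow(o) == nrow(sel) &&
          all(paste(o[, 1], o[, 2]) %in% paste(sel[, 1], sel[, 2])),
        logical(1)))
      expect_true(match_one)
    }
  }
})

test_that("retreat and return dates follow the 50-km distance rule", {
  # land row at the bottom; ice edge far (>50 km) in weeks 27-40
  stk <- hand_stack(function(x, y, t) {
    w <- polarland:::week_of_doy(t)
    if (w >= 27 && w <= 40) ifelse(y > 162.5, 0.8, 0) else 0.8
  }, nx = 6, ny = 12, days = 1:365)
  seg <- c(stk$x_centers[3], stk$y_centers[2]) # first water row
  weekly <- weekly_mean(stk)
  rr <- retreat_return_dates(seg[1], seg[2], weekly, stk)
  expect_equal(unname(rr), c(week_start_doy_ <- (27 - 1) * 7 + 1,
                             (41 - 1) * 7 + 1))
  # day-scan oracle agrees
  expect_equal(unname(retreat_scan_oracle(seg[1], seg[2], stk)),
               unname(rr))
  # pack always within 50 km: sentinel (365, 1)
  stk2 <- hand_stack(function(x, y, t) 0.8, nx = 6, ny = 12, days = 1:365)
  rr2 <- retreat_return_dates(seg[1], seg[2], weekly_mean(stk2), stk2)
  expect_equal(unname(rr2), c(365, 1))
  # no ice at all: retreat on day 1, never returns
  stk3 <- hand_stack(function(x, y, t) 0, nx = 6, ny = 12, days = 1:365)
  rr3 <- retreat_return_dates(seg[1], seg[2], weekly_mean(stk3), stk3)
  expect_equal(unname(rr3), c(1, 365))
})

test_that("retreat dates are monotone in distance and threshold", {
  cfg <- sim_config(seed = 41, ice_year_jitter_sd = 0)
  stk <- generate_ice_stack(cfg, 1)
  weekly <- weekly_mean(stk)
  coast <- default_coast(cfg)
  segs <- coastal_segments(stk, coast)
  s <- segs[segs$label == "wrangel", ][1, ]
  # wider distance rule: retreat no earlier
  prev <- -Inf
  for (dk in c(25, 50, 100)) {
    r <- retreat_return_dates(s$x, s$y, weekly, stk, distance_km = dk)[1]
    expect_gte(r, prev)
    prev <- r
  }
  # higher concentration threshold: less ice, retreat never later
  prev <- Inf
  for (th in c(0.15, 0.5, 0.9)) {
    r <- retreat_return_dates(s$x, s$y, weekly, stk, threshold = th)[1]
    expect_lte(r, prev)
    prev <- r
  }
})

test_that("shelf coverage fractions count threshold cells exactly", {
  stk_full <- hand_stack(function(x, y, t) 0.9, days = 210:310)
  expect_equal(shelf_ice_fraction(stk_full), 1)
  stk_none <- hand_stack(function(x, y, t) 0.05, days = 210:310)
  expect_equal(shelf_ice_fraction(stk_none), 0)
  # half the shelf at 0.2 concentration, half bare: 0.5
  stk_half <- hand_stack(function(x, y, t) 0, days = 210:310)
  shelf_cells <- which(stk_half$shelf_mask)
  on <- shelf_cells[seq(1, length(shelf_cells), by = 2)]
  for (k in seq_along(stk_half$dates)) {
    g <- stk_half$conc[, , k]
    g[on] <- 0.2
    stk_half$conc[, , k] <- g
  }
  expect_equal(shelf_ice_fraction(stk_half),
               length(on) / length(shelf_cells))
})
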