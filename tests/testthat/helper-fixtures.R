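# Shared fixture builders. Everything is generated in code at test time.

# a predicted_path-like object built directly from daily positions
make_path <- function(time, x, y, gap_excluded = FALSE, bear_id = "T1",
                      period = 1) {
  out <- data.frame(time = time, doy = ordinal_date(time), x = x, y = y,
                    sd = 0.1, gap_excluded = rep_len(gap_excluded,
                                                     length(time)),
                    observed_support = 1)
  attr(out, "bear_id") <- bear_id
  attr(out, "period") <- period
  class(out) <- c("predicted_path", "data.frame")
  out
}

# single-island coast for geometry tests: 100x100 km square at (0..100)
square_coast <- function(buffer_km = 5) {
  make_coast(list(isle = cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))),
             buffer_km = buffer_km)
}

# a small ice stack built by hand from a per-day concentration function
hand_stack <- function(conc_fun, nx = 8, ny = 12, cell = 25,
                       land_rows = 1, days = 1:365) {
  xc <- (seq_len(nx) - 0.5) * cell
  yc <- (seq_len(ny) - 0.5) * cell
  conc <- array(0, c(nx, ny, length(days)))
  for (k in seq_along(days))
    conc[, , k] <- outer(xc, yc, function(x, y)
      rep_len(conc_fun(x, y, t = days[k]), length(x)))
  land <- matrix(FALSE, nx, ny)
  if (land_rows > 0) land[, seq_len(land_rows)] <- TRUE
  out <- list(dates = days, conc = conc, land_mask = land,
              shelf_mask = !land & col(land) <= ny / 2,
              x_centers = xc, y_centers = yc, cell_km = cell,
              year = 1, period = 1)
  class(out) <- "ice_stack"
  out
}

# small-cohort configuration for fast pipeline tests
small_config <- function(seed = 3, ...) {
  sim_config(seed = seed, n_bears_period1 = 8, n_bears_period2 = 6,
             years_by_period = list(1:2, 3:4), ...)
}

# cache expensive shared fixtures across test files within one run
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}
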