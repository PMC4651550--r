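test_that("Kalman log-likelihood equals the joint-Gaussian density", {
  set.seed(7)
  for (rep in 1:3) {
    times <- sort(stats::runif(6, 0, 12))
    tr <- simulate_ctcrw_track(0.6, 1.8, times, error_sd_m = 800)
    tau2 <- (tr$fixes$error_sd / 1000)^2
    for (par in list(c(0.6, 1.8), c(0.2, 3), c(1.5, 0.7))) {
      ll_kf <- polarland:::ctcrw_loglik(par[1], par[2], times,
                                        tr$fixes$x, tr$fixes$y, tau2)
      ll_bf <- joint_gaussian_loglik(tr$fixes$x, times, par[1], par[2],
                                     tau2, tr$fixes$x[1]) +
        joint_gaussian_loglik(tr$fixes$y, times, par[1], par[2],
                              tau2, tr$fixes$y[1])
      expect_lt(abs(ll_kf - ll_bf), 1e-8)
    }
  }
})

test_that("discrete innovation covariance matches numerical integration", {
  # Var/Cov of (integrated position, velocity) over a gap, from the
  # covariance kernel of the OU velocity started at a known value:
  # cov(v(s), v(u)) = sigma^2/(2 beta) (e^{-b|s-u|} - e^{-b(s+u)})
  beta <- 0.7; sigma <- 1.9; delta <- 2.3
  n <- 2000
  s <- (seq_len(n) - 0.5) * delta / n
  K <- sigma^2 / (2 * beta) *
    (exp(-beta * abs(outer(s, s, "-"))) - exp(-beta * outer(s, s, "+")))
  w <- delta / n
  q_pp_num <- sum(K) * w^2
  q_pv_num <- sum(K[, n] * w) # cov(integral, v(delta)) via last column
  q_vv_num <- sigma^2 / (2 * beta) * (1 - exp(-2 * beta * delta))
  d <- polarland:::ctcrw_discretize(beta, sigma, delta)
  expect_lt(abs(d$q_pp - q_pp_num) / d$q_pp, 1e-3)
  expect_lt(abs(d$q_pv - q_pv_num) / d$q_pv, 1e-2)
  expect_lt(abs(d$q_vv - q_vv_num), 1e-12)
})

test_that("with vanishing measurement error predictions pass through fixes", {
  set.seed(21)
  times <- seq(0, 60, by = 2)
  tr <- simulate_ctcrw_track(0.5, 2, times, error_sd_m = 1)
  fit <- fit_ctcrw(tr)
  sm <- polarland:::ctcrw_smooth_at(fit, times)
  expect_lt(max(abs(sm$x - tr$fixes$x)), 0.01)
  expect_lt(max(abs(sm$y - tr$fixes$y)), 0.01)
  # GPS-class daily prediction lands within 3 x 30 m of the fix
  path <- predict_daily(fit, 0, 60)
  at_obs <- path[path$time %in% times, ]
  expect_lt(max(abs(at_obs$x - tr$fixes$x[match(at_obs$time, times)])), 0.09)
})

test_that("the smoother equals direct Gaussian conditioning", {
  set.seed(5)
  times <- c(0, 2, 5, 6.5, 9, 12)
  tr <- simulate_ctcrw_track(0.8, 1.5, times, error_sd_m = 1000)
  fit <- fit_ctcrw_fixed(tr, beta = 0.8, sigma = 1.5)
  query <- c(1, 3.3, 7, 11)
  sm <- polarland:::ctcrw_smooth_at(fit, query)
  grid <- sort(unique(c(times, query)))
  obs_idx <- match(times, grid)
  tau2 <- (tr$fixes$error_sd / 1000)^2
  for (ax in c("x", "y")) {
    cm <- joint_gaussian_cond_mean(grid, obs_idx, tr$fixes[[ax]], tau2,
                                   0.8, 1.5, tr$fixes[[ax]][1])
    expect_lt(max(abs(sm[[ax]] - cm[match(query, grid)])), 1e-6)
  }
})

test_that("days bracketed by >14-day observation gaps are excluded", {
  set.seed(3)
  fx <- data.frame(time = c(seq(0, 30, by = 2), seq(45, 80, by = 2)),
                   x = 0, y = 0, class = "GPS")
  fx$x <- fx$time * 0.5 + stats::rnorm(nrow(fx), 0, 0.3)
  fx$y <- stats::rnorm(nrow(fx), 0, 0.3)
  tr <- make_track("G1", 2, fx)
  fit <- fit_ctcrw(tr)
  path <- predict_daily(fit, 0, max(fx$time))
  in_gap <- path$time > 30 & path$time < 45
  expect_true(all(path$gap_excluded[in_gap]))
  expect_false(any(path$gap_excluded[path$time <= 30 |
                                       (path$time >= 45 &
                                          path$time <= max(fx$time))]))
  # a 13-day gap is tolerated
  fx2 <- fx; fx2$time <- c(seq(0, 30, by = 2), seq(43, 78, by = 2))
  tr2 <- make_track("G2", 2, fx2)
  path2 <- predict_daily(fit_ctcrw(tr2), 0, max(fx2$time))
  expect_false(any(path2$gap_excluded))
})

test_that("estimates are invariant to shifting the time origin", {
  set.seed(9)
  tr <- simulate_ctcrw_track(0.5, 2, sort(stats::runif(80, 0, 120)),
                             error_sd_m = 500)
  f1 <- fit_ctcrw(tr)
  tr2 <- tr; tr2$fixes$time <- tr2$fixes$time + 1000
  f2 <- fit_ctcrw(tr2)
  expect_equal(f1$beta_hat, f2$beta_hat, tolerance = 1e-8)
  expect_equal(f1$sigma_hat, f2$sigma_hat, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("an extra nearby observation never inflates predictive variance", {
  set.seed(2)
  times <- seq(0, 40, by = 4)
  tr <- simulate_ctcrw_track(0.5, 2, times, error_sd_m = 1000)
  fit <- fit_ctcrw_fixed(tr, 0.5, 2)
  sd_before <- polarland:::ctcrw_smooth_at(fit, 18)$sd
  extra <- rbind(tr$fixes, data.frame(time = 17.5, x = 5, y = 5,
                                      class = "1", error_sd = 1000))
  extra <- extra[order(extra$time), ]
  tr2 <- tr; tr2$fixes <- extra
  fit2 <- fit_ctcrw_fixed(tr2, 0.5, 2)
  sd_after <- polarland:::ctcrw_smooth_at(fit2, 18)$sd
  expect_lte(sd_after, sd_before)
})

test_that("parameters are recovered on exact-simulation tracks", {
  set.seed(77)
  ok <- 0
  for (r in 1:10) {
    tr <- simulate_ctcrw_track(0.5, 2, sort(stats::runif(300, 0, 300)),
                               error_sd_m = 1000)
    f <- fit_ctcrw(tr)
    ok <- ok + (abs(f$beta_hat - 0.5) <= 3 * f$se_beta &&
                  abs(f$sigma_hat - 2) <= 3 * f$se_sigma)
  }
  expect_gte(ok, 9)
})

test_that("degenerate and underdetermined tracks are rejected", {
  fx <- data.frame(time = 1:5, x = 0, y = 0, class = "GPS")
  expect_error(fit_ctcrw(make_track("E1", 2, fx)), "at least 10 fixes")
  fx2 <- data.frame(time = seq(0, 5, length.out = 12), x = 0, y = 0,
                    class = "GPS")
  expect_error(fit_ctcrw(make_track("E2", 2, fx2)), "span")
})
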