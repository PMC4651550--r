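# Independent brute-force oracles used across test files.

# Joint-Gaussian moments of the (position, velocity) state chain at the
# given epochs, built directly from the exact discrete transitions -- no
# Kalman recursion involved.
state_chain_moments <- function(times, beta, sigma, x0, P0v = 1e6) {
  n <- length(times)
  m <- numeric(2 * n)
  S <- matrix(0, 2 * n, 2 * n)
  m[1:2] <- c(x0, 0)
  S[1:2, 1:2] <- diag(c(P0v, P0v))
  for (i in seq_len(n)[-1]) {
    d <- polarland:::ctcrw_discretize(beta, sigma, times[i] - times[i - 1])
    Tm <- matrix(c(1, 0, d$t_pv, d$t_vv), 2, 2)
    Q <- matrix(c(d$q_pp, d$q_pv, d$q_pv, d$q_vv), 2, 2)
    i0 <- 2 * (i - 1) + 1; ip <- 2 * (i - 2) + 1
    m[i0:(i0 + 1)] <- Tm %*% m[ip:(ip + 1)]
    for (j in seq_len(i - 1)) {
      j0 <- 2 * (j - 1) + 1
      blk <- Tm %*% S[ip:(ip + 1), j0:(j0 + 1)]
      S[i0:(i0 + 1), j0:(j0 + 1)] <- blk
      S[j0:(j0 + 1), i0:(i0 + 1)] <- t(blk)
    }
    S[i0:(i0 + 1), i0:(i0 + 1)] <-
      Tm %*% S[ip:(ip + 1), ip:(ip + 1)] %*% t(Tm) + Q
  }
  list(mean = m, cov = S)
}

# Direct multivariate-normal log-density of one axis of observations.
joint_gaussian_loglik <- function(obs, times, beta, sigma, tau2,
                                  x0, P0v = 1e6) {
  mom <- state_chain_moments(times, beta, sigma, x0, P0v)
  n <- length(times)
  H <- matrix(0, n, 2 * n)
  for (i in seq_len(n)) H[i, 2 * (i - 1) + 1] <- 1
  mu <- as.numeric(H %*% mom$mean)
  V <- H %*% mom$cov %*% t(H) + diag(tau2, n)
  L <- chol(V)
  z <- backsolve(L, obs - mu, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z * z)
}

# Conditional mean of the position at query epochs given observations at
# (a subset of) the epochs -- the smoother's answer, by direct Gaussian
# conditioning on the union grid.
joint_gaussian_cond_mean <- function(grid, obs_idx, obs, tau2, beta, sigma,
                                     x0, P0v = 1e6) {
  mom <- state_chain_moments(grid, beta, sigma, x0, P0v)
  n <- length(grid)
  H <- matrix(0, length(obs_idx), 2 * n)
  for (k in seq_along(obs_idx)) H[k, 2 * (obs_idx[k] - 1) + 1] <- 1
  V <- H %*% mom$cov %*% t(H) + diag(tau2, length(obs_idx))
  K <- mom$cov %*% t(H) %*% solve(V)
  post <- mom$mean + as.numeric(K %*% (obs - H %*% mom$mean))
  post[seq(1, 2 * n, by = 2)] # positions
}

# Brute-force connected components by transitive closure on the adjacency
# matrix of TRUE cells (no flood fill involved).
components_by_closure <- function(mask, connectivity = 8) {
  idx <- which(mask, arr.ind = TRUE)
  k <- nrow(idx)
  if (k == 0) return(list())
  A <- diag(k) > 0
  for (a in seq_len(k)) for (b in seq_len(k)) {
    dx <- abs(idx[a, 1] - idx[b, 1]); dy <- abs(idx[a, 2] - idx[b, 2])
    adj <- if (connectivity == 8) max(dx, dy) == 1 else dx + dy == 1
    if (adj) A[a, b] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0 | A
    if (identical(A2, A)) break
    A <- A2
  }
  groups <- unique(apply(A, 1, function(r) paste(which(r), collapse = ",")))
  lapply(groups, function(g) idx[as.integer(strsplit(g, ",")[[1]]), ,
                                 drop = FALSE])
}

# Exact conditional log-likelihood of use-availability strata for a single
# coefficient, maximized by grid/golden search.
cond_loglik_1d <- function(beta, strata, covariate) {
  sum(vapply(split(strata, strata$stratum), function(s) {
    eta <- beta * s[[covariate]]
    eta[s$used == 1] - log(sum(exp(eta)))
  }, numeric(1)))
}

grid_max_clogit_1d <- function(strata, covariate, lower = -2, upper = 2) {
  stats::optimize(function(b) cond_loglik_1d(b, strata, covariate),
                  c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# Day-by-day distance-scan oracle for retreat/return dates, operating on
# weekly grids expanded back to days (the module under test works on the
# same weekly blocks, so the oracle shares the dates but not the code
# path: per-day largest component + exhaustive distance minimum).
retreat_scan_oracle <- function(seg_x, seg_y, stack, distance_km = 50,
                                threshold = 0.15) {
  weekly <- weekly_mean(stack)
  wk <- polarland:::week_of_doy(stack$dates)
  beyond_day <- vapply(seq_along(stack$dates), function(t) {
    g <- weekly$grids[[match(wk[t], sort(unique(wk)))]]
    comp <- pack_ice_component(g, stack$land_mask, threshold)
    idx <- which(comp, arr.ind = TRUE)
    if (!nrow(idx)) return(TRUE)
    dmin <- sqrt(min((stack$x_centers[idx[, 1]] - seg_x)^2 +
                       (stack$y_centers[idx[, 2]] - seg_y)^2))
    dmin > distance_km
  }, logical(1))
  ri <- which(beyond_day)[1]
  if (is.na(ri)) return(c(365, 1))
  bi <- which(!beyond_day & seq_along(beyond_day) > ri)[1]
  c(stack$dates[ri], if (is.na(bi)) 365 else stack$dates[bi])
}
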