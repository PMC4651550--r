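#' Continuous-time correlated random walk (integrated Ornstein-Uhlenbeck)
#'
#' The movement model treats velocity as an Ornstein-Uhlenbeck process with
#' autocorrelation decay `beta` (1/day) and diffusion `sigma` (km/day^1.5);
#' position is the time integral of velocity. Both planar axes share the
#' parameters and are independent. Observed fixes are true positions plus
#' zero-mean Gaussian error whose SD is fixed by the Argos quality class.
#' The model is fitted by maximizing the exact Kalman-filter likelihood over
#' the irregular fix times, and daily positions are predicted by fixed-
#' interval smoothing (conditioning on all fixes).
#'
#' @name ctcrw
NULL

# Exact discrete transition of the (position, velocity) state over a gap of
# delta days: transition matrix entries and innovation covariance. Closed
# forms of the matrix exponential for the integrated OU generator.
ctcrw_discretize <- function(beta, sigma, delta) {
  a <- exp(-beta * delta)
  list(
    t_pv = (1 - a) / beta,      # position gain from velocity
    t_vv = a,                   # velocity decay
    q_pp = sigma^2 / beta^2 * (delta - 2 * (1 - a) / beta + (1 - a^2) / (2 * beta)),
    q_pv = sigma^2 * (1 - a)^2 / (2 * beta^2),
    q_vv = sigma^2 * (1 - a^2) / (2 * beta)
  )
}

# Kalman filter for one axis over a shared epoch grid. Scalar 2-state
# implementation for speed. obs[i] is NA at prediction-only epochs;
# tau2[i] is the measurement variance (km^2) where obs is present.
# Returns the log-likelihood and, if keep = TRUE, the filtered and
# one-step-predicted moments needed by the smoother.
ctcrw_kfilter <- function(times, obs, tau2, beta, sigma, x0, P0, keep = FALSE) {
  n <- length(times)
  mp <- P0 # 2x2
  # state mean (p, v) and covariance entries carried as scalars
  p <- x0[1]; v <- x0[2]
  Ppp <- mp[1, 1]; Ppv <- mp[1, 2]; Pvv <- mp[2, 2]
  ll <- 0
  if (keep) {
    fp <- numeric(n); fv <- numeric(n)
    fPpp <- numeric(n); fPpv <- numeric(n); fPvv <- numeric(n)
    pp <- numeric(n); pv <- numeric(n)
    pPpp <- numeric(n); pPpv <- numeric(n); pPvv <- numeric(n)
    tpv <- numeric(n); tvv <- numeric(n)
  }
  tprev <- times[1]
  for (i in seq_len(n)) {
    delta <- times[i] - tprev
    if (delta > 0) {
      a <- exp(-beta * delta)
      Tpv <- (1 - a) / beta
      qvv <- sigma^2 * (1 - a^2) / (2 * beta)
      qpv <- sigma^2 * (1 - a)^2 / (2 * beta^2)
      qpp <- sigma^2 / beta^2 * (delta - 2 * (1 - a) / beta + (1 - a^2) / (2 * beta))
      # x <- T x ; P <- T P T' + Q
      p <- p + Tpv * v
      v <- a * v
      nPpp <- Ppp + 2 * Tpv * Ppv + Tpv^2 * Pvv + qpp
      nPpv <- a * (Ppv + Tpv * Pvv) + qpv
      nPvv <- a^2 * Pvv + qvv
      Ppp <- nPpp; Ppv <- nPpv; Pvv <- nPvv
    } else {
      Tpv <- 0; a <- 1
    }
    if (keep) {
      pp[i] <- p; pv[i] <- v
      pPpp[i] <- Ppp; pPpv[i] <- Ppv; pPvv[i] <- Pvv
      tpv[i] <- Tpv; tvv[i] <- a
    }
    if (!is.na(obs[i])) {
      S <- Ppp + tau2[i]
      if (!is.finite(S) || S <= 0) { ll <- -Inf; break }
      e <- obs[i] - p
      ll <- ll - 0.5 * (log(2 * pi * S) + e * e / S)
      kp <- Ppp / S; kv <- Ppv / S
      p <- p + kp * e
      v <- v + kv * e
      nPpp <- (1 - kp) * Ppp
      nPpv <- (1 - kp) * Ppv
      nPvv <- Pvv - kv * Ppv
      Ppp <- nPpp; Ppv <- nPpv; Pvv <- nPvv
    }
    if (keep) {
      fp[i] <- p; fv[i] <- v
      fPpp[i] <- Ppp; fPpv[i] <- Ppv; fPvv[i] <- Pvv
    }
    tprev <- times[i]
  }
  if (!keep) return(list(loglik = ll))
  list(loglik = ll, fp = fp, fv = fv, fPpp = fPpp, fPpv = fPpv, fPvv = fPvv,
       pp = pp, pv = pv, pPpp = pPpp, pPpv = pPpv, pPvv = pPvv,
       tpv = tpv, tvv = tvv)
}

# Rauch-Tung-Striebel smoother on the output of ctcrw_kfilter(keep = TRUE).
# Returns smoothed position mean and variance per epoch.
ctcrw_ksmooth <- function(kf) {
  n <- length(kf$fp)
  sp <- numeric(n); sv <- numeric(n); sPpp <- numeric(n)
  sp[n] <- kf$fp[n]; sv[n] <- kf$fv[n]
  Spp <- kf$fPpp[n]; Spv <- kf$fPpv[n]; Svv <- kf$fPvv[n]
  sPpp[n] <- Spp
  for (i in (n - 1):1) {
    if (n == 1) break
    j <- i + 1
    # C = P_f[i] T' ; G = C %*% solve(P_pred[j])
    Tpv <- kf$tpv[j]; a <- kf$tvv[j]
    c11 <- kf$fPpp[i] + Tpv * kf$fPpv[i]   # cov(p_i, p_j^pred)
    c12 <- a * kf$fPpv[i]                  # cov(p_i, v_j^pred)
    c21 <- kf$fPpv[i] + Tpv * kf$fPvv[i]   # cov(v_i, p_j^pred)
    c22 <- a * kf$fPvv[i]
    # invert 2x2 predicted covariance
    d <- kf$pPpp[j] * kf$pPvv[j] - kf$pPpv[j]^2
    i11 <- kf$pPvv[j] / d; i12 <- -kf$pPpv[j] / d; i22 <- kf$pPpp[j] / d
    g11 <- c11 * i11 + c12 * i12; g12 <- c11 * i12 + c12 * i22
    g21 <- c21 * i11 + c22 * i12; g22 <- c21 * i12 + c22 * i22
    dp <- sp[j] - kf$pp[j]; dv <- sv[j] - kf$pv[j]
    sp[i] <- kf$fp[i] + g11 * dp + g12 * dv
    sv[i] <- kf$fv[i] + g21 * dp + g22 * dv
    # smoothed covariance (position entry only needed downstream, but the
    # recursion requires the full 2x2)
    e11 <- Spp - kf$pPpp[j]; e12 <- Spv - kf$pPpv[j]; e22 <- Svv - kf$pPvv[j]
    nSpp <- kf$fPpp[i] + g11 * (e11 * g11 + e12 * g12) + g12 * (e12 * g11 + e22 * g12)
    nSpv <- kf$fPpv[i] + g11 * (e11 * g21 + e12 * g22) + g12 * (e12 * g21 + e22 * g22)
    nSvv <- kf$fPvv[i] + g21 * (e11 * g21 + e12 * g22) + g22 * (e12 * g21 + e22 * g22)
    Spp <- nSpp; Spv <- nSpv; Svv <- nSvv
    sPpp[i] <- Spp
  }
  list(p = sp, v = sv, var_p = sPpp)
}

ctcrw_loglik <- function(beta, sigma, times, x, y, tau2, P0v = 1e6) {
  x0x <- c(x[which(!is.na(x))[1]], 0)
  x0y <- c(y[which(!is.na(y))[1]], 0)
  P0 <- matrix(c(P0v, 0, 0, P0v), 2)
  ctcrw_kfilter(times, x, tau2, beta, sigma, x0x, P0)$loglik +
    ctcrw_kfilter(times, y, tau2, beta, sigma, x0y, P0)$loglik
}

#' Fit the CTCRW movement model to a filtered track
#'
#' Maximum-likelihood estimation of the velocity autocorrelation decay
#' `beta` (1/day) and diffusion `sigma` (km/day^1.5) by numerical
#' optimization of the exact Kalman-filter likelihood on log-transformed
#' parameters, with three starting points to avoid boundary traps. Per-class
#' measurement SDs are fixed constants taken from the track, not estimated.
#' The initial state is the first fix position with zero velocity and a
#' diffuse covariance (1e6 km^2 per component).
#'
#' @param track a `bear_track` (see [make_track()]); needs at least 10 fixes
#'   spanning at least 20 days.
#' @param n_starts number of optimizer starting points.
#' @return a `ctcrw_fit` with elements `beta_hat`, `sigma_hat`, `loglik`,
#'   `se` (delta-method SEs of beta and sigma), `converged`, and the data
#'   needed for prediction.
#' @export
fit_ctcrw <- function(track, n_starts = 3) {
  fx <- track$fixes
  stopifnot(is.data.frame(fx))
  if (nrow(fx) < 10) stop("need at least 10 fixes to fit the CTCRW model")
  if (diff(range(fx$time)) < 20) stop("fixes must span at least 20 days")
  if (any(diff(fx$time) <= 0)) stop("fix times must be strictly increasing")
  times <- fx$time
  tau2 <- (fx$error_sd / 1000)^2 # m -> km
  # moment-based starting scale: displacement variance per unit time
  dt <- diff(times); dd <- sqrt(diff(fx$x)^2 + diff(fx$y)^2)
  v_scale <- stats::median(dd / pmax(dt, 1 / 24))
  sig0 <- max(v_scale, 0.5)
  starts <- list(c(log(0.5), log(sig0)),
                 c(log(2), log(sig0 * 2)),
                 c(log(0.1), log(sig0 / 2)))[seq_len(n_starts)]
  nll <- function(theta) {
    b <- exp(theta[1]); s <- exp(theta[2])
    if (!is.finite(b) || !is.finite(s) || b > 1e4 || s > 1e4) return(1e10)
    ll <- ctcrw_loglik(b, s, times, fx$x, fx$y, tau2)
    if (!is.finite(ll)) return(1e10) else -ll
  }
  best <- NULL
  for (st in starts) {
    op <- stats::optim(st, nll, method = "Nelder-Mead",
                       control = list(reltol = 1e-10, maxit = 500))
    if (is.null(best) || op$value < best$value) best <- op
  }
  # Wald SEs on the natural scale via numerical Hessian + delta method
  H <- stats::optimHess(best$par, nll)
  se <- rep(NA_real_, 2)
  ok <- all(is.finite(H)) && det(H) > 0
  if (ok) {
    V <- solve(H)
    se <- sqrt(pmax(diag(V), 0)) * exp(best$par) # d(exp(t))/dt = exp(t)
  }
  out <- list(beta_hat = exp(best$par[1]), sigma_hat = exp(best$par[2]),
              se_beta = se[1], se_sigma = se[2],
              loglik = -best$value,
              converged = best$convergence == 0 && is.finite(best$value),
              track = track, tau2 = tau2)
  class(out) <- "ctcrw_fit"
  out
}

#' Construct a CTCRW fit with known parameters
#'
#' Bypasses estimation and returns a `ctcrw_fit` holding the supplied
#' parameters, for prediction and smoothing with externally fixed values
#' (simulation checks, sensitivity analyses).
#'
#' @inheritParams fit_ctcrw
#' @param beta,sigma fixed parameter values (> 0).
#' @return a converged `ctcrw_fit`.
#' @export
fit_ctcrw_fixed <- function(track, beta, sigma) {
  stopifnot(beta > 0, sigma > 0)
  fx <- track$fixes
  tau2 <- (fx$error_sd / 1000)^2
  ll <- ctcrw_loglik(beta, sigma, fx$time, fx$x, fx$y, tau2)
  out <- list(beta_hat = beta, sigma_hat = sigma,
              se_beta = NA_real_, se_sigma = NA_real_, loglik = ll,
              converged = TRUE, track = track, tau2 = tau2)
  class(out) <- "ctcrw_fit"
  out
}

#' @export
print.ctcrw_fit <- function(x, ...) {
  cat("CTCRW fit:", x$track$bear_id, "\n")
  cat(sprintf("  beta  = %.4f /day (SE %.4f)\n", x$beta_hat, x$se_beta))
  cat(sprintf("  sigma = %.4f km/day^1.5 (SE %.4f)\n", x$sigma_hat, x$se_sigma))
  cat(sprintf("  loglik = %.3f  converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

# Smoothed position at arbitrary epochs: augment the fix grid with the
# requested times (as prediction-only epochs), filter + RTS-smooth both axes.
ctcrw_smooth_at <- function(fit, at) {
  fx <- fit$track$fixes
  grid <- sort(unique(c(fx$time, at)))
  n <- length(grid)
  obs_x <- rep(NA_real_, n); obs_y <- rep(NA_real_, n); tau2 <- rep(NA_real_, n)
  idx <- match(fx$time, grid)
  obs_x[idx] <- fx$x; obs_y[idx] <- fx$y; tau2[idx] <- fit$tau2
  P0 <- diag(c(1e6, 1e6))
  kx <- ctcrw_kfilter(grid, obs_x, tau2, fit$beta_hat, fit$sigma_hat,
                      c(fx$x[1], 0), P0, keep = TRUE)
  ky <- ctcrw_kfilter(grid, obs_y, tau2, fit$beta_hat, fit$sigma_hat,
                      c(fx$y[1], 0), P0, keep = TRUE)
  sx <- ctcrw_ksmooth(kx); sy <- ctcrw_ksmooth(ky)
  j <- match(at, grid)
  data.frame(time = at, x = sx$p[j], y = sy$p[j],
             sd = sqrt(pmax(sx$var_p[j], 0) + pmax(sy$var_p[j], 0)) / sqrt(2),
             var_x = pmax(sx$var_p[j], 0), var_y = pmax(sy$var_p[j], 0))
}

#' Predict regular daily positions from a fitted CTCRW model
#'
#' Smoothed (conditioned on all fixes) daily positions at 00:00 on each
#' calendar day in `[start, end]`, with per-day position SD. Days whose
#' bracketing observed fixes are more than `max_gap_days` apart are flagged
#' `gap_excluded`; these stay in the table so gap coverage can be reported,
#' but downstream land-day counts skip them. Days outside the observed time
#' range are also flagged (no bracketing support).
#'
#' @param fit a converged `ctcrw_fit`.
#' @param start,end first and last study-time day to predict (integers).
#' @param max_gap_days gap-exclusion threshold in days (default 14).
#' @return a `predicted_path`: data frame with `time`, `doy`, `x`, `y`,
#'   `sd`, `gap_excluded`, `observed_support`.
#' @export
predict_daily <- function(fit, start, end, max_gap_days = 14) {
  stopifnot(inherits(fit, "ctcrw_fit"))
  if (!isTRUE(fit$converged)) stop("CTCRW fit did not converge")
  days <- seq(floor(start), floor(end))
  sm <- ctcrw_smooth_at(fit, days)
  ft <- fit$track$fixes$time
  prev_obs <- findInterval(days, ft)            # index of last fix <= day
  next_obs <- length(ft) - findInterval(-days, rev(-ft)) + 1 # first fix >= day
  gap <- rep(TRUE, length(days))
  inside <- prev_obs >= 1 & next_obs <= length(ft)
  gap[inside] <- (ft[pmin(next_obs[inside], length(ft))] -
                    ft[pmax(prev_obs[inside], 1)]) > max_gap_days
  sup <- pmin(abs(days - ft[pmax(prev_obs, 1)]),
              abs(ft[pmin(next_obs, length(ft))] - days))
  out <- data.frame(time = days, doy = ordinal_date(days),
                    x = sm$x, y = sm$y, sd = sm$sd,
                    gap_excluded = gap, observed_support = sup)
  attr(out, "bear_id") <- fit$track$bear_id
  attr(out, "period") <- fit$track$period
  class(out) <- c("predicted_path", "data.frame")
  out
}
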