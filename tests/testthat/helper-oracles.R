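# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (prefix-sum OLS, vectorized RK4 factors) so that
# agreement is evidence, not tautology.

# closed-form biomass/substrate/CER of the piecewise batch model
oracle_trajectory <- function(t, mu, lag, x0, s0, y_sx, y_cx, m_co2,
                              t_pellet = Inf, r = 0, decay = 0.15) {
  x_max <- x0 + y_sx * s0
  tex_exp <- lag + log(x_max / x0) / mu
  if (is.finite(t_pellet) && t_pellet < tex_exp) {
    x_p <- x0 * exp(mu * (t_pellet - lag))
    tex <- t_pellet + (x_max - x_p) / r
  } else {
    t_pellet <- Inf
    x_p <- NA_real_
    tex <- tex_exp
  }
  x <- ifelse(t < lag, x0,
       ifelse(t < min(t_pellet, tex), x0 * exp(mu * (t - lag)),
       ifelse(t < tex, x_p + r * (t - t_pellet), x_max)))
  dx <- ifelse(t < lag, 0,
        ifelse(t < min(t_pellet, tex), mu * x,
        ifelse(t < tex, r, 0)))
  act <- ifelse(t >= tex, exp(-decay * (t - tex)), 1)
  cer_g <- y_cx * dx + m_co2 * x * act
  list(x = x, s = pmax(s0 - (x - x0) / y_sx, 0), cer_g = cer_g,
       cer_mmol = cer_g / 44.0095 * 1000, t_exhaust = tex)
}

# brute-force Euler-free ODE integration (plain RK4 loop at a small step),
# used to corroborate the closed-form exhaustion time
oracle_exhaustion_rk4 <- function(mu, lag, x0, s0, y_sx, dt = 0.005) {
  x <- x0
  t <- lag
  x_max <- x0 + y_sx * s0
  f <- function(x) mu * x
  while (x < x_max && t < 1000) {
    k1 <- f(x); k2 <- f(x + dt * k1 / 2)
    k3 <- f(x + dt * k2 / 2); k4 <- f(x + dt * k3)
    x_new <- x + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    if (x_new >= x_max) {
      return(t + dt * (x_max - x) / (x_new - x))
    }
    x <- x_new
    t <- t + dt
  }
  t
}

# exhaustive enumeration of all contiguous windows; OLS through cor()/cov(),
# a different route than the package's cumulative sums
oracle_best_window <- function(t, y, r2_min, min_points, anchored = FALSE) {
  n <- length(t)
  best <- NULL
  starts <- if (anchored) 1L else seq_len(n)
  for (a in starts) {
    if (a + min_points - 1 > n) next
    for (b in seq(a + min_points - 1, n)) {
      tt <- t[a:b]; yy <- y[a:b]
      r2 <- if (stats::var(yy) == 0) 1 else stats::cor(tt, yy)^2
      if (r2 >= r2_min) {
        len <- b - a + 1
        if (is.null(best) || len > best$len) {
          best <- list(len = len, a = a, b = b,
                       slope = stats::cov(tt, yy) / stats::var(tt), r2 = r2)
        }
      }
    }
  }
  best
}

# brute-force scan for the earliest run of k samples above a threshold
oracle_lag_scan <- function(co2, t, thr, k) {
  for (i in seq_len(length(co2) - k + 1)) {
    if (all(co2[i:(i + k - 1)] > thr)) return(t[i])
  }
  NA_real_
}

# noise-free twin of a run's detected lag end (same rule on the clean signal)
true_lag_end <- function(run, threshold_pct, k_consecutive = 3) {
  gas <- run$off_gas
  gas$co2_pct <- gas$co2_pct_true
  detect_lag_end(gas, threshold_pct, k_consecutive)
}

zero_noise <- function(config) {
  config$offgas_cv <- 0
  config$dw_sd <- 0
  config$glucose_sd <- 0
  config$replicate_cv <- 0
  config
}
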