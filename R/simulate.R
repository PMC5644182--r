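#' Configuration for a synthetic batch fermentation
#'
#' Bundles the kinetic parameters, reactor settings, sampling schedules and
#' noise levels of a simulated submerged batch cultivation. Defaults emulate a
#' 1 L stirred reactor (0.9 L working volume) on a defined medium with
#' 15 g/L glucose, sparged with air ramped from 0.1 to 0.9 vvm over the first
#' 1200 min, inoculated with a spore suspension (about 1e9 spores/L, i.e. a
#' few mg dry weight per litre).
#'
#' The growth model is piecewise: biomass is constant during the lag phase;
#' grows exponentially at `mu_max` from the end of the lag; optionally
#' switches at `t_pellet_h` (pellet/clump formation) to constant-rate linear
#' accretion `nonexp_rate`; and stops when the substrate is exhausted, after
#' which the metabolically active fraction decays at `starvation_decay`.
#' CO2 evolution is `y_cx * dX/dt + m_co2 * X_active`.
#'
#' @param mu_max Maximum specific growth rate (1/h).
#' @param lag_h Lag-phase duration (h).
#' @param x0 Initial viable biomass (g DW/L).
#' @param s0 Initial substrate (g/L).
#' @param y_sx Biomass yield on substrate (g DW/g).
#' @param y_cx CO2 yield on biomass formed (g CO2/g DW).
#' @param m_co2 Maintenance CO2 coefficient (g CO2/g DW/h).
#' @param t_pellet_h Transition time to the non-exponential regime (h), or
#'   `NULL` for fully dispersed growth (no transition).
#' @param nonexp_rate Constant biomass accretion rate after the transition
#'   (g DW/L/h). Ignored when `t_pellet_h` is `NULL`.
#' @param starvation_decay First-order decay rate of metabolically active
#'   biomass after substrate exhaustion (1/h); shapes the post-peak CO2 decline.
#' @param inlet_co2_pct CO2 content of the inlet air (% v/v).
#' @param airflow_start_vvm,airflow_end_vvm,airflow_ramp_min Linear airflow
#'   ramp (vvm over minutes); constant afterwards.
#' @param volume_l Working volume (L).
#' @param offgas_interval_min Off-gas logging interval (min).
#' @param t_end_h End of the simulated run (h); `NULL` = substrate exhaustion
#'   of the nominal parameters plus 15 h.
#' @param dw_times,glucose_times Sampling times (h) for dry weight and
#'   glucose; `NULL` = every 2 h from 6 h until shortly after exhaustion,
#'   with glucose drawn from the same broth samples as dry weight.
#' @param offgas_cv Multiplicative (lognormal) CV of the off-gas CO2 signal.
#' @param dw_sd,glucose_sd Additive Gaussian SD of dry weight / glucose
#'   samples (g/L), truncated at 0.
#' @param replicate_cv Between-replicate lognormal CV applied to `mu_max`
#'   and `lag_h`.
#' @param seed Integer root seed; replicate streams are derived from
#'   `(seed, replicate)` so replicates are independent but reproducible.
#' @return A `sim_config` object (named list).
#' @seealso [simulate_run()], [simulate_triplicate()]
#' @export
sim_config <- function(mu_max = 0.2, lag_h = 14, x0 = 0.003, s0 = 15,
                       y_sx = 0.5, y_cx = 1.0, m_co2 = 0.02,
                       t_pellet_h = NULL, nonexp_rate = 0.08,
                       starvation_decay = 0.15, inlet_co2_pct = 0.04,
                       airflow_start_vvm = 0.1, airflow_end_vvm = 0.9,
                       airflow_ramp_min = 1200, volume_l = 0.9,
                       offgas_interval_min = 6, t_end_h = NULL,
                       dw_times = NULL, glucose_times = NULL,
                       offgas_cv = 0.01, dw_sd = 0.1, glucose_sd = 0.1,
                       replicate_cv = 0.05, seed = 1L) {
  cfg <- list(
    mu_max = mu_max, lag_h = lag_h, x0 = x0, s0 = s0, y_sx = y_sx,
    y_cx = y_cx, m_co2 = m_co2,
    t_pellet_h = if (is.null(t_pellet_h)) Inf else t_pellet_h,
    nonexp_rate = nonexp_rate, starvation_decay = starvation_decay,
    inlet_co2_pct = inlet_co2_pct,
    airflow_start_vvm = airflow_start_vvm, airflow_end_vvm = airflow_end_vvm,
    airflow_ramp_min = airflow_ramp_min, volume_l = volume_l,
    offgas_interval_min = offgas_interval_min, t_end_h = t_end_h,
    dw_times = dw_times, glucose_times = glucose_times,
    offgas_cv = offgas_cv, dw_sd = dw_sd, glucose_sd = glucose_sd,
    replicate_cv = replicate_cv, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) abort(msg, class = "fermkin_config_error")
  if (!(cfg$mu_max > 0)) stop_cfg("`mu_max` must be > 0.")
  if (!(cfg$y_sx > 0 && cfg$y_sx <= 1.5)) stop_cfg("`y_sx` must be in (0, 1.5].")
  if (!(cfg$s0 > 0)) stop_cfg("`s0` must be > 0.")
  if (!(cfg$x0 > 0)) stop_cfg("`x0` must be > 0.")
  if (cfg$lag_h < 0) stop_cfg("`lag_h` must be >= 0.")
  if (cfg$offgas_interval_min <= 0) stop_cfg("off-gas interval must be > 0.")
  if (cfg$offgas_cv < 0 || cfg$dw_sd < 0 || cfg$glucose_sd < 0 ||
      cfg$replicate_cv < 0) stop_cfg("noise levels must be >= 0.")
  if (is.finite(cfg$t_pellet_h)) {
    if (cfg$t_pellet_h <= cfg$lag_h)
      stop_cfg("`t_pellet_h` must fall after the lag phase.")
    if (!(cfg$nonexp_rate > 0))
      stop_cfg("`nonexp_rate` must be > 0 when a pellet transition is set.")
  }
  if (!(cfg$volume_l > 0)) stop_cfg("`volume_l` must be > 0.")
  if (cfg$airflow_start_vvm <= 0 || cfg$airflow_end_vvm <= 0)
    stop_cfg("airflow must be > 0.")
  invisible(cfg)
}

# one-step RK4 growth factor for dX/dt = mu * X over step h
rk4_growth_factor <- function(mu, h) {
  z <- mu * h
  1 + z + z^2 / 2 + z^3 / 6 + z^4 / 24
}

# biomass at arbitrary times in the exponential regime by fixed-step RK4
# (step h, fractional final step), vectorized over `tau` = time since lag end
rk4_exp_biomass <- function(x0, mu, tau, h) {
  k <- floor(tau / h + 1e-12)
  rem <- pmax(tau - k * h, 0)
  x0 * rk4_growth_factor(mu, h)^k * rk4_growth_factor(mu, rem)
}

# regime breakpoints of the piecewise growth model, in closed form
sim_events <- function(cfg, mu = cfg$mu_max, lag = cfg$lag_h) {
  x_max <- cfg$x0 + cfg$y_sx * cfg$s0
  tp <- cfg$t_pellet_h
  t_exhaust_exp <- lag + log(x_max / cfg$x0) / mu
  if (is.finite(tp) && tp < t_exhaust_exp) {
    x_p <- cfg$x0 * exp(mu * (tp - lag))
    t_exhaust <- tp + (x_max - x_p) / cfg$nonexp_rate
  } else {
    tp <- Inf
    x_p <- NA_real_
    t_exhaust <- t_exhaust_exp
  }
  exp_end <- min(tp, t_exhaust)
  # CER just before the end of each growth regime (g CO2/L/h); the global
  # CO2 maximum sits at substrate exhaustion iff the maintenance-driven climb
  # during the non-exponential phase exceeds the CER drop at the transition
  cer_exp_end <- (cfg$y_cx * mu + cfg$m_co2) * cfg$x0 * exp(mu * (exp_end - lag))
  if (is.finite(tp)) {
    cer_exhaust <- cfg$y_cx * cfg$nonexp_rate + cfg$m_co2 * x_max
    t_co2max <- if (cer_exhaust >= cer_exp_end) t_exhaust else tp
  } else {
    t_co2max <- t_exhaust
  }
  list(x_max = x_max, t_pellet = tp, x_pellet = x_p, t_exhaust = t_exhaust,
       exp_end = exp_end, t_co2max = t_co2max,
       nonexp_duration = max(t_co2max - exp_end, 0))
}

# deterministic trajectory at arbitrary times: biomass, substrate, CER
# integration: fixed-step RK4 at 1/10 of the off-gas interval within each
# regime (the regime ODEs are linear, so the one-step map is a constant
# growth factor); regime boundaries located in closed form
sim_trajectory <- function(cfg, times, mu = cfg$mu_max, lag = cfg$lag_h) {
  ev <- sim_events(cfg, mu, lag)
  h <- cfg$offgas_interval_min / 60 / 10
  x <- rep(cfg$x0, length(times))
  dx <- rep(0, length(times))
  active <- rep(1, length(times))

  in_exp <- times >= lag & times < min(ev$t_pellet, ev$t_exhaust)
  x[in_exp] <- rk4_exp_biomass(cfg$x0, mu, times[in_exp] - lag, h)
  dx[in_exp] <- mu * x[in_exp]

  if (is.finite(ev$t_pellet)) {
    in_lin <- times >= ev$t_pellet & times < ev$t_exhaust
    x[in_lin] <- ev$x_pellet + cfg$nonexp_rate * (times[in_lin] - ev$t_pellet)
    dx[in_lin] <- cfg$nonexp_rate
  }
  done <- times >= ev$t_exhaust
  x[done] <- ev$x_max
  active[done] <- exp(-cfg$starvation_decay * (times[done] - ev$t_exhaust))

  s <- pmax(cfg$s0 - (x - cfg$x0) / cfg$y_sx, 0)
  cer_g <- cfg$y_cx * dx + cfg$m_co2 * x * active   # g CO2/L/h
  if (any(x < 0) || any(s < -1e-9)) {
    abort("negative concentration during integration (step-size contract violated)",
          class = "fermkin_internal_error")
  }
  tibble(time_h = times, biomass_gl = x, substrate_gl = s,
         cer_g_l_h = cer_g, cer_mmol_l_h = cer_g / MW_CO2 * 1000)
}

# airflow profile (vvm) at time t (hours)
airflow_at <- function(cfg, t_h) {
  ramp_h <- cfg$airflow_ramp_min / 60
  frac <- pmin(pmax(t_h / ramp_h, 0), 1)
  cfg$airflow_start_vvm + (cfg$airflow_end_vvm - cfg$airflow_start_vvm) * frac
}

# exhaust CO2 percentage implied by a volumetric CER (mmol/L broth/h)
cer_to_pct <- function(cer_mmol, vvm, inlet_pct) {
  inlet_pct + cer_mmol / 1000 * MOLAR_VOLUME_25C / (vvm * 60) * 100
}

derive_seed <- function(seed, replicate) {
  as.integer((as.numeric(seed) * 1009 + replicate * 7919) %% 2147483647)
}

#' Simulate one batch fermentation run
#'
#' Generates a complete synthetic bioreactor run: noisy off-gas CO2/O2 series,
#' sparse dry-weight and glucose sample tables, and the exact ground truth of
#' the underlying growth model. Identical `(config, replicate)` always gives
#' identical output.
#'
#' @param config A [sim_config()].
#' @param replicate Replicate index (>= 1); combined with `config$seed` to
#'   derive the replicate's random stream and its realized `mu_max`/`lag_h`
#'   (perturbed by `replicate_cv`).
#' @return A `fermentation_run` object: a list with tibbles `off_gas`
#'   (`time_h, co2_pct, co2_pct_true, o2_pct, airflow_vvm, volume_l`),
#'   `dry_weight` (`time_h, dw_gl`), `glucose` (`time_h, glucose_gl`), the
#'   one-row tibble `truth` (see [ground_truth()]) and metadata `meta`.
#' @examples
#' run <- simulate_run(sim_config(seed = 42))
#' ground_truth(run)
#' @export
simulate_run <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (replicate < 1) abort("`replicate` must be >= 1.", class = "fermkin_config_error")
  set.seed(derive_seed(config$seed, replicate))

  # replicate-level biological variability on mu and lag (mean-1 lognormal)
  if (config$replicate_cv > 0) {
    s <- sqrt(log(1 + config$replicate_cv^2))
    mu <- config$mu_max * exp(rnorm(1) * s - s^2 / 2)
    lag <- config$lag_h * exp(rnorm(1) * s - s^2 / 2)
  } else {
    mu <- config$mu_max
    lag <- config$lag_h
  }

  ev_nom <- sim_events(config)   # schedules are config-driven, shared by replicates
  t_end <- config$t_end_h %||% (ev_nom$t_exhaust + 15)
  if (ev_nom$t_exhaust <= config$lag_h)
    abort("substrate exhausted before the lag phase ends; adjust config.",
          class = "fermkin_config_error")

  dt <- config$offgas_interval_min / 60
  t_gas <- seq(0, t_end, by = dt)
  traj <- sim_trajectory(config, t_gas, mu = mu, lag = lag)
  vvm <- airflow_at(config, t_gas)
  pct_true <- cer_to_pct(traj$cer_mmol_l_h, vvm, config$inlet_co2_pct)
  pct <- pct_true
  if (config$offgas_cv > 0) {
    sln <- sqrt(log(1 + config$offgas_cv^2))
    noise <- rlnorm(length(t_gas), meanlog = -sln^2 / 2, sdlog = sln)
    pct <- config$inlet_co2_pct + (pct_true - config$inlet_co2_pct) * noise
  }
  o2 <- 20.95 - (pct - config$inlet_co2_pct)   # mirrored signal, RQ ~ 1

  dw_t <- config$dw_times %||% seq(6, min(t_end, ev_nom$t_exhaust + 4), by = 2)
  glc_t <- config$glucose_times %||% dw_t   # one broth sample serves both assays
  traj_dw <- sim_trajectory(config, dw_t, mu = mu, lag = lag)
  traj_glc <- sim_trajectory(config, glc_t, mu = mu, lag = lag)
  dw <- pmax(traj_dw$biomass_gl + rnorm(length(dw_t), 0, config$dw_sd), 0)
  glc <- pmax(traj_glc$substrate_gl + rnorm(length(glc_t), 0, config$glucose_sd), 0)

  ev <- sim_events(config, mu = mu, lag = lag)
  truth <- tibble(
    replicate = as.integer(replicate),
    mu_max = mu, lag_h = lag,
    exp_end_h = ev$exp_end,
    t_co2max_h = ev$t_co2max,
    nonexp_duration_h = ev$nonexp_duration,
    final_biomass_gl = ev$x_max,
    t_exhaust_h = ev$t_exhaust
  )

  structure(list(
    off_gas = tibble(time_h = t_gas, co2_pct = pct, co2_pct_true = pct_true,
                     o2_pct = o2, airflow_vvm = vvm,
                     volume_l = config$volume_l),
    dry_weight = tibble(time_h = dw_t, dw_gl = dw),
    glucose = tibble(time_h = glc_t, glucose_gl = glc),
    truth = truth,
    meta = list(config = config, replicate = as.integer(replicate),
                mu_realized = mu, lag_realized = lag)
  ), class = "fermentation_run")
}

#' Simulate a biological triplicate
#'
#' Three runs sharing the configured sampling grids, with replicate-level
#' `mu_max` and `lag_h` perturbed by `replicate_cv` (zero CV gives three
#' identical runs).
#'
#' @inheritParams simulate_run
#' @return List of three `fermentation_run` objects.
#' @export
simulate_triplicate <- function(config) {
  lapply(1:3, function(i) simulate_run(config, replicate = i))
}

#' Ground truth of a simulated run
#'
#' @param run A `fermentation_run` from [simulate_run()].
#' @return One-row tibble: realized `mu_max` and `lag_h`, `exp_end_h`,
#'   `t_co2max_h`, `nonexp_duration_h`, `final_biomass_gl`, `t_exhaust_h`.
#' @export
ground_truth <- function(run) {
  stopifnot(inherits(run, "fermentation_run"))
  run$truth
}

#' @export
print.fermentation_run <- function(x, ...) {
  cfg <- x$meta$config
  cat(sprintf("<fermentation_run> replicate %d | mu = %.3f /h, lag = %.1f h\n",
              x$meta$replicate, x$meta$mu_realized, x$meta$lag_realized))
  cat(sprintf("  off-gas: %d samples every %.0f min to %.1f h\n",
              nrow(x$off_gas), cfg$offgas_interval_min, max(x$off_gas$time_h)))
  cat(sprintf("  dry weight: %d samples; glucose: %d samples\n",
              nrow(x$dry_weight), nrow(x$glucose)))
  cat(sprintf("  truth: exp end %.2f h, CO2 max %.2f h, non-exp %.2f h\n",
              x$truth$exp_end_h, x$truth$t_co2max_h, x$truth$nonexp_duration_h))
  invisible(x)
}
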