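fast_cfg <- function(...) {
  args <- utils::modifyList(
    list(x0 = 0.01, lag_h = 15, replicate_cv = 0, offgas_cv = 0,
         dw_sd = 0, glucose_sd = 0),
    list(...))
  do.call(sim_config, args)
}

test_that("zero-noise dry weight follows the exponential model exactly", {
  cfg <- fast_cfg(mu_max = 0.2, dw_times = c(20, 25))
  run <- simulate_run(cfg)
  expect_equal(run$dry_weight$dw_gl[2] / run$dry_weight$dw_gl[1],
               exp(0.2 * 5), tolerance = 1e-9)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(mu_max = -0.1), class = "fermkin_config_error")
  expect_error(sim_config(y_sx = 2), class = "fermkin_config_error")
  expect_error(sim_config(s0 = 0), class = "fermkin_config_error")
  expect_error(sim_config(offgas_interval_min = 0), class = "fermkin_config_error")
  expect_error(sim_config(t_pellet_h = 5, lag_h = 10), class = "fermkin_config_error")
})

test_that("runs without a pellet transition have zero non-exponential truth", {
  run <- simulate_run(fast_cfg())
  expect_equal(ground_truth(run)$nonexp_duration_h, 0)
  expect_equal(ground_truth(run)$exp_end_h, ground_truth(run)$t_exhaust_h)
})

test_that("substrate exhaustion matches the closed form and an RK4 oracle", {
  cfg <- fast_cfg(mu_max = 0.2, s0 = 15, y_sx = 0.5)
  tex <- ground_truth(simulate_run(cfg))$t_exhaust_h
  closed <- 15 + log(1 + 0.5 * 15 / 0.01) / 0.2
  expect_equal(tex, closed, tolerance = 1e-9)
  expect_equal(oracle_exhaustion_rk4(0.2, 15, 0.01, 15, 0.5), closed,
               tolerance = 1e-4)
})

test_that("zero-noise tables are mutually mass-balanced at every sample", {
  cfg <- fast_cfg(mu_max = 0.25, y_sx = 0.58)
  run <- simulate_run(cfg)
  growth <- run$dry_weight$dw_gl > 0.02 & run$glucose$glucose_gl > 0.01
  gain <- run$dry_weight$dw_gl[growth] - 0.01
  consumed <- 15 - run$glucose$glucose_gl[growth]
  expect_equal(gain / consumed, rep(0.58, sum(growth)), tolerance = 1e-6)
})

test_that("biomass is non-decreasing and substrate non-increasing", {
  run <- simulate_run(fast_cfg(t_pellet_h = 30, nonexp_rate = 0.1))
  expect_true(all(diff(run$dry_weight$dw_gl) >= -1e-12))
  expect_true(all(diff(run$glucose$glucose_gl) <= 1e-12))
})

test_that("identical (config, replicate) reproduces byte-identical runs", {
  cfg <- sim_config(seed = 99)
  r1 <- simulate_run(cfg, replicate = 2)
  r2 <- simulate_run(cfg, replicate = 2)
  expect_identical(r1$off_gas, r2$off_gas)
  expect_identical(r1$dry_weight, r2$dry_weight)
  expect_identical(r1$truth, r2$truth)
})

test_that("simulated trajectory matches the closed-form oracle, incl. pellet regime", {
  cfg <- fast_cfg(mu_max = 0.22, y_cx = 0.5, m_co2 = 0.04,
                  t_pellet_h = 36, nonexp_rate = 0.075, lag_h = 12)
  run <- simulate_run(cfg)
  t <- run$off_gas$time_h
  or <- oracle_trajectory(t, 0.22, 12, 0.01, 15, 0.5, 0.5, 0.04,
                          t_pellet = 36, r = 0.075)
  cer_pkg <- compute_cer(dplyr::mutate(run$off_gas, co2_pct = co2_pct_true),
                         inlet_co2_pct = 0.04)
  expect_equal(cer_pkg$cer_mmol_l_h, or$cer_mmol, tolerance = 1e-6)
  expect_equal(ground_truth(run)$t_exhaust_h, or$t_exhaust, tolerance = 1e-8)
})

test_that("fixed-step integration is insensitive to a 10x finer step", {
  co <- fast_cfg(offgas_interval_min = 6)
  fi <- fast_cfg(offgas_interval_min = 0.6,
                 t_end_h = NULL)
  t_probe <- c(20, 30, 40, 45)
  x_co <- simulate_run(co)$off_gas
  x_fi <- simulate_run(fi)$off_gas
  v_co <- x_co$co2_pct_true[match(t_probe, x_co$time_h)]
  v_fi <- x_fi$co2_pct_true[match(t_probe, x_fi$time_h)]
  expect_equal(v_co, v_fi, tolerance = 1e-3)
})

test_that("triplicates share grids; zero replicate CV gives identical runs", {
  runs <- simulate_triplicate(fast_cfg())
  expect_identical(runs[[1]]$off_gas$time_h, runs[[2]]$off_gas$time_h)
  expect_identical(runs[[1]]$dry_weight$time_h, runs[[3]]$dry_weight$time_h)
  truths <- lapply(runs, function(r) ground_truth(r)[-1])  # drop replicate id
  expect_identical(truths[[1]], truths[[2]])
  expect_identical(truths[[1]], truths[[3]])
})

test_that("between-replicate variability realizes the configured CV", {
  cfg <- sim_config(replicate_cv = 0.05, t_end_h = 30,
                    dw_times = c(10, 20), seed = 7)
  mus <- unlist(lapply(1:200, function(i) {
    cfg$seed <- 1000L + i
    vapply(simulate_triplicate(cfg), function(r) ground_truth(r)$mu_max,
           numeric(1))
  }))
  cv <- sd(mus) / mean(mus)
  expect_lt(abs(cv - 0.05) / 0.05, 0.20)
})

test_that("planted features land at the [M+H]+ m/z of their compound", {
  lib <- compound_library(tibble::tibble(name = "griseofulvin",
                                         formula = "C17H17ClO6"))
  ft <- simulate_feature_tables(
    tibble::tibble(name = "griseofulvin", area = 1e6, intensity = 2e4),
    lib, n_noise = 0, dropout = 0, mz_jitter_ppm = 0, seed = 3)
  expect_length(ft$tables, 3)
  for (tb in ft$tables) {
    expect_equal(nrow(tb), 1)
    expect_equal(tb$mz, 353.078642, tolerance = 1e-6)  # frozen reference
  }
})

test_that("feature-table dropout and noise placement behave as configured", {
  lib <- compound_library(tibble::tibble(
    name = c("a", "b", "c", "d", "e"),
    monoisotopic_mass = c(200.1, 300.2, 400.3, 500.4, 600.5)))
  planted <- tibble::tibble(name = lib$name, area = 1e6, intensity = 2e4)
  full <- simulate_feature_tables(planted, lib, n_noise = 0, dropout = 0,
                                  seed = 1)
  expect_true(all(vapply(full$tables, nrow, integer(1)) == 5))
  none <- simulate_feature_tables(planted, lib, n_noise = 4, dropout = 1,
                                  seed = 1)
  expect_true(all(vapply(none$tables, nrow, integer(1)) == 4))
  expect_true(all(grepl("^N", unlist(lapply(none$tables, `[[`, "feature_id")))))
  # noise masses keep their guaranteed separation from all library adducts
  adducts <- c(outer(lib$monoisotopic_mass,
                     c(1.00727647, 22.98922070, 18.03382555), `+`))
  for (tb in none$tables) {
    sep <- vapply(tb$mz, function(m) min(abs(m - adducts) / m * 1e6), numeric(1))
    expect_true(all(sep >= 30))
  }
})
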