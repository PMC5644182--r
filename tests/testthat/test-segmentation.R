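gas_of <- function(t, co2) {
  tibble::tibble(time_h = t, co2_pct = co2, airflow_vvm = 0.9, volume_l = 0.9)
}

test_that("lag detection follows the consecutive-threshold rule", {
  expect_equal(detect_lag_end(gas_of(0:4, c(1, 2, 7, 8, 9)), 6, 2), 2)
  expect_true(is.na(detect_lag_end(gas_of(0:4, c(7, 1, 7, 1, 7)), 6, 2)))
  # run shorter than k does not fire even if a later longer run exists
  expect_equal(detect_lag_end(gas_of(0:6, c(7, 7, 1, 7, 7, 7, 7)), 6, 3), 3)
})

test_that("lag detection equals a brute-force scan on random 0/10 sequences", {
  set.seed(11)
  for (i in 1:40) {
    co2 <- sample(c(0, 10), 15, replace = TRUE)
    thr <- sample(c(3, 6, 9), 1)
    k <- sample(1:4, 1)
    t <- seq(0, 14) / 2
    expect_identical(detect_lag_end(gas_of(t, co2), thr, k),
                     oracle_lag_scan(co2, t, thr, k))
  }
})

test_that("a pure exponential yields the full range, exact slope and R2 = 1", {
  t <- seq(2, 12, by = 0.5)
  cer <- tibble::tibble(time_h = t, cer_mmol_l_h = NA_real_,
                        acc_co2_mmol_l = 3 * exp(0.25 * t))
  for (anchor in c(TRUE, FALSE)) {
    fit <- fit_exponential_window(cer, anchor = anchor)
    expect_equal(fit$start_h, 2)
    expect_equal(fit$end_h, 12)
    expect_equal(fit$slope, 0.25, tolerance = 1e-10)
    expect_equal(fit$r2, 1, tolerance = 1e-12)
  }
})

test_that("window selection equals exhaustive enumeration on short series", {
  set.seed(23)
  for (i in 1:60) {
    n <- sample(6:20, 1)
    t <- sort(runif(n, 0, 10))
    kind <- i %% 3
    y <- if (kind == 0) cumsum(rnorm(n, 0.2, 0.3)) else
         if (kind == 1) 0.3 * t + rnorm(n, 0, 0.05) else
         c(0.5 * t[t <= 5], 2.5 + 0.05 * (t[t > 5] - 5)) + rnorm(n, 0, 0.02)
    cer <- tibble::tibble(time_h = t, cer_mmol_l_h = NA_real_,
                          acc_co2_mmol_l = exp(y))
    for (anchored in c(FALSE, TRUE)) {
      oracle <- oracle_best_window(t, y, 0.99, 3, anchored = anchored)
      got <- tryCatch(
        fit_exponential_window(cer, r2_min = 0.99, min_points = 3,
                               anchor = anchored),
        fermkin_no_window = function(e) NULL)
      if (is.null(oracle)) {
        expect_null(got)
      } else {
        expect_equal(got$start_h, t[oracle$a])
        expect_equal(got$end_h, t[oracle$b])
        expect_equal(got$slope, oracle$slope, tolerance = 1e-8)
      }
    }
  }
})

test_that("failing windows report the best achieved fit", {
  set.seed(5)
  t <- 1:10
  cer <- tibble::tibble(time_h = t, cer_mmol_l_h = NA_real_,
                        acc_co2_mmol_l = exp(rnorm(10, 0, 2)))
  err <- tryCatch(fit_exponential_window(cer, r2_min = 0.9999),
                  fermkin_no_window = function(e) conditionMessage(e))
  expect_match(err, "best: .*R2")
})

test_that("CO2 maximum honors smoothing, refinement and earliest-tie rule", {
  t <- seq(0, 10, by = 0.5)
  uni <- exp(-(t - 6.5)^2)
  expect_equal(find_co2_max(gas_of(t, uni), smooth_window_h = 1), 6.5)
  twin <- c(0, 1, 5, 1, 0, 1, 5, 1, 0, rep(0, 12))
  expect_equal(find_co2_max(gas_of(t, twin), smooth_window_h = 0), 1)
  # noisy vs clean argmax within 2 sampling intervals
  cfg <- sim_config(x0 = 0.01, replicate_cv = 0, seed = 31)
  run <- simulate_run(cfg)
  clean <- dplyr::mutate(run$off_gas, co2_pct = co2_pct_true)
  expect_lte(abs(find_co2_max(run$off_gas, 1) - find_co2_max(clean, 1)),
             2 * 0.1)
})

test_that("noise-free pelleted run: exponential fit ends at the transition", {
  sc <- scenario_config("pelleted-DM")
  run <- simulate_run(zero_noise(sc$config))
  seg <- segment_run(run, threshold_pct = sc$params$threshold_pct)
  dt <- sc$config$offgas_interval_min / 60
  expect_lte(abs(seg$exp_end_h - 40), dt)
  # the anchored window is short here (threshold near half peak), so the
  # slope is a plausibility check, not a precision claim
  expect_equal(seg$fit$slope, 0.2, tolerance = 0.1)
})

test_that("noise-free dispersed run segments with zero non-exponential phase", {
  sc <- scenario_config("dispersed-DM")
  run <- simulate_run(zero_noise(sc$config))
  seg <- segment_run(run, threshold_pct = sc$params$threshold_pct)
  expect_lte(seg$nonexp_duration_h, sc$config$offgas_interval_min / 60)
  expect_gte(seg$fit$r2, 0.99)
  expect_equal(co2_rate(seg), 0.2, tolerance = 0.01)
})

test_that("segmentation is idempotent under truncation past the CO2 maximum", {
  sc <- scenario_config("dispersed-DM", seed = 4)
  run <- simulate_run(sc$config)
  seg_full <- segment_run(run, threshold_pct = sc$params$threshold_pct)
  cut <- dplyr::filter(run$off_gas, time_h <= seg_full$t_co2max_h + 3)
  seg_cut <- segment_run(cut, threshold_pct = sc$params$threshold_pct)
  expect_equal(tidy(seg_cut), tidy(seg_full))
})

test_that("segmentation failures are structured and stage-labelled", {
  flat <- gas_of(seq(0, 5, 0.5), rep(0.05, 11))
  err <- tryCatch(segment_run(flat, threshold_pct = 6),
                  fermkin_segmentation_error = function(e) e)
  expect_s3_class(err, "fermkin_segmentation_error")
  expect_equal(err$stage, "lag")
})

test_that("tidiers expose the segmentation and fit as tibbles", {
  sc <- scenario_config("dispersed-DM", seed = 2)
  seg <- segment_run(simulate_run(sc$config),
                     threshold_pct = sc$params$threshold_pct)
  row <- tidy(seg)
  expect_named(row, c("lag_end_h", "exp_start_h", "exp_end_h", "t_co2max_h",
                      "nonexp_duration_h", "co2_rate_h", "r2", "n_points"))
  expect_equal(nrow(row), 1)
  expect_equal(glance(seg$fit)$slope, row$co2_rate_h)
  expect_equal(tidy(seg$fit)$estimate[2], row$co2_rate_h)
})
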