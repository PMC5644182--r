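#' Maximum specific growth rate from dry-weight samples
#'
#' Ordinary least squares of `ln(dry weight)` against time on the samples
#' inside the growth window (semi-logarithmic regression). The estimate is
#' reported only when at least `min_points` samples fall in the window and
#' the fit reaches `r2_min`; otherwise the result is flagged absent — sparse
#' dry-weight sampling during a short exponential phase is the typical cause,
#' in which case the CO2 production rate is the usable alternative.
#'
#' @param dw Tibble with `time_h` and `dw_gl` (g DW/L).
#' @param window Numeric length-2: growth-window start and end (h).
#' @param r2_min Minimum R-squared to accept the fit (default 0.96).
#' @param min_points Minimum samples in the window (default 3).
#' @param min_dw_gl Quantification floor (g/L); in-window samples below it
#'   are not used (0 disables the floor).
#' @return One-row tibble: `mu` (1/h), `mu_r2`, `mu_n`, `flag`
#'   (`NA` when accepted, otherwise `"n<3"`-style reason). `mu` is `NA` when
#'   flagged.
#' @examples
#' dw <- tibble::tibble(time_h = c(10, 12, 14),
#'                      dw_gl = exp(0.2 * c(10, 12, 14)))
#' mu_from_dryweight(dw, window = c(10, 14))
#' @export
mu_from_dryweight <- function(dw, window, r2_min = 0.96, min_points = 3,
                              min_dw_gl = 0) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  inside <- dw$time_h >= window[1] & dw$time_h <= window[2]
  if (min_dw_gl > 0) inside <- inside & dw$dw_gl >= min_dw_gl
  t <- dw$time_h[inside]
  x <- dw$dw_gl[inside]
  if (any(x <= 0)) {
    abort("non-positive dry weight inside the growth window.",
          class = "fermkin_kinetics_error")
  }
  absent <- function(flag) tibble(mu = NA_real_, mu_r2 = NA_real_,
                                  mu_n = length(t), flag = flag)
  if (length(t) < min_points) return(absent(sprintf("n<%d", min_points)))
  fit <- stats::lm(log(x) ~ t)
  y <- log(x)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  if (r2 < r2_min) return(absent(sprintf("R2<%.2f", r2_min)))
  tibble(mu = unname(stats::coef(fit)[2]), mu_r2 = r2, mu_n = length(t),
         flag = NA_character_)
}

# nearest sample to `at` within `tol` hours; NA when none qualifies
nearest_sample <- function(time_h, value, at, tol) {
  d <- abs(time_h - at)
  i <- which.min(d)
  if (!length(i) || d[i] > tol) return(NA_real_)
  value[i]
}

#' Biomass yield on substrate over the growth phase
#'
#' The ratio between the biomass gain and the substrate consumption across
#' the growth window, `(DW_end - DW_start) / (S_start - S_end)`, with window
#' endpoints matched to the nearest sample of each series.
#'
#' @param dw Tibble `time_h`, `dw_gl`.
#' @param glucose Tibble `time_h`, `glucose_gl`.
#' @param window Growth window `(start_h, end_h)`; the default pipeline uses
#'   lag end to the CO2 maximum.
#' @param match_tol_h Maximum distance (h) between a window endpoint and the
#'   sample used for it.
#' @return Yield in g DW per g substrate.
#' @examples
#' dw <- tibble::tibble(time_h = c(10, 40), dw_gl = c(0.5, 5))
#' glc <- tibble::tibble(time_h = c(10, 40), glucose_gl = c(15, 6))
#' yield_sx(dw, glc, window = c(10, 40)) # 0.5
#' @export
yield_sx <- function(dw, glucose, window, match_tol_h = 2) {
  stopifnot(length(window) == 2, window[1] < window[2])
  dw_start <- nearest_sample(dw$time_h, dw$dw_gl, window[1], match_tol_h)
  dw_end <- nearest_sample(dw$time_h, dw$dw_gl, window[2], match_tol_h)
  s_start <- nearest_sample(glucose$time_h, glucose$glucose_gl, window[1], match_tol_h)
  s_end <- nearest_sample(glucose$time_h, glucose$glucose_gl, window[2], match_tol_h)
  if (anyNA(c(dw_start, dw_end, s_start, s_end))) {
    abort(sprintf("no sample within %.3g h of a window endpoint.", match_tol_h),
          class = "fermkin_kinetics_error")
  }
  if (s_start <= s_end) {
    abort("no measurable substrate consumption over the window.",
          class = c("fermkin_kinetics_error", "fermkin_no_consumption"))
  }
  (dw_end - dw_start) / (s_start - s_end)
}

#' Maximum CO2 production rate from an accepted exponential fit
#'
#' The slope of `ln(accumulated CO2)` against time over the exponential
#' window (1/h). During balanced exponential growth the CO2 evolution rate is
#' proportional to biomass, so this slope estimates the maximum specific
#' growth rate without dry-weight samples.
#'
#' @param fit An `exp_window_fit` from [fit_exponential_window()] or a
#'   `phase_segmentation`.
#' @return Rate (1/h).
#' @export
co2_rate <- function(fit) {
  if (inherits(fit, "phase_segmentation")) fit <- fit$fit
  stopifnot(inherits(fit, "exp_window_fit"))
  fit$slope
}

#' Summarize replicate values
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation across replicates; `NA` values are excluded but counted.
#'
#' @param values Numeric vector (one value per replicate; `NA` = absent).
#' @return One-row tibble: `mean`, `sd`, `n`, `cv`, `n_missing`. With a
#'   single value `sd`/`cv` are `NA`; with none, all statistics are `NA`.
#' @examples
#' summarize_replicates(c(0.20, 0.22, 0.24))
#' @export
summarize_replicates <- function(values) {
  ok <- values[!is.na(values)]
  n <- length(ok)
  if (n == 0) {
    return(tibble(mean = NA_real_, sd = NA_real_, n = 0L, cv = NA_real_,
                  n_missing = length(values)))
  }
  m <- mean(ok)
  s <- if (n > 1) sd(ok) else NA_real_
  tibble(mean = m, sd = s, n = n,
         cv = if (!is.na(s) && m != 0) s / m else NA_real_,
         n_missing = length(values) - n)
}

#' Kinetic characteristics of one segmented run
#'
#' Combines the segmentation with the sparse sample tables: maximum specific
#' growth rate from dry weight over the exponential window, CO2 production
#' rate from the accepted fit, and biomass yield on substrate over the growth
#' phase (lag end to CO2 maximum). Absent values are flagged, never imputed.
#'
#' @param run A `fermentation_run` (or a list with `dry_weight`, `glucose`).
#' @param seg The run's [segment_run()] result.
#' @param mu_r2_min Acceptance R-squared for the dry-weight fit.
#' @param min_dw_gl Dry-weight quantification floor (g/L) for the mu fit.
#' @param match_tol_h Endpoint matching tolerance for the yield.
#' @return One-row tibble: `mu`, `mu_r2`, `mu_n`, `co2_rate_h`, `y_sx`,
#'   `lag_end_h`, `nonexp_duration_h`, `flag`.
#' @export
analyze_run <- function(run, seg, mu_r2_min = 0.96, min_dw_gl = 0.2,
                        match_tol_h = 2) {
  stopifnot(inherits(seg, "phase_segmentation"))
  mu <- mu_from_dryweight(run$dry_weight,
                          window = c(seg$exp_start_h, seg$exp_end_h),
                          r2_min = mu_r2_min, min_dw_gl = min_dw_gl)
  ysx <- tryCatch(
    yield_sx(run$dry_weight, run$glucose,
             window = c(seg$lag_end_h, seg$t_co2max_h),
             match_tol_h = match_tol_h),
    fermkin_kinetics_error = function(e) NA_real_)
  dplyr::bind_cols(
    mu,
    tibble(co2_rate_h = co2_rate(seg), y_sx = ysx,
           lag_end_h = seg$lag_end_h,
           nonexp_duration_h = seg$nonexp_duration_h)
  )
}

#' Summarize kinetics across replicates
#'
#' @param results Tibble of per-run [analyze_run()] rows (one per replicate).
#' @return Tibble with one row per parameter (`mu`, `co2_rate_h`, `y_sx`,
#'   `lag_end_h`, `nonexp_duration_h`) and columns `mean`, `sd`, `n`, `cv`,
#'   `n_missing`.
#' @export
summarize_triplicate <- function(results) {
  params <- c("mu", "co2_rate_h", "y_sx", "lag_end_h", "nonexp_duration_h")
  purrr::map_dfr(params, function(p) {
    dplyr::bind_cols(tibble(parameter = p),
                     summarize_replicates(results[[p]]))
  })
}
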