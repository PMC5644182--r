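#' Detect the end of the lag phase from off-gas CO2
#'
#' The lag phase ends at the first sample of the earliest run of at least
#' `k_consecutive` consecutive off-gas samples with CO2 above
#' `threshold_pct`. The 6% default mirrors common practice on signals that
#' peak near or above that level; pick a threshold commensurate with the
#' signal scale of your reactor/airflow combination.
#'
#' @param gas Off-gas tibble (`time_h`, `co2_pct`, `airflow_vvm`).
#' @param threshold_pct CO2 threshold (% v/v), strictly exceeded.
#' @param k_consecutive Minimum run length of qualifying samples.
#' @return Time (h) of the lag-phase end, or `NA_real_` when no qualifying
#'   run exists (never a silent 0).
#' @examples
#' gas <- tibble::tibble(time_h = 0:4, co2_pct = c(1, 2, 7, 8, 9),
#'                       airflow_vvm = 0.9)
#' detect_lag_end(gas, threshold_pct = 6, k_consecutive = 2) # 2
#' @export
detect_lag_end <- function(gas, threshold_pct = 6, k_consecutive = 3) {
  validate_offgas(gas)
  if (k_consecutive < 1) abort("`k_consecutive` must be >= 1.",
                               class = "fermkin_config_error")
  if (threshold_pct <= 0) abort("`threshold_pct` must be > 0.",
                                class = "fermkin_config_error")
  over <- gas$co2_pct > threshold_pct
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k_consecutive)
  if (!length(hit)) return(NA_real_)
  gas$time_h[starts[hit[1]]]
}

# OLS statistics of y ~ x for all windows sharing a fixed start, via
# cumulative sums; returns slope/intercept/r2 vectors indexed by window end
cumulative_ols <- function(x, y) {
  n <- length(x)
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x^2); cxy <- cumsum(x * y); cyy <- cumsum(y^2)
  m <- seq_len(n)
  ssx <- cxx - cx^2 / m
  ssy <- cyy - cy^2 / m
  sxy <- cxy - cx * cy / m
  slope <- ifelse(ssx > 0, sxy / ssx, NA_real_)
  r2 <- ifelse(ssy > 0, sxy^2 / (ssx * ssy), 1)
  list(slope = slope, intercept = cy / m - slope * cx / m, r2 = r2)
}

new_exp_window_fit <- function(start_h, end_h, n, slope, intercept, r2,
                               r2_min, min_points, anchor) {
  structure(list(start_h = start_h, end_h = end_h, n = n, slope = slope,
                 intercept = intercept, r2 = r2, r2_min = r2_min,
                 min_points = min_points, anchor = anchor),
            class = "exp_window_fit")
}

#' Fit the exponential-growth window on log accumulated CO2
#'
#' Ordinary least squares of `ln(acc CO2)` against time over a contiguous
#' sample window; the accepted window must reach `r2_min` and contain at
#' least `min_points` samples, and its slope is the maximum CO2 production
#' rate (1/h).
#'
#' Two selection modes are available. With `anchor = TRUE` (the default, and
#' what [segment_run()] uses) the window starts at the first sample at or
#' after `after_h` — in practice the detected lag end — and extends to the
#' latest end still satisfying the fit criteria; this pins the fit to the
#' early exponential rise and localizes the kink where exponential growth
#' stops. With `anchor = FALSE` all contiguous windows starting at or after
#' `after_h` compete, and the longest one satisfying the criteria wins (ties
#' broken by earliest start); on signals with a long, slowly-curving
#' post-exponential regime this free search can prefer that regime, which is
#' why it is not the default.
#'
#' @param cer CER tibble (from [compute_cer()]); `acc_co2_mmol_l` is computed
#'   via [accumulate_co2()] when missing.
#' @param after_h Earliest admissible window start (h).
#' @param before_h Latest admissible window end (h), e.g. the CO2 maximum.
#' @param r2_min Minimum R-squared of the accepted fit.
#' @param min_points Minimum number of samples in the window.
#' @param anchor See Details.
#' @return An `exp_window_fit` with `start_h`, `end_h`, `n`, `slope` (1/h),
#'   `intercept`, `r2`. Errors with class `"fermkin_no_window"` (reporting
#'   the best achieved length and R-squared) when no window qualifies.
#' @seealso [co2_rate()], [segment_run()]
#' @export
fit_exponential_window <- function(cer, after_h = 0, before_h = Inf,
                                   r2_min = 0.99, min_points = 3,
                                   anchor = TRUE) {
  if (!(r2_min > 0 && r2_min < 1)) abort("`r2_min` must be in (0, 1).",
                                         class = "fermkin_config_error")
  if (min_points < 3) abort("`min_points` must be >= 3.",
                            class = "fermkin_config_error")
  if (!("acc_co2_mmol_l" %in% names(cer))) cer <- accumulate_co2(cer)
  keep <- cer$time_h >= after_h & cer$time_h <= before_h &
    cer$acc_co2_mmol_l > 0
  t <- cer$time_h[keep]
  y <- log(cer$acc_co2_mmol_l[keep])
  n <- length(t)
  if (n < min_points) {
    abort(sprintf("no window: only %d usable points at or after %.3g h.", n, after_h),
          class = "fermkin_no_window")
  }

  best <- NULL
  best_seen <- c(len = 0, r2 = -Inf)
  starts <- if (anchor) 1L else seq_len(n - min_points + 1L)
  for (a in starts) {
    ols <- cumulative_ols(t[a:n], y[a:n])
    m <- seq_len(n - a + 1L)
    ok <- which(m >= min_points & ols$r2 >= r2_min)
    cand_r2 <- ols$r2[m >= min_points]
    if (length(cand_r2)) {
      j_best <- which.max(cand_r2)
      if (cand_r2[j_best] > best_seen["r2"]) {
        best_seen <- c(len = j_best + min_points - 1L, r2 = cand_r2[j_best])
      }
    }
    if (length(ok)) {
      j <- max(ok)   # longest qualifying end for this start
      if (is.null(best) || j > best$len) {
        best <- list(len = j, a = a, slope = ols$slope[j],
                     intercept = ols$intercept[j], r2 = ols$r2[j])
      }
    }
  }
  if (is.null(best)) {
    abort(sprintf(
      "no contiguous window met R2 >= %.3g with >= %d points (best: %d points, R2 = %.4f).",
      r2_min, min_points, best_seen["len"], best_seen["r2"]),
      class = "fermkin_no_window")
  }
  b <- best$a + best$len - 1L
  new_exp_window_fit(start_h = t[best$a], end_h = t[b], n = best$len,
                     slope = best$slope, intercept = best$intercept,
                     r2 = best$r2, r2_min = r2_min, min_points = min_points,
                     anchor = anchor)
}

#' Locate the CO2 off-gas maximum
#'
#' Finds the time of the maximum exhaust CO2. The signal is first smoothed
#' with a centered moving average (noise rejection), then the raw maximum is
#' taken within one smoothing window of the smoothed maximum, so the sharp
#' rise-then-crash corner at substrate exhaustion is located exactly on clean
#' signals. Ties resolve to the earliest time.
#'
#' @param gas Off-gas tibble.
#' @param smooth_window_h Moving-average window (h); 0 disables smoothing.
#' @param refine Take the raw argmax near the smoothed argmax (default TRUE).
#' @return Time (h) of the CO2 maximum.
#' @export
find_co2_max <- function(gas, smooth_window_h = 1, refine = TRUE) {
  validate_offgas(gas)
  sm <- moving_average_time(gas$time_h, gas$co2_pct, smooth_window_h)
  i0 <- which.max(sm)
  if (!refine || smooth_window_h <= 0) return(gas$time_h[i0])
  nb <- which(abs(gas$time_h - gas$time_h[i0]) <= smooth_window_h)
  gas$time_h[nb[which.max(gas$co2_pct[nb])]]
}

#' Segment a fermentation run into growth phases
#'
#' Composes the rule-based pipeline: lag-phase end from consecutive
#' above-threshold CO2 samples ([detect_lag_end()]), exponential window on
#' log accumulated CO2 anchored at the lag end and capped at the CO2 maximum
#' ([fit_exponential_window()]), CO2 maximum ([find_co2_max()]), and the
#' non-exponential-phase duration as the time from the end of the
#' exponential fit to the CO2 maximum, floored at 0.
#'
#' @param run A `fermentation_run` or an off-gas tibble.
#' @param threshold_pct,k_consecutive Lag detection rule, see
#'   [detect_lag_end()].
#' @param r2_min,min_points Exponential-fit acceptance, see
#'   [fit_exponential_window()].
#' @param smooth_window_h Smoothing for the CO2 maximum.
#' @param inlet_co2_pct Inlet CO2 (% v/v) subtracted in the gas balance.
#' @param anchor Window-selection mode, see [fit_exponential_window()].
#' @return A `phase_segmentation` object with fields `lag_end_h`,
#'   `exp_start_h`, `exp_end_h`, `t_co2max_h`, `nonexp_duration_h` and the
#'   accepted `fit`. Errors carry class `"fermkin_segmentation_error"` and a
#'   `stage` field (`"lag"`, `"exponential_fit"`).
#' @examples
#' run <- simulate_run(sim_config(seed = 1))
#' seg <- segment_run(run, threshold_pct = 0.1)
#' tidy(seg)
#' @export
segment_run <- function(run, threshold_pct = 6, k_consecutive = 3,
                        r2_min = 0.99, min_points = 3, smooth_window_h = 1,
                        inlet_co2_pct = 0.04, anchor = TRUE) {
  gas <- if (inherits(run, "fermentation_run")) run$off_gas else run
  validate_offgas(gas)

  lag_end <- detect_lag_end(gas, threshold_pct, k_consecutive)
  if (is.na(lag_end)) {
    abort(sprintf(
      "lag not detected: no run of %d consecutive samples above %.3g%% CO2.",
      k_consecutive, threshold_pct),
      class = c("fermkin_segmentation_error", "fermkin_no_lag"),
      stage = "lag")
  }
  t_max <- find_co2_max(gas, smooth_window_h)
  cer <- accumulate_co2(compute_cer(gas, inlet_co2_pct))
  fit <- tryCatch(
    fit_exponential_window(cer, after_h = lag_end, before_h = t_max,
                           r2_min = r2_min, min_points = min_points,
                           anchor = anchor),
    fermkin_no_window = function(e) {
      abort(paste0("exponential fit failed: ", conditionMessage(e)),
            class = "fermkin_segmentation_error", stage = "exponential_fit",
            parent = e)
    })

  structure(list(
    lag_end_h = lag_end,
    exp_start_h = fit$start_h,
    exp_end_h = fit$end_h,
    t_co2max_h = t_max,
    nonexp_duration_h = max(t_max - fit$end_h, 0),
    fit = fit,
    params = list(threshold_pct = threshold_pct, k_consecutive = k_consecutive,
                  r2_min = r2_min, min_points = min_points,
                  smooth_window_h = smooth_window_h,
                  inlet_co2_pct = inlet_co2_pct, anchor = anchor)
  ), class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf(
    "<phase_segmentation> lag end %.2f h | exponential %.2f-%.2f h (slope %.3f /h, R2 %.4f, n %d)\n",
    x$lag_end_h, x$exp_start_h, x$exp_end_h, x$fit$slope, x$fit$r2, x$fit$n))
  cat(sprintf("  CO2 max at %.2f h; non-exponential phase %.2f h\n",
              x$t_co2max_h, x$nonexp_duration_h))
  invisible(x)
}

#' @export
print.exp_window_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_window_fit> %.2f-%.2f h | slope %.4f /h, R2 %.5f, n = %d (%s)\n",
    x$start_h, x$end_h, x$slope, x$r2, x$n,
    if (x$anchor) "anchored" else "free search"))
  invisible(x)
}

#' Tidy an exponential-window fit
#'
#' @param x An `exp_window_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (broom convention).
#' @export
tidy.exp_window_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "time_h"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.exp_window_fit
#' @export
glance.exp_window_fit <- function(x, ...) {
  tibble(r.squared = x$r2, nobs = x$n, start_h = x$start_h, end_h = x$end_h,
         slope = x$slope)
}

#' Tidy a phase segmentation
#'
#' @param x A `phase_segmentation`.
#' @param ... Unused.
#' @return One-row tibble: lag end, exponential window, CO2 maximum,
#'   non-exponential duration, CO2 production rate and fit diagnostics.
#' @export
tidy.phase_segmentation <- function(x, ...) {
  tibble(lag_end_h = x$lag_end_h, exp_start_h = x$exp_start_h,
         exp_end_h = x$exp_end_h, t_co2max_h = x$t_co2max_h,
         nonexp_duration_h = x$nonexp_duration_h,
         co2_rate_h = x$fit$slope, r2 = x$fit$r2, n_points = x$fit$n)
}
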