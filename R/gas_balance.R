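validate_offgas <- function(gas) {
  need <- c("time_h", "co2_pct", "airflow_vvm")
  missing_cols <- setdiff(need, names(gas))
  if (length(missing_cols)) {
    abort(paste0("off-gas table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fermkin_offgas_error")
  }
  if (nrow(gas) < 2) abort("off-gas series needs at least 2 points.",
                           class = "fermkin_offgas_error")
  if (any(diff(gas$time_h) <= 0)) {
    abort("off-gas time must be strictly increasing.",
          class = "fermkin_offgas_error")
  }
  if (any(gas$co2_pct < 0 | gas$co2_pct > 100)) {
    abort("co2_pct must lie in [0, 100].", class = "fermkin_offgas_error")
  }
  if (any(gas$airflow_vvm < 0)) {
    abort("airflow_vvm must be >= 0.", class = "fermkin_offgas_error")
  }
  invisible(gas)
}

#' CO2 evolution rate from off-gas composition and airflow
#'
#' Converts exhaust CO2 percentage, airflow and working volume into the CO2
#' evolution rate (CER) per litre of broth. The gas balance is
#' `CER = airflow * 60 * (co2out - co2in)/100 / Vm` with airflow in vvm (so
#' the working volume cancels) and `Vm = 24.465 L/mol`, the molar volume at
#' the 25 degC cultivation temperature. Negative rates (exhaust below inlet)
#' are floored at zero.
#'
#' @param gas Off-gas tibble with columns `time_h`, `co2_pct`, `airflow_vvm`
#'   (and optionally `volume_l`, `o2_pct`).
#' @param inlet_co2_pct Inlet CO2 (% v/v); atmospheric air is about 0.04.
#'   Use 0 to skip inlet correction.
#' @return Tibble `time_h`, `cer_mmol_l_h` (mmol CO2 per L broth per h).
#' @examples
#' gas <- tibble::tibble(time_h = 0:1, co2_pct = c(1.04, 1.04),
#'                       airflow_vvm = 0.9)
#' compute_cer(gas)
#' @export
compute_cer <- function(gas, inlet_co2_pct = 0.04) {
  validate_offgas(gas)
  cer <- gas$airflow_vvm * 60 * (gas$co2_pct - inlet_co2_pct) / 100 /
    MOLAR_VOLUME_25C * 1000   # mmol / L broth / h
  tibble(time_h = gas$time_h, cer_mmol_l_h = pmax(cer, 0))
}

#' Accumulated CO2 by trapezoidal integration
#'
#' @param cer Tibble with `time_h` and `cer_mmol_l_h` (from [compute_cer()]).
#' @return Input with an `acc_co2_mmol_l` column, the running trapezoidal
#'   integral of the CER starting at 0.
#' @export
accumulate_co2 <- function(cer) {
  if (!all(c("time_h", "cer_mmol_l_h") %in% names(cer))) {
    abort("`cer` needs columns time_h and cer_mmol_l_h.",
          class = "fermkin_offgas_error")
  }
  if (any(diff(cer$time_h) <= 0)) {
    abort("time must be strictly increasing.", class = "fermkin_offgas_error")
  }
  x <- cer$time_h
  y <- cer$cer_mmol_l_h
  acc <- c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
  dplyr::mutate(cer, acc_co2_mmol_l = acc)
}

# centered moving average over a time window (h) on a possibly irregular
# grid; truncated windows at the ends; O(n) via cumulative sums
moving_average_time <- function(t, y, window_h) {
  if (window_h <= 0) return(y)
  half <- window_h / 2
  lo <- findInterval(t - half, t, left.open = TRUE) + 1L
  hi <- findInterval(t + half, t)
  cs <- c(0, cumsum(y))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth an off-gas CO2 signal
#'
#' Centered moving average of `co2_pct` over a time window; endpoints use
#' truncated windows, and `window_h = 0` returns the input unchanged.
#'
#' @param gas Off-gas tibble.
#' @param window_h Window width (h).
#' @return The off-gas tibble with smoothed `co2_pct`.
#' @export
smooth_offgas <- function(gas, window_h = 1) {
  if (window_h < 0) abort("`window_h` must be >= 0.", class = "fermkin_offgas_error")
  validate_offgas(gas)
  dplyr::mutate(gas, co2_pct = moving_average_time(gas$time_h, gas$co2_pct, window_h))
}

#' Read / write off-gas CSV
#'
#' Off-gas files carry one header line and columns `time_h`, `co2_pct`,
#' optional `o2_pct`, `airflow_vvm` and optionally `volume_l`.
#'
#' @param path File path.
#' @param volume_l Working volume (L) to attach when the file has no
#'   `volume_l` column.
#' @return A validated off-gas tibble.
#' @export
read_offgas_csv <- function(path, volume_l = NULL) {
  gas <- readr::read_csv(path, show_col_types = FALSE)
  if (!("volume_l" %in% names(gas)) && !is.null(volume_l)) {
    gas$volume_l <- volume_l
  }
  validate_offgas(gas)
  gas
}

#' @rdname read_offgas_csv
#' @param gas Off-gas tibble to write.
#' @export
write_offgas_csv <- function(gas, path) {
  readr::write_csv(gas, path)
  invisible(path)
}
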