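#' Plot a fermentation run
#'
#' Growth-curve panel in the style of standard fermentation profiles: exhaust
#' CO2 (% v/v) as a line in the upper facet, dry weight and glucose samples
#' (g/L) as points in the lower facet.
#'
#' @param object A `fermentation_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fermentation_run <- function(object, ...) {
  gas <- dplyr::mutate(object$off_gas, panel = "Exhaust CO2 (%)")
  conc <- bind_rows(
    dplyr::transmute(object$dry_weight, time_h = .data$time_h,
                     value = .data$dw_gl, series = "dry weight (g/L)"),
    dplyr::transmute(object$glucose, time_h = .data$time_h,
                     value = .data$glucose_gl, series = "glucose (g/L)")
  )
  conc$panel <- "Concentrations (g/L)"
  ggplot2::ggplot() +
    ggplot2::geom_line(data = gas,
                       ggplot2::aes(x = .data$time_h, y = .data$co2_pct),
                       colour = "grey25") +
    ggplot2::geom_point(data = conc,
                        ggplot2::aes(x = .data$time_h, y = .data$value,
                                     shape = .data$series)) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a segmented off-gas profile
#'
#' Exhaust CO2 over time with the exponential phase shaded in light orange
#' and the non-exponential phase (end of the exponential fit to the CO2
#' maximum) in light grey.
#'
#' @param run A `fermentation_run` or off-gas tibble.
#' @param seg The matching [segment_run()] result.
#' @return A ggplot object.
#' @export
plot_segmentation <- function(run, seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  gas <- if (inherits(run, "fermentation_run")) run$off_gas else run
  shade <- tibble(
    xmin = c(seg$exp_start_h, seg$exp_end_h),
    xmax = c(seg$exp_end_h, seg$t_co2max_h),
    phase = factor(c("exponential", "non-exponential"),
                   levels = c("exponential", "non-exponential"))
  )
  shade <- filter(shade, .data$xmax > .data$xmin)
  ggplot2::ggplot(gas, ggplot2::aes(x = .data$time_h, y = .data$co2_pct)) +
    ggplot2::geom_rect(data = shade, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$phase), alpha = 0.35) +
    ggplot2::scale_fill_manual(values = c(exponential = "#FDBE85",
                                          "non-exponential" = "grey80")) +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::geom_vline(xintercept = seg$lag_end_h, linetype = "dashed") +
    ggplot2::labs(x = "Time (h)", y = "Exhaust CO2 (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the exponential fit on log accumulated CO2
#'
#' @param object An `exp_window_fit`.
#' @param cer The CER tibble the fit was computed on (with accumulated CO2).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exp_window_fit <- function(object, cer, ...) {
  if (!("acc_co2_mmol_l" %in% names(cer))) cer <- accumulate_co2(cer)
  cer <- filter(cer, .data$acc_co2_mmol_l > 0)
  ggplot2::ggplot(cer, ggplot2::aes(x = .data$time_h,
                                    y = log(.data$acc_co2_mmol_l))) +
    ggplot2::geom_point(size = 0.4, colour = "grey40") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::annotate("rect", xmin = object$start_h, xmax = object$end_h,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red") +
    ggplot2::labs(x = "Time (h)", y = "ln accumulated CO2 (mmol/L)") +
    ggplot2::theme_minimal()
}
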