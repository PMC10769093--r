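#' Forest-style plot of stratified delay estimates
#'
#' One panel per quantity: mean busy probability, delay per 10 pp, and
#' mean additional minutes, with 95% bootstrap intervals by stratum.
#'
#' @param object An `ambusy_estimates` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ambusy_estimates <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble(stratum = object$stratum,
           quantity = "busy probability",
           estimate = object$mean_busy_probability,
           lower = object$mb_lower, upper = object$mb_upper),
    tibble(stratum = object$stratum,
           quantity = "delay per 10 pp (min)",
           estimate = object$delay_per_10pp,
           lower = object$delay_lower, upper = object$delay_upper),
    tibble(stratum = object$stratum,
           quantity = "mean additional (min)",
           estimate = object$mean_additional_min,
           lower = object$add_lower, upper = object$add_upper)
  )
  long$stratum <- factor(long$stratum, levels = rev(unique(object$stratum)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate, y = .data$stratum)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
      height = 0.25, na.rm = TRUE) +
    ggplot2::facet_wrap(~quantity, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Busy-ambulance exposure and delay by stratum") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Calibration of the busy-probability exposure
#'
#' Bins incidents by estimated busy probability and plots, per bin, the
#' observed fraction whose ground-truth preferred unit was actually busy.
#' A well-calibrated exposure tracks the diagonal; monotone increase is
#' what the delay analysis relies on.
#'
#' @param exposure Exposure tibble from [estimate_busy_exposure()].
#' @param ground_truth Ground-truth tibble from [simulate_operations()].
#' @param bins Number of probability bins (default 10).
#' @return A ggplot object; the binned table is attached as attribute
#'   `"calibration"`.
#' @export
plot_exposure_calibration <- function(exposure, ground_truth, bins = 10) {
  tab <- calibration_table(exposure, ground_truth, bins = bins)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean_exposure,
                                         y = .data$observed_busy)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "mean estimated busy probability (bin)",
                  y = "observed fraction with busy preferred unit",
                  title = "Exposure calibration against simulator ground truth") +
    ggplot2::theme_minimal()
  attr(p, "calibration") <- tab
  p
}

#' Binned exposure-calibration table
#'
#' @inheritParams plot_exposure_calibration
#' @return Tibble `bin`, `mean_exposure`, `observed_busy`, `n`.
#' @export
calibration_table <- function(exposure, ground_truth, bins = 10) {
  ok <- exposure[exposure$status == "ok", c("incident_id", "busy_probability")]
  joined <- dplyr::inner_join(ok, ground_truth, by = "incident_id")
  brk <- unique(quantile(joined$busy_probability,
                         probs = seq(0, 1, length.out = bins + 1)))
  joined$bin <- cut(joined$busy_probability, breaks = brk,
                    include.lowest = TRUE)
  joined |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_exposure = mean(.data$busy_probability),
                     observed_busy = mean(.data$truly_busy),
                     n = dplyr::n(), .groups = "drop")
}
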