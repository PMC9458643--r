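# shared fill scale: green n.r., red hunch, blue bend (figure convention)
behaviour_fill <- function() {
  ggplot2::scale_fill_manual(values = c(
    "hunch" = "#d7301f", "bend" = "#0570b0", "n.r." = "#41ab5d",
    "hunch-bend-seq" = "#fdae61", "bend-hunch-seq" = "#74add1"),
    drop = FALSE)
}

#' Plot a circuit trajectory
#'
#' Rate time courses of all seven neurons with the stimulus periods
#' shaded; when a [normalization_reference()] is supplied, a behaviour
#' band (instantaneous hunch/bend/n.r. label) is drawn beneath the traces.
#'
#' @param object A `circuit_trajectory`.
#' @param reference Optional [normalization_reference()] enabling the
#'   behaviour band.
#' @param thresholds A [classifier_thresholds()] for the band.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot circuit_trajectory
#' @export
autoplot.circuit_trajectory <- function(object, reference = NULL,
                                        thresholds = classifier_thresholds(),
                                        ...) {
  long <- tidy(object)
  prot <- attr(object, "protocol")
  band_h <- -0.05 * max(long$rate, 1)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$rate,
                                          colour = .data$neuron)) +
    ggplot2::annotate("rect", xmin = prot$pulse_onset,
                      xmax = prot$pulse_onset + prot$pulse_duration,
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = prot$pulse_onset, linetype = "dashed") +
    ggplot2::labs(x = "time (AU)", y = "rate", colour = NULL) +
    ggplot2::theme_minimal()
  if (prot$prepulse)
    p <- p + ggplot2::annotate("rect", xmin = prot$prepulse_onset,
                               xmax = prot$prepulse_onset + prot$prepulse_duration,
                               ymin = -Inf, ymax = Inf, alpha = 0.08)
  if (!is.null(reference)) {
    lab <- behaviour_labels(object, reference, thresholds)
    p <- p + ggplot2::geom_tile(
      data = mutate(lab, y = band_h),
      ggplot2::aes(x = .data$time, y = .data$y, fill = .data$label),
      height = abs(band_h), inherit.aes = FALSE) + behaviour_fill()
  }
  p
}

#' Plot a behavioural landscape
#'
#' Raster of the selected behaviour over the `w_iLNb`-`w_iLNa` plane
#' (`w_iLNb` on the x axis, `w_iLNa` on the y axis).
#'
#' @param object A `behaviour_landscape`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot behaviour_landscape
#' @export
autoplot.behaviour_landscape <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$w_iLNb, .data$w_iLNa,
                                       fill = .data$label)) +
    ggplot2::geom_raster() + behaviour_fill() +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::labs(x = "w_iLNb", y = "w_iLNa", fill = "behaviour") +
    ggplot2::theme_minimal()
}

#' Plot a prepulse change map
#'
#' @param object A [change_map()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppi_change_map
#' @export
autoplot.ppi_change_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$w_iLNb, .data$w_iLNa,
                                       fill = .data$change)) +
    ggplot2::geom_raster() +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::labs(x = "w_iLNb", y = "w_iLNa", fill = "change") +
    ggplot2::theme_minimal()
}

#' Plot a persistence map
#'
#' Residual activity at pulse onset per neuron, as one raster facet per
#' neuron.
#'
#' @param object A [persistence_map()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppi_persistence_map
#' @export
autoplot.ppi_persistence_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$w_iLNb, .data$w_iLNa,
                                       fill = .data$residual)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~neuron, nrow = 2) +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::labs(x = "w_iLNb", y = "w_iLNa",
                  fill = if (isTRUE(attr(object, "normalized")))
                    "residual / r*" else "residual") +
    ggplot2::theme_minimal()
}

#' Plot a lead-interval sweep
#'
#' Startle area fraction per lead interval with the no-prepulse baseline
#' as a horizontal reference line.
#'
#' @param object A [lead_interval_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lead_interval_sweep
#' @export
autoplot.lead_interval_sweep <- function(object, ...) {
  base <- object$startle_fraction[is.na(object$lead_interval)]
  dat <- object[!is.na(object$lead_interval), ]
  ggplot2::ggplot(dat, ggplot2::aes(factor(.data$lead_interval),
                                    .data$startle_fraction)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "lead interval (AU)", y = "startle area fraction") +
    ggplot2::theme_minimal()
}
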