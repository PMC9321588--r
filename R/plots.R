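#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` gives a quick diagnostic figure for each result type: the
#' face-flux structure of a flow field, the mixing curves of a
#' `mixing_result` (CoM on a log scale with the mixed threshold), and the
#' scalar time series of a `cm_sim`. [plot_lifeline()] draws one or more
#' uptake-ratio lifelines colored by regime.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name lagcm-plots
NULL

#' @rdname lagcm-plots
#' @method autoplot flow_field
#' @export
autoplot.flow_field <- function(object, ...) {
  fa <- object$faces
  cells <- object$cells
  mag <- rowsum(abs(fa$flux), fa$cell_a, na.rm = TRUE)
  cells$flux_mag <- 0
  cells$flux_mag[as.integer(rownames(mag))] <- mag[, 1]
  k1 <- cells[cells$ik == 1L, ]
  ggplot2::ggplot(k1, ggplot2::aes(x = .data$r, y = .data$y, fill = .data$flux_mag)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r (m)", y = "y (m)", fill = "|flux| out (kg/s)",
                  title = "Synthetic stirred-tank flow field (first azimuthal slice)")
}

#' @rdname lagcm-plots
#' @method autoplot mixing_result
#' @export
autoplot.mixing_result <- function(object, ...) {
  s <- object$series
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$time, y = .data$com)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$com_threshold, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (s)", y = "coefficient of mixing",
                  title = sprintf("%s mixing, %s", object$kind, object$layout))
  if (object$kind == "tracer") {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = abs(.data$probe - 1) + 1e-12),
                                color = "grey50")
  }
  p
}

#' @rdname lagcm-plots
#' @method autoplot cm_sim
#' @export
autoplot.cm_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$scalars,
    cols = dplyr::any_of(c("cs_vol_mean", "cs_parcel_mean", "cx", "mu", "qp")),
    names_to = "quantity", values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%s on %s", object$mode, object$layout))
}

#' @rdname lagcm-plots
#' @param lifelines A lifelines tibble (parcel, time, ratio) from a
#'   `cm_sim`, optionally already labeled.
#' @param parcels Which parcel ids to draw (default: first 3).
#' @export
plot_lifeline <- function(lifelines, parcels = NULL) {
  parcels <- parcels %||% utils::head(unique(lifelines$parcel), 3)
  d <- lifelines[lifelines$parcel %in% parcels, ]
  if (is.null(d$label)) d$label <- classify_regimes(d$ratio)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$ratio)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$label), size = 0.4) +
    ggplot2::scale_color_manual(values = c(E = "#c0392b", L = "#d4a017", S = "#2a6fbb")) +
    ggplot2::facet_wrap(~parcel, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "qs / qs,max", color = "regime")
}
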