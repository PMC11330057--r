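raster_df <- function(m, value_name = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value_name := as.vector(m)
  )
}

#' Plot a contrast map
#'
#' @param object A [contrast_map()].
#' @param threshold Detection threshold drawn as the midpoint of the colour
#'   scale.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contrast_map <- function(object, threshold = 0.1, ...) {
  d <- raster_df(object$values, "contrast")
  d$contrast[as.vector(object$excluded)] <- NA
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$contrast)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = threshold, low = "grey20",
                                  mid = "white", high = "firebrick",
                                  na.value = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  title = sprintf("Contrast map (%s), i_s = %.3g",
                                  object$modality, object$i_s))
}

#' Plot a segmented lesion mask
#'
#' @param object A `lesion_segment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lesion_segment <- function(object, ...) {
  d <- raster_df(object$mask, "lesion")
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$lesion)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey95",
                                          `TRUE` = "firebrick")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "column (px)", y = "row (px)",
      title = if (object$detected) {
        sprintf("Lesion: %d px, mean contrast %.3f", object$area_px,
                object$mean_contrast)
      } else {
        "Negative detection"
      }
    ) +
    ggplot2::theme(legend.position = "none")
}

#' Plot a cylindrical-ruler intensity profile
#'
#' @param object A [ruler_profile()].
#' @param measurement Optional `depth_measurement` whose minima are marked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ruler_profile <- function(object, measurement = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$distance_mm,
                                            .data$intensity)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "optical distance along ruler (mm)",
                  y = "mean disk intensity")
  if (!is.null(measurement) && isTRUE(measurement$detected)) {
    p <- p +
      ggplot2::geom_point(data = measurement$minima, colour = "firebrick",
                          size = 2) +
      ggplot2::labs(title = sprintf("Lesion depth %.3f mm (physical)",
                                    measurement$depth_mm))
  }
  p
}

#' Plot detection rates per method and surface group
#'
#' @param rates Output of [detection_rates()].
#' @return A ggplot.
#' @export
plot_detection_rates <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(.data$method, .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~group) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "detection rate") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
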