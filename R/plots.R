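#' Plot a layer mask set
#'
#' Raster plot of the plasma-membrane band, the intracellular layers and
#' the interior, coloured by layer label.
#'
#' @param object a `layer_mask_set`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.layer_mask_set <- function(object, ...) {
  lab <- matrix(NA_character_, nrow(object$pm), ncol(object$pm))
  lab[object$interior] <- "interior"
  for (k in rev(seq_len(object$n_layers)))
    lab[object$inner[[k]]] <- paste0("L", k)
  lab[object$pm] <- "PM"
  df <- tibble::tibble(
    row = rep(seq_len(nrow(lab)), times = ncol(lab)),
    col = rep(seq_len(ncol(lab)), each = nrow(lab)),
    layer = factor(as.vector(lab), levels = LAYER_LEVELS)
  )
  df <- dplyr::filter(df, !is.na(.data$layer))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$layer)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = "layer") +
    ggplot2::theme_minimal()
}

#' Plot a fibre image channel with detected spots and the contour
#'
#' @param image a `fibre_image`.
#' @param contour optional `membrane_contour` to overlay.
#' @param spots optional [detect_spots()] table to overlay.
#' @param channel which channel to show.
#' @return a ggplot.
#' @export
plot_fibre_image <- function(image, contour = NULL, spots = NULL,
                             channel = c("glut4", "dystrophin", "mhc1")) {
  channel <- match.arg(channel)
  m <- image[[channel]]
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    intensity = as.vector(m)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = channel) +
    ggplot2::theme_minimal()
  if (!is.null(contour)) {
    v <- as.data.frame(contour$vertices)
    names(v) <- c("row", "col")
    p <- p + ggplot2::geom_path(
      data = rbind(v, v[1, ]),
      ggplot2::aes(.data$col, .data$row), inherit.aes = FALSE,
      colour = "red", linewidth = 0.4)
  }
  if (!is.null(spots) && nrow(spots) > 0) {
    p <- p + ggplot2::geom_point(
      data = spots,
      ggplot2::aes(.data$centroid_col, .data$centroid_row,
                   shape = .data$size_class),
      inherit.aes = FALSE, colour = "yellow", size = 1.2)
  }
  p
}

#' Plot mean spot counts per layer by condition
#'
#' @param measurements measurement tibble.
#' @param size_class `"small"` or `"large"`.
#' @return a ggplot of mean count (+- SE) per layer, faceted by group and
#'   infusion, coloured by timepoint.
#' @export
plot_spot_counts <- function(measurements, size_class = c("small", "large")) {
  size_class <- match.arg(size_class)
  counts <- summarize_study(measurements)$spot_counts |>
    dplyr::filter(.data$size_class == !!size_class)
  ggplot2::ggplot(counts, ggplot2::aes(
    .data$layer, .data$mean_count,
    fill = factor(.data$timepoint_h))) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_count - .data$se_count,
      ymax = .data$mean_count + .data$se_count),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::facet_grid(group ~ infusion) +
    ggplot2::labs(x = "layer", y = sprintf("mean %s spots per fibre",
                                           size_class),
                  fill = "timepoint (h)") +
    ggplot2::theme_minimal()
}

#' Plot the colocalization time course
#'
#' @param measurements measurement tibble.
#' @return a ggplot of mean PCC (+- SE) over the biopsy timepoints by group
#'   and infusion.
#' @export
plot_pcc_timecourse <- function(measurements) {
  tab <- summarize_study(measurements)$pcc
  ggplot2::ggplot(tab, ggplot2::aes(
    .data$timepoint_h, .data$mean_pcc,
    colour = .data$group, linetype = .data$infusion)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_pcc - .data$se_pcc,
      ymax = .data$mean_pcc + .data$se_pcc)) +
    ggplot2::labs(x = "infusion time (h)",
                  y = "GLUT4-dystrophin PCC") +
    ggplot2::theme_minimal()
}
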