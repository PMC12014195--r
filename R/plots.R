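# ggplot2 visualisations for the result objects.

lab_to_hex <- function(lab) {
  rgb <- lab_to_srgb(to_lab_rows(lab))
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a segmentation map in matched palette colours
#'
#' Renders the FST-class raster with every pixel painted in its matched
#' palette colour, the spatial-mapping view of a segmentation.
#'
#' @param object An `fst_segmentation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fst_segmentation
#' @export
autoplot.fst_segmentation <- function(object, ...) {
  hex <- lab_to_hex(as.matrix(object$palette[, c("L", "a", "b")]))
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object$fst_raster)),
              times = ncol(object$fst_raster)),
    col = rep(seq_len(ncol(object$fst_raster)),
              each = nrow(object$fst_raster)),
    fst = factor(as.vector(object$fst_raster), levels = 1:6,
                 labels = paste("FST", as.roman(1:6)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$fst)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = stats::setNames(
      hex, paste("FST", as.roman(1:6))), drop = TRUE, name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("FST segmentation (k = %d)", object$k),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Swatch panel of cluster centres beside their matched palette colours
#'
#' Each cluster centre is shown next to the palette entry it matched, with
#' the Delta-E distance and pixel fraction annotated - the visual check that
#' the matching is sensible.
#'
#' @param object An `fst_match`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fst_match
#' @export
autoplot.fst_match <- function(object, ...) {
  m <- tidy(object)
  center_hex <- lab_to_hex(object$centers)
  pal_lab <- as.matrix(object$palette[, c("L", "a", "b")])
  pal_hex <- lab_to_hex(pal_lab[m$fst, , drop = FALSE])
  df <- tibble::tibble(
    cluster = rep(m$cluster, 2),
    side = rep(c("cluster centre", "matched FST"), each = nrow(m)),
    hex = c(center_hex, pal_hex),
    label = c(sprintf("dE %.1f", m$delta_e),
              sprintf("FST %s (%.0f%%)", as.character(as.roman(m$fst)), 100 * m$fraction))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$side, y = factor(.data$cluster),
                                   fill = .data$hex)) +
    ggplot2::geom_tile(color = "grey30", linewidth = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(title = sprintf("%s: dominant FST %s", object$image_id,
                                  as.character(as.roman(object$dominant_fst))),
                  x = NULL, y = "cluster") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of an evaluation
#'
#' @param object An `fst_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fst_evaluation
#' @export
autoplot.fst_evaluation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$predicted_fst),
                                   y = factor(.data$true_fst),
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 name = "count") +
    ggplot2::scale_y_discrete(limits = rev(as.character(1:6))) +
    ggplot2::labs(x = "predicted FST", y = "true FST",
                  title = sprintf("accuracy %.2f, +/-%d tolerance %.2f",
                                  object$metrics$accuracy, object$tolerance,
                                  object$tolerance_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot a clustering model benchmark table
#'
#' One panel per validity index, models ordered by silhouette. Failed rows
#' are dropped from the plot (they stay in the table).
#'
#' @param benchmark A tibble from [benchmark_models()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(benchmark) {
  ok <- dplyr::filter(benchmark, .data$status == "ok")
  if (nrow(ok) == 0L) stop("no successful benchmark rows to plot",
                           call. = FALSE)
  long <- tidyr::pivot_longer(
    ok, c("silhouette", "calinski_harabasz", "davies_bouldin"),
    names_to = "index", values_to = "value")
  long$model <- factor(long$model,
                       levels = ok$model[order(ok$silhouette)])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$model)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::facet_wrap(~index, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Clustering validity indices by model") +
    ggplot2::theme_minimal()
}
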