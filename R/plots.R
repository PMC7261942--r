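# ggplot2 views of the result objects.

#' Plot a slice with optional mask overlays
#'
#' @param volume a [sequence_volume()].
#' @param slice slice index.
#' @param masks optional named list `class -> lesion_mask` to overlay.
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, slice = 1L, masks = NULL) {
  img <- volume$intensities[slice, , ]
  df <- tidyr::expand_grid(row = seq_len(nrow(img)),
                           col = seq_len(ncol(img)))
  df$intensity <- as.vector(img)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s, slice %d", volume$modality, slice),
                  fill = "a.u.") +
    ggplot2::theme_minimal()
  if (!is.null(masks)) {
    ov <- purrr::imap(masks, function(m, cls) {
      v <- if (inherits(m, "lesion_mask")) m$values else m
      idx <- which(v[slice, , ] != 0, arr.ind = TRUE)
      if (nrow(idx) == 0) return(NULL)
      tibble::tibble(row = idx[, 1], col = idx[, 2], class = cls)
    }) |> dplyr::bind_rows()
    if (nrow(ov) > 0) {
      p <- p + ggplot2::geom_tile(
        data = ov,
        ggplot2::aes(x = .data$col, y = .data$row, colour = .data$class),
        fill = NA, linewidth = 0.3, inherit.aes = FALSE
      )
    }
  }
  p
}

#' Training-curve plot for a fitted segmentor
#'
#' @param object a `csvd_train_state`.
#' @param ... unused.
#' @return A ggplot object with training and validation accuracy per epoch.
#' @export
autoplot.csvd_train_state <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            cols = c("train_accuracy", "val_accuracy"),
                            names_to = "series", values_to = "accuracy")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$accuracy,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "epoch", y = "mean Dice", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-class metric plot for an evaluation report
#'
#' @param object a `csvd_report`.
#' @param ... unused.
#' @return A ggplot bar chart of per-class Dice and region F1.
#' @export
autoplot.csvd_report <- function(object, ...) {
  df <- object$aggregate |>
    dplyr::filter(.data$class != "OVERALL") |>
    dplyr::select(dplyr::all_of(c("class", "dice", "region_f1"))) |>
    tidyr::pivot_longer(cols = c("dice", "region_f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "score", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
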