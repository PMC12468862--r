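#' Tidy a fold report
#'
#' One row per fold with the four metrics, broom-style.
#'
#' @param x a `cxr_fold_report`.
#' @param ... unused.
#' @return tibble of per-fold metrics.
#' @export
tidy.cxr_fold_report <- function(x, ...) {
  x$folds
}

#' One-row summary of a fold report
#'
#' @param x a `cxr_fold_report`.
#' @param ... unused.
#' @return one-row tibble: mean and sd per metric, `k`.
#' @export
glance.cxr_fold_report <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    accuracy = x$mean[["accuracy"]], accuracy_sd = x$sd[["accuracy"]],
    precision = x$mean[["precision"]], precision_sd = x$sd[["precision"]],
    recall = x$mean[["recall"]], recall_sd = x$sd[["recall"]],
    f1 = x$mean[["f1"]], f1_sd = x$sd[["f1"]]
  )
}

#' @export
tidy.cxr_comparison <- function(x, ...) x$table

#' @export
glance.cxr_comparison <- function(x, ...) x$wide

# generics re-exported so tidy()/glance() work without loading broom
#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot a grayscale image or mask
#'
#' ggplot2 raster rendering in anatomical orientation (row 1 at the
#' top). An optional [crop_box()] overlay is drawn in red.
#'
#' @param img numeric matrix in `[0,1]` or logical mask.
#' @param box optional [crop_box()] to overlay.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_image <- function(img, box = NULL, title = NULL) {
  if (is.logical(img)) img <- matrix(as.numeric(img), nrow(img), ncol(img))
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.vector(t(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = title, fill = "intensity")
  if (!is.null(box)) {
    p <- p + ggplot2::annotate("rect", xmin = box$left + 0.5,
                               xmax = box$right + 0.5,
                               ymin = box$top + 0.5, ymax = box$bottom + 0.5,
                               colour = "red", fill = NA, linewidth = 0.6)
  }
  p
}

#' @export
autoplot.cxr_profile <- function(object, ...) {
  df <- tibble::tibble(index = seq_along(object) - 1L,
                       count = as.numeric(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste(attr(object, "axis"), "(0-based index)"),
                  y = "foreground pixels",
                  title = "projection profile") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cxr_fold_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds,
                            cols = c("accuracy", "precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d-fold cross-validation", object$k)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cxr_comparison <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$method, y = .data$mean,
                               fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = NULL, title = "method comparison") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
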