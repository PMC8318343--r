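#' Box plot of true-error magnitude by correction iteration
#'
#' The convergence view: per-iteration distribution of `|t_xy|` (and
#' `|t_z|`) across trials, with dashed lines at the patch-clamp-relevant
#' windows (2.5 um in xy — half a typical 10 um cell — and 3 um in z).
#'
#' @param trajectories Tibble from [run_correction_trials()].
#' @param xy_threshold_um,z_threshold_um Reference lines (um).
#' @return A ggplot object.
#' @export
plot_convergence <- function(trajectories, xy_threshold_um = 2.5,
                             z_threshold_um = 3) {
  long <- trajectories |>
    dplyr::select("trial", "iteration", "t_xy", "t_z_abs") |>
    tidyr::pivot_longer(c("t_xy", "t_z_abs"), names_to = "axis",
                        values_to = "error_um") |>
    dplyr::mutate(axis = dplyr::recode(.data$axis, t_xy = "|t| in xy",
                                       t_z_abs = "|t| in z"))
  ref <- tibble::tibble(axis = c("|t| in xy", "|t| in z"),
                        threshold = c(xy_threshold_um, z_threshold_um))
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$iteration),
                                     .data$error_um)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3, fill = "grey85") +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = "correction iteration", y = "true error (µm)") +
    ggplot2::theme_minimal()
}

#' Training curves of a fitted tip-localization CNN
#'
#' Mini-batch loss (log scale) and validation RMSE against iteration.
#'
#' @param object A trained [pipette_cnn][build_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pipette_cnn
#' @export
autoplot.pipette_cnn <- function(object, ...) {
  log <- object$log
  if (is.null(log)) stop("model has no training log", call. = FALSE)
  val <- log[!is.na(log$val_rmse), ]
  ggplot2::ggplot(log[!is.na(log$loss), ],
                  ggplot2::aes(.data$iteration, .data$loss)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(data = val,
                        ggplot2::aes(.data$iteration, .data$val_rmse),
                        colour = "firebrick", size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration",
                  y = "mini-batch loss / validation RMSE (red)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Success-rate comparison bar chart
#'
#' @param report Tibble from [success_rate_report()].
#' @param method_names Labels for groups 1 and 2.
#' @return A ggplot object.
#' @export
plot_success_rates <- function(report,
                               method_names = c("cross-correlation", "CNN")) {
  long <- report |>
    dplyr::select("stage", "rate1_pct", "rate2_pct") |>
    tidyr::pivot_longer(c("rate1_pct", "rate2_pct"), names_to = "method",
                        values_to = "rate_pct") |>
    dplyr::mutate(method = ifelse(.data$method == "rate1_pct",
                                  method_names[1], method_names[2]))
  ggplot2::ggplot(long, ggplot2::aes(.data$stage, .data$rate_pct,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "success rate (%)", fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Display a rendered scene with annotations
#'
#' @param image Intensity matrix.
#' @param annotation Optional tibble with `col_px`, `row_px` to overlay.
#' @return A ggplot object (raster heat map, image orientation).
#' @export
plot_scene <- function(image, annotation = NULL) {
  df <- tidyr::expand_grid(row = seq_len(nrow(image)) - 1L,
                           col = seq_len(ncol(image)) - 1L)
  df$intensity <- as.vector(t(image))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(annotation)) {
    p <- p + ggplot2::geom_point(
      data = annotation,
      ggplot2::aes(.data$col_px, .data$row_px),
      inherit.aes = FALSE, colour = "red", shape = 3, size = 3
    )
  }
  p
}
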