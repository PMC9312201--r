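#' Plot trajectories of a scene or track table
#'
#' Draws box-centre trajectories coloured by identity, in image
#' coordinates (y axis reversed so the plot matches the camera view).
#' Optionally overlays a counting line.
#'
#' @param tracks A track table (`frame`, `id`, box columns) - tracker
#'   output or simulator ground truth.
#' @param line Optional [counting_line()] to overlay.
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, line = NULL) {
  df <- dplyr::mutate(tracks, cx = .data$left + .data$width / 2,
                      cy = .data$top + .data$height / 2)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$cx, .data$cy,
                                        colour = factor(.data$id),
                                        group = .data$id)) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "track id") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (!is.null(line)) {
    p <- p + ggplot2::annotate("segment",
                               x = line$p1[1], y = line$p1[2],
                               xend = line$p2[1], yend = line$p2[2],
                               colour = "red", linewidth = 1)
  }
  p
}

#' @rdname plot_tracks
#' @param object,... `autoplot` method arguments.
#' @method autoplot pen_scene
#' @export
autoplot.pen_scene <- function(object, ...) {
  plot_tracks(object$gt, object$config$line) +
    ggplot2::ggtitle(sprintf("simulated pen scene (%d targets, %d frames)",
                             object$config$n_targets, object$config$frames))
}

#' Plot the cumulative count over time
#'
#' @param object A `line_count` from [count_crossings()].
#' @param ... Unused.
#' @return A ggplot object (step curve of the cumulative count, with the
#'   crossing frames marked).
#' @method autoplot line_count
#' @export
autoplot.line_count <- function(object, ...) {
  p <- ggplot2::ggplot(object$per_frame,
                       ggplot2::aes(.data$frame, .data$count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "frame", y = "cumulative count") +
    ggplot2::theme_minimal()
  if (nrow(object$B) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$B$cross_frame,
                                 linetype = "dotted", colour = "red")
  }
  p
}

#' Plot per-pair tracking errors
#'
#' @param object A `tracking_eval` from [tracking_eval()].
#' @param ... Unused.
#' @return A ggplot object: per-frame mean overlap rate and centre-location
#'   error, with the sequence-level AOR / ACLE as reference lines.
#' @method autoplot tracking_eval
#' @export
autoplot.tracking_eval <- function(object, ...) {
  df <- object$per_pair |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(OR = mean(.data$OR), CLE = mean(.data$CLE)) |>
    tidyr::pivot_longer(c("OR", "CLE"), names_to = "metric")
  ref <- tibble::tibble(metric = c("OR", "CLE"),
                        value = c(object$AOR, object$ACLE))
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "frame", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
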