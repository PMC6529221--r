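# ggplot2 views of the main result types.

#' Heatmap of an overlap matrix
#'
#' White-to-black heatmap of overlap scores, rows/columns ordered by
#' complete-linkage clustering. For a square matrix over one mask set, the
#' 100% self-overlap diagonal can be replaced by a -1 sentinel at render time
#' (shown in a contrasting fill) so it does not dominate the colour scale;
#' the stored matrix always keeps the true values.
#'
#' @param object An `lh_overlap_matrix`.
#' @param cluster Reorder rows/columns by [cluster_matrix()].
#' @param diagonal_sentinel Apply the -1 diagonal convention when row and
#'   column sets coincide.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lh_overlap_matrix
#' @export
autoplot.lh_overlap_matrix <- function(object, cluster = TRUE,
                                       diagonal_sentinel = TRUE, ...) {
  df <- tidy(object)
  vals <- object$values
  square <- identical(object$row_labels, object$col_labels)
  if (diagonal_sentinel && square) {
    sent <- df$row == df$col
    df$score[sent] <- -1
  }
  row_ord <- object$row_labels; col_ord <- object$col_labels
  if (cluster && nrow(vals) >= 2 && ncol(vals) >= 2) {
    cl <- cluster_matrix(object)
    row_ord <- object$row_labels[cl$row_order]
    col_ord <- object$col_labels[cl$col_order]
  }
  df$row <- factor(df$row, levels = rev(row_ord))
  df$col <- factor(df$col, levels = col_ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 100), na.value = "grey50",
                                 name = "overlap %") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Preference index over time
#'
#' PI trace with the light-ON epochs shaded.
#'
#' @param object An `lh_pi_series`.
#' @param schedule Optional schedule tibble used to shade ON epochs.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lh_pi_series
#' @export
autoplot.lh_pi_series <- function(object, schedule = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$pi))
  if (!is.null(schedule)) {
    on <- schedule[schedule$state == "on", , drop = FALSE]
    p <- p + ggplot2::annotate("rect", xmin = on$start_s, xmax = on$end_s,
                               ymin = -1, ymax = 1, alpha = 0.15,
                               fill = "red")
  }
  p + ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "time (s)", y = "preference index") +
    ggplot2::theme_classic()
}

#' Flight response trace
#'
#' Group mean response with per-fly traces underneath; samples where a
#' significance series flags `p < alpha` are marked above the traces.
#'
#' @param object An `lh_response_trace`.
#' @param significance Optional output of [per_timepoint_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lh_response_trace
#' @export
autoplot.lh_response_trace <- function(object, significance = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_rel)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$response,
                                    group = .data$fly_id),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_response),
                       colour = "magenta4", linewidth = 0.8) +
    ggplot2::labs(x = "time from LED onset (s)",
                  y = sprintf("%s response", object$parameter)) +
    ggplot2::theme_classic()
  if (!is.null(significance)) {
    sig <- significance[significance$significant, , drop = FALSE]
    if (nrow(sig)) {
      y_top <- max(df$response, na.rm = TRUE)
      p <- p + ggplot2::annotate("point", x = sig$time_rel, y = y_top * 1.05,
                                 shape = 3, colour = "red", size = 0.6)
    }
  }
  p
}

#' Screen results overview
#'
#' Lines ordered by Dunn z, -log10 adjusted p, significance highlighted.
#'
#' @param object An `lh_screen_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lh_screen_result
#' @export
autoplot.lh_screen_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$line_id <- factor(df$line_id, levels = df$line_id[order(df$z)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$line_id,
                                   y = -log10(.data$adjusted_p),
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "sig_level")),
                        linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "dodgerblue3")) +
    ggplot2::labs(x = NULL, y = "-log10 adjusted p") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Maximum-intensity projection of a modality map
#'
#' @param object An `lh_modality_map`.
#' @param axis Projection axis, default `"z"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lh_modality_map
#' @export
autoplot.lh_modality_map <- function(object, axis = "z", ...) {
  ax <- match(axis, c("x", "y", "z"))
  proj <- apply(object$mean_volume$data, setdiff(1:3, ax), max)
  df <- tidyr::expand_grid(i = seq_len(nrow(proj)), j = seq_len(ncol(proj)))
  df$value <- proj[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                  name = "mean occupancy") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (n = %d exemplars)", object$modality,
                                  object$n_exemplars),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
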