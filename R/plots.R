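#' Plot the unified-distance matrix of a trained map
#'
#' @param object A `som_model`.
#' @param ... Unused.
#' @return A ggplot: cells tiled by unified distance, ridges marking
#'   psychotype borders.
#' @method autoplot som_model
#' @export
autoplot.som_model <- function(object, ...) {
  ggplot2::ggplot(u_matrix(object),
                  ggplot2::aes(.data$col, .data$row,
                               fill = .data$unified_distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = "U-matrix") +
    ggplot2::theme_minimal()
}

#' Plot a per-cell overlay
#'
#' @param object A [cell_overlay()].
#' @param fill Overlay quantity to map to fill: `"depression_odds"`
#'   (default, log1p-transformed for display), `"n"`, `"pct_male"` or one of
#'   the `mean_wb_*` columns.
#' @param ... Unused.
#' @return A ggplot; unoccupied cells are drawn grey.
#' @method autoplot cell_overlay
#' @export
autoplot.cell_overlay <- function(object, fill = "depression_odds", ...) {
  df <- dplyr::mutate(
    as_tibble(object),
    .fill = if (fill == "depression_odds") {
      log1p(ifelse(is.finite(.data$depression_odds),
                   .data$depression_odds, NA))
    } else .data[[fill]],
    .fill = ifelse(.data$occupied, .data$.fill, NA)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$.fill)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "column", y = "row",
                  fill = if (fill == "depression_odds") "log(1+odds)" else fill) +
    ggplot2::theme_minimal()
}

#' Plot a psychotype cluster map
#'
#' @param object A [cluster_codebook()] result.
#' @param ... Unused.
#' @return A ggplot of the cell-to-cluster assignment.
#' @method autoplot som_clusters
#' @export
autoplot.som_clusters <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$col, .data$row,
                               fill = factor(.data$cluster))) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot a self-improvement path
#'
#' @param object A [shortest_path()] result.
#' @param type `"trajectories"` (per-feature codebook values along the path)
#'   or `"map"` (the route on the grid).
#' @param features Optional subset of feature names for the trajectory view.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot path_result
#' @export
autoplot.path_result <- function(object, type = c("trajectories", "map"),
                                 features = NULL, ...) {
  type <- match.arg(type)
  if (type == "map") {
    return(
      ggplot2::ggplot(object$coords, ggplot2::aes(.data$col, .data$row)) +
        ggplot2::geom_path(linewidth = 1) +
        ggplot2::geom_point(size = 2) +
        ggplot2::scale_y_reverse() +
        ggplot2::coord_equal() +
        ggplot2::labs(x = "column", y = "row") +
        ggplot2::theme_minimal()
    )
  }
  traj <- object$trajectories
  if (!is.null(features)) {
    traj <- dplyr::filter(traj, .data$feature %in% features)
  }
  ggplot2::ggplot(traj, ggplot2::aes(.data$step, .data$value,
                                     colour = .data$feature)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "path step", y = "codebook value (item units)") +
    ggplot2::theme_minimal()
}
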