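#' Grayscale position raster of a cohort
#'
#' One row per larva, time on the x axis, and a four-level gray value per
#' frame encoding the zone (dark = center zone, light = edge zone). Rows
#' are sorted top-down by the larva's time-to-contact (pre-search
#' duration), and phase boundaries are marked.
#'
#' @param tracks Named list of `repaired_track` tibbles.
#' @param timelines Named list of `experiment_timeline` objects (same
#'   names).
#' @param config An [arena_config()].
#' @return A ggplot object.
#' @export
grayscale_position_plot <- function(tracks, timelines, config) {
  stopifnot(length(tracks) >= 1, all(names(tracks) %in% names(timelines)))
  pre <- vapply(names(tracks),
                function(id) diff(timelines[[id]]$pre_search), numeric(1))
  ord <- names(tracks)[order(pre)]
  df <- dplyr::bind_rows(lapply(ord, function(id) {
    tr <- tracks[[id]]
    tibble::tibble(larva_id = id, t_s = tr$t_s,
                   zone = zone_of(tr$r_mm, config$zone_edges_mm))
  }))
  df$larva_id <- factor(df$larva_id, levels = rev(ord))
  greys <- stats::setNames(c("grey15", "grey45", "grey70", "grey90"),
                           zone_labels())
  bounds <- dplyr::bind_rows(lapply(ord, function(id) {
    tl <- timelines[[id]]
    tibble::tibble(larva_id = id,
                   t_s = vapply(tl, `[`, numeric(1), 2)[-4])
  }))
  bounds$larva_id <- factor(bounds$larva_id, levels = rev(ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$larva_id,
                                   fill = .data$zone)) +
    ggplot2::geom_tile(height = 0.9) +
    ggplot2::geom_point(data = bounds,
                        ggplot2::aes(x = .data$t_s, y = .data$larva_id),
                        inherit.aes = FALSE,
                        shape = "|", size = 3, color = "red") +
    ggplot2::scale_fill_manual(values = greys, drop = FALSE) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "zone") +
    ggplot2::theme_minimal()
}

#' Proportion of time (or track length) per distance category
#'
#' @param per_category Named list of per-larva named vectors (each of the
#'   seven categories), or a single named vector.
#' @return Tibble `category`, `proportion` (summing to 1).
#' @export
category_proportions <- function(per_category) {
  if (is.list(per_category)) {
    per_category <- Reduce(`+`, per_category)
  }
  stopifnot(length(per_category) == 7, sum(per_category) > 0)
  tibble::tibble(
    category = factor(names(per_category), levels = names(per_category)),
    proportion = as.numeric(per_category) / sum(per_category)
  )
}

#' Pie chart of per-category proportions
#'
#' Wedges run counterclockwise from the innermost category (dark) to the
#' edge category (light).
#'
#' @param per_category As in [category_proportions()].
#' @param palette Two colors interpolated across the seven categories.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
zone_pie_figure <- function(per_category, palette = c("darkred", "bisque"),
                            title = NULL) {
  props <- category_proportions(per_category)
  cols <- grDevices::colorRampPalette(palette)(nrow(props))
  ggplot2::ggplot(props, ggplot2::aes(x = "", y = .data$proportion,
                                      fill = .data$category)) +
    ggplot2::geom_col(width = 1, color = "white") +
    ggplot2::coord_polar(theta = "y", direction = -1) +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "category (mm)") +
    ggplot2::theme_void()
}

#' Box plot comparing a metric between phases
#'
#' Boxes show the median as middle line, the 25% and 75% quantiles as box
#' boundaries and the minimum/maximum as whiskers; a significance star
#' annotation is added when a p-value is supplied.
#'
#' @param metrics Per-larva per-phase metrics tibble (from
#'   [phase_metrics()] rows, or `run_pipeline()$metrics`).
#' @param metric Column name to plot.
#' @param phases Which phases to show.
#' @param p_value Optional p-value to annotate with stars.
#' @return A ggplot object.
#' @export
metric_box_figure <- function(metrics, metric = "search_score",
                              phases = c("baseline", "search_analyzed"),
                              p_value = NULL) {
  df <- metrics[metrics$phase %in% phases, c("phase", metric)]
  names(df)[2] <- "value"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$value)) +
    ggplot2::geom_boxplot(coef = Inf) +  # whiskers to min/max
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_classic()
  if (!is.null(p_value)) {
    p <- p + ggplot2::annotate(
      "text", x = 1.5, y = max(df$value, na.rm = TRUE),
      label = significance_stars(p_value), vjust = -0.5)
  }
  p
}

#' Mean distance to center over time with individual traces
#'
#' @param bins `minute_bins` tibble from [run_pipeline()], one phase.
#' @return A ggplot object.
#' @export
distance_time_figure <- function(bins) {
  stopifnot(all(c("larva_id", "bin", "mean_r_mm") %in% names(bins)))
  mean_df <- dplyr::summarise(dplyr::group_by(bins, .data$bin),
                              mean_r_mm = mean(.data$mean_r_mm),
                              .groups = "drop")
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$mean_r_mm)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$larva_id),
                       color = "grey70") +
    ggplot2::geom_line(data = mean_df, color = "blue", linewidth = 1) +
    ggplot2::labs(x = "minute", y = "distance to center (mm)") +
    ggplot2::theme_classic()
}
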