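#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' objects: the average-evolvability trajectory of a run (extinction events as
#' dashed verticals), the across-run mean trajectory of a condition, and the
#' per-niche evolvability heatmap. `plot_conditions()` overlays several
#' conditions' mean trajectories for the side-by-side comparison the headline
#' figure makes.
#'
#' @param object A `run_result`, `condition_result` or `heatmap_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name extinctsim-plots
NULL

#' @rdname extinctsim-plots
#' @export
autoplot.run_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$series,
                       ggplot2::aes(x = .data$generation, y = .data$avg_evolvability)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "Average evolvability")
  if (length(object$extinction_events) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$extinction_events,
                                 linetype = "dashed", colour = "grey60")
  }
  p
}

#' @rdname extinctsim-plots
#' @export
autoplot.condition_result <- function(object, ...) {
  ggplot2::ggplot(object$mean_series,
                  ggplot2::aes(x = .data$generation, y = .data$avg_evolvability)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "Average evolvability",
                  title = object$name)
}

#' @rdname extinctsim-plots
#' @export
autoplot.heatmap_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$niche_x, y = .data$niche_y,
                                   fill = .data$evolvability)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Niche x", y = "Niche y", fill = "Evolvability")
}

#' @rdname extinctsim-plots
#' @param conditions A list of `condition_result` objects.
#' @export
plot_conditions <- function(conditions, ...) {
  df <- purrr::map_dfr(conditions, function(cr) {
    tibble::tibble(condition = cr$name, cr$mean_series)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$avg_evolvability,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "Average evolvability", colour = "Condition")
}

#' @export
plot.run_result <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.condition_result <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.heatmap_grid <- function(x, ...) print(autoplot(x, ...))
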