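#' Population summary metrics
#'
#' `average_evolvability()` is the arithmetic mean evolvability over all
#' organisms; `occupied_niche_count()` is the number of niches holding at least
#' one organism.
#'
#' @param pop A `population`.
#' @return A single number.
#' @examples
#' cfg <- sim_config(grid_width = 3, grid_height = 3, generations = 1)
#' average_evolvability(seed_population(cfg))
#' @export
average_evolvability <- function(pop) {
  if (nrow(pop) == 0L) {
    abort("Average evolvability is undefined for an empty population.",
          class = "extinctsim_empty_population")
  }
  mean(pop$evolvability)
}

#' @rdname average_evolvability
#' @export
occupied_niche_count <- function(pop) {
  if (nrow(pop) == 0L) return(0L)
  length(unique(niche_key(pop)))
}

#' Per-niche mean evolvability heatmap
#'
#' Maps each occupied niche to the mean evolvability of its occupants;
#' unoccupied niches are `NA`. This is the substrate of the evolvability
#' snapshot figures: lighter cells mark more evolvable neighbourhoods.
#'
#' @param pop A `population`.
#' @param grid_width,grid_height Torus dimensions; default to the population's
#'   own attributes.
#' @return A `heatmap_grid`: a `grid_height` x `grid_width` numeric matrix
#'   (rows indexed by `niche_y + 1`, columns by `niche_x + 1`) with `NA` in
#'   empty cells.
#' @export
evolvability_heatmap <- function(pop,
                                 grid_width = attr(pop, "grid_width"),
                                 grid_height = attr(pop, "grid_height")) {
  m <- matrix(NA_real_, nrow = grid_height, ncol = grid_width)
  if (nrow(pop) > 0L) {
    means <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(pop), .data$niche_x, .data$niche_y),
      evolvability = mean(.data$evolvability), .groups = "drop")
    m[cbind(means$niche_y + 1L, means$niche_x + 1L)] <- means$evolvability
  }
  structure(m, class = c("heatmap_grid", "matrix", "array"))
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf("<heatmap_grid> %d x %d, %d occupied cells, mean evolvability %.4f\n",
              ncol(x), nrow(x), sum(!is.na(x)), mean(x, na.rm = TRUE)))
  invisible(x)
}

#' @rdname evolvability_heatmap
#' @param x A `heatmap_grid`.
#' @param ... Unused.
#' @export
tidy.heatmap_grid <- function(x, ...) {
  idx <- which(!is.na(x), arr.ind = TRUE)
  tibble::tibble(niche_x = as.integer(idx[, "col"] - 1L),
                 niche_y = as.integer(idx[, "row"] - 1L),
                 evolvability = x[idx])
}

#' Toroidal distance between niches
#'
#' Distance on the wrapped grid, using per axis the minimal wrapped
#' displacement `min(|d|, dim - |d|)`. The default metric is Euclidean;
#' Manhattan is available since correlation analyses should be robust to the
#' choice. Vectorised over coordinates.
#'
#' @param ax,ay,bx,by Integer vectors of 0-based coordinates.
#' @param grid_width,grid_height Torus dimensions.
#' @param method `"euclidean"` (default) or `"manhattan"`.
#' @return Numeric vector of distances.
#' @examples
#' toroidal_distance(0, 0, 400, 0, 401, 401) # wraps: distance 1
#' @export
toroidal_distance <- function(ax, ay, bx, by, grid_width, grid_height,
                              method = c("euclidean", "manhattan")) {
  method <- match.arg(method)
  dx <- abs(ax - bx)
  dx <- pmin(dx, grid_width - dx)
  dy <- abs(ay - by)
  dy <- pmin(dy, grid_height - dy)
  if (method == "euclidean") sqrt(dx^2 + dy^2) else dx + dy
}

#' Rebound magnitude after an extinction event
#'
#' How many additional niches are occupied `lag` generations after an
#' extinction event, relative to the occupied count immediately after the
#' event (before that generation's reproduction). Larger rebounds indicate a
#' population that re-radiates faster, a population-level proxy for
#' evolvability.
#'
#' @param result A `run_result`.
#' @param extinction_generation One of `result$extinction_events`.
#' @param lag Positive integer number of generations (default 10).
#' @return Integer rebound (occupied at `extinction_generation + lag` minus
#'   occupied immediately after the extinction).
#' @export
rebound_magnitude <- function(result, extinction_generation, lag = 10L) {
  lag <- as.integer(lag)
  if (!extinction_generation %in% result$extinction_events) {
    abort("`extinction_generation` is not a logged extinction event.",
          class = "extinctsim_metric_error")
  }
  horizon <- result$config$generations
  if (extinction_generation + lag > horizon) {
    abort("`lag` runs past the end of the simulation.",
          class = "extinctsim_metric_error")
  }
  after <- result$extinction_log$occupied_after[
    result$extinction_log$generation == extinction_generation]
  later <- result$series$occupied_niches[
    result$series$generation == extinction_generation + lag]
  as.integer(later - after)
}
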