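#' Run one simulation
#'
#' Executes the full generational loop: the run RNG is seeded from
#' `config$seed` (if non-`NULL`), the extinction schedule is expanded into
#' event generations, the founder population is placed, and then for each
#' generation `g = 1, ..., generations` an extinction (if scheduled at `g`) is
#' applied *before* reproduction, followed by one [step_generation()]. The
#' per-generation series (including generation 0) records average
#' evolvability, occupied-niche count and population size after the
#' generation completes. Identical configs and seeds give bit-identical
#' results.
#'
#' @param config A [sim_config()].
#' @return An object of class `run_result`: a list with
#'   \describe{
#'     \item{series}{tibble `generation`, `avg_evolvability`,
#'       `occupied_niches`, `population_size` with `generations + 1` rows.}
#'     \item{extinction_events}{integer vector of generations at which an
#'       extinction was applied.}
#'     \item{extinction_log}{tibble `generation`, `occupied_before`,
#'       `occupied_after` (occupied-niche counts around each event, measured
#'       before that generation's reproduction).}
#'     \item{snapshots}{named list of `population` snapshots at
#'       `config$snapshot_generations` (end of generation).}
#'     \item{final_population}{the `population` after the last generation.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' res <- run_simulation(sim_config(grid_width = 11, grid_height = 11,
#'                                  niche_capacity = 5, generations = 20, seed = 1))
#' tail(res$series, 3)
#' @export
run_simulation <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  events <- event_generations(config$schedule, config$generations)
  founder <- seed_population(config)
  n <- config$generations

  raw <- cpp_run_simulation(founder$niche_x, founder$niche_y, founder$evolvability,
                            config$grid_width, config$grid_height,
                            config$niche_capacity, config$offspring_per_parent,
                            config$evolvability_mutation_rate,
                            config$evolvability_perturbation_half_width,
                            n, events, config$severity,
                            config$snapshot_generations)

  as_pop <- function(snap, generation) {
    new_population(snap$niche_x, snap$niche_y, snap$evolvability,
                   generation, config$grid_width, config$grid_height)
  }
  snapshots <- purrr::imap(raw$snapshots, function(snap, g) {
    as_pop(snap, as.integer(g))
  })

  structure(list(
    series = tibble::tibble(generation = 0:n,
                            avg_evolvability = raw$avg_evolvability,
                            occupied_niches = raw$occupied_niches,
                            population_size = raw$population_size),
    extinction_events = raw$ext_generation,
    extinction_log = tibble::tibble(generation = raw$ext_generation,
                                    occupied_before = raw$ext_before,
                                    occupied_after = raw$ext_after),
    snapshots = snapshots,
    final_population = new_population(raw$final_x, raw$final_y, raw$final_ev,
                                      n, config$grid_width, config$grid_height),
    config = config
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  fin <- x$series[nrow(x$series), ]
  cat(sprintf(
    "<run_result> %d generations on %d x %d grid; %d extinction events\n",
    x$config$generations, x$config$grid_width, x$config$grid_height,
    length(x$extinction_events)))
  cat(sprintf("  final: avg evolvability %.4f, %d occupied niches, %d organisms\n",
              fin$avg_evolvability, fin$occupied_niches, fin$population_size))
  invisible(x)
}

#' @rdname run_simulation
#' @param x A `run_result`.
#' @param ... Unused.
#' @export
tidy.run_result <- function(x, ...) {
  x$series
}

#' @rdname run_simulation
#' @export
glance.run_result <- function(x, ...) {
  fin <- x$series[nrow(x$series), ]
  tibble::tibble(
    generations = x$config$generations,
    n_extinctions = length(x$extinction_events),
    final_avg_evolvability = fin$avg_evolvability,
    final_occupied_niches = fin$occupied_niches,
    final_population_size = fin$population_size
  )
}

#' Detect the saturation generation of a run
#'
#' The saturation generation is the first generation after which the
#' occupied-niche count does not increase for `window` consecutive
#' generations. In a Control run this marks the point where every reachable
#' niche is filled and evolvability changes only by drift.
#'
#' @param result A `run_result`.
#' @param window Integer, number of consecutive non-increasing generations
#'   required (default 100).
#' @return The saturation generation (integer), or `NA_integer_` if the run
#'   never plateaus for that long.
#' @export
detect_saturation <- function(result, window = 100L) {
  occ <- result$series$occupied_niches
  n <- length(occ)
  window <- as.integer(window)
  for (i in seq_len(n - window)) {
    if (all(occ[(i + 1L):(i + window)] <= occ[i])) {
      return(result$series$generation[i])
    }
  }
  NA_integer_
}
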