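#' Mutate niche coordinates
#'
#' A niche mutation shifts a coordinate by one unit in exactly one dimension,
#' chosen uniformly among the four cardinal moves, with toroidal wraparound.
#' Vectorised over coordinates.
#'
#' @param niche_x,niche_y Integer vectors of 0-based coordinates.
#' @param grid_width,grid_height Torus dimensions.
#' @return A tibble with columns `niche_x`, `niche_y`, one row per input.
#' @examples
#' set.seed(1)
#' mutate_niche(0L, 0L, 401L, 401L) # may wrap to (400, 0) or (0, 400)
#' @export
mutate_niche <- function(niche_x, niche_y, grid_width, grid_height) {
  stopifnot(length(niche_x) == length(niche_y))
  if (any(niche_x < 0L | niche_x >= grid_width | niche_y < 0L | niche_y >= grid_height)) {
    abort("Coordinates must lie within the grid.", class = "extinctsim_pop_error")
  }
  # evolvability 1 forces a shift; reuses the offspring machinery so the
  # move-set definition lives in exactly one place
  out <- cpp_make_offspring(as.integer(niche_x), as.integer(niche_y),
                            rep(1.0, length(niche_x)),
                            as.integer(grid_width), as.integer(grid_height),
                            0.0, 0.0)
  tibble::tibble(niche_x = out$niche_x, niche_y = out$niche_y)
}

#' Generate offspring
#'
#' Each parent yields one offspring per call. The offspring inherits the
#' parent's niche unless a niche shift fires (probability = parent
#' evolvability), in which case it moves to a uniformly chosen cardinal
#' neighbour with wraparound. Independently, with probability
#' `evolvability_mutation_rate` the inherited evolvability is perturbed by a
#' Uniform(-h, h) draw (`h = evolvability_perturbation_half_width`) and clamped
#' to \[0, 1\].
#'
#' @param parents A `population` (or tibble with `niche_x`, `niche_y`,
#'   `evolvability`).
#' @param config A [sim_config()].
#' @return A tibble with columns `niche_x`, `niche_y`, `evolvability` and
#'   `resident` (`TRUE` if the offspring stayed in its parent's niche), one row
#'   per parent.
#' @export
make_offspring <- function(parents, config) {
  validate_sim_config(config)
  out <- cpp_make_offspring(parents$niche_x, parents$niche_y, parents$evolvability,
                            config$grid_width, config$grid_height,
                            config$evolvability_mutation_rate,
                            config$evolvability_perturbation_half_width)
  tibble::tibble(niche_x = out$niche_x, niche_y = out$niche_y,
                 evolvability = out$evolvability, resident = out$resident)
}

#' Enforce the niche carrying capacity with resident priority
#'
#' Offspring produced within a niche (residents) fill it first; immigrants
#' (offspring that shifted in from a neighbouring niche) can only take slots
#' residents leave free. If a niche becomes full from residents alone, no
#' immigrant can enter it. Within each priority class the survivors are a
#' uniform random subset.
#'
#' @param offspring A tibble as returned by [make_offspring()]: columns
#'   `niche_x`, `niche_y`, `evolvability`, `resident`.
#' @param config A [sim_config()] supplying grid dimensions and
#'   `niche_capacity`.
#' @return The surviving offspring rows, in input order; no niche exceeds
#'   capacity.
#' @export
enforce_capacity <- function(offspring, config) {
  validate_sim_config(config)
  if (config$niche_capacity < 1L) {
    abort("`niche_capacity` must be >= 1.", class = "extinctsim_config_error")
  }
  keep <- cpp_enforce_capacity(offspring$niche_x, offspring$niche_y,
                               offspring$resident,
                               config$grid_width, config$grid_height,
                               config$niche_capacity)
  offspring[keep, , drop = FALSE]
}

#' Advance the population one generation
#'
#' Generations are non-overlapping: every parent is replaced by
#' `offspring_per_parent` offspring drawn with [make_offspring()], and the
#' survivors are selected by the resident-priority capacity rule of
#' [enforce_capacity()]. In the single-niche, zero-evolvability limit the
#' population size follows `min(offspring_per_parent^t, niche_capacity)`.
#'
#' @param pop A `population`.
#' @param config A [sim_config()].
#' @return The next-generation `population`; its `generation` attribute is
#'   incremented and an `occupied_niches` attribute carries the survivor
#'   niche count.
#' @export
step_generation <- function(pop, config) {
  validate_sim_config(config)
  if (nrow(pop) == 0L) {
    abort("Cannot step an empty population.", class = "extinctsim_empty_population")
  }
  res <- cpp_step_generation(pop$niche_x, pop$niche_y, pop$evolvability,
                             config$grid_width, config$grid_height,
                             config$niche_capacity, config$offspring_per_parent,
                             config$evolvability_mutation_rate,
                             config$evolvability_perturbation_half_width)
  out <- pop_like(pop, res$niche_x, res$niche_y, res$evolvability,
                  generation = attr(pop, "generation") + 1L)
  attr(out, "occupied_niches") <- res$occupied
  out
}

#' Apply a mass-extinction event
#'
#' `severity` occupied niches are chosen uniformly at random without
#' replacement and spared; every organism in any other niche is removed. If the
#' population occupies no more niches than `severity`, it is left untouched.
#'
#' @param pop A non-empty `population`.
#' @param severity Positive integer, number of occupied niches to spare.
#' @return The surviving `population`.
#' @export
apply_extinction <- function(pop, severity) {
  if (nrow(pop) == 0L) {
    abort("Cannot apply an extinction to an empty population.",
          class = "extinctsim_empty_population")
  }
  severity <- as.integer(severity)
  if (severity < 1L) {
    abort("`severity` must be >= 1.", class = "extinctsim_config_error")
  }
  key <- niche_key(pop)
  occupied <- unique(key)
  if (length(occupied) <= severity) {
    return(pop)
  }
  spared <- sample(occupied, severity)
  keep <- key %in% spared
  pop_like(pop, pop$niche_x[keep], pop$niche_y[keep], pop$evolvability[keep])
}
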