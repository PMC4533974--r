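#' Population objects
#'
#' A population is a tibble with one row per organism and columns `niche_x`,
#' `niche_y` (0-based torus coordinates) and `evolvability` (the heritable
#' per-offspring niche-shift probability). Grid dimensions and the generation
#' counter travel along as attributes so that metrics and plotting know the
#' torus they live on.
#'
#' @param niche_x,niche_y Integer vectors of 0-based coordinates.
#' @param evolvability Numeric vector of probabilities in \[0, 1\].
#' @param generation Non-negative integer generation counter.
#' @param grid_width,grid_height Torus dimensions.
#' @return A tibble of class `population`.
#' @export
new_population <- function(niche_x, niche_y, evolvability,
                           generation, grid_width, grid_height) {
  out <- tibble::tibble(niche_x = as.integer(niche_x),
                        niche_y = as.integer(niche_y),
                        evolvability = as.numeric(evolvability))
  attr(out, "generation") <- as.integer(generation)
  attr(out, "grid_width") <- as.integer(grid_width)
  attr(out, "grid_height") <- as.integer(grid_height)
  class(out) <- c("population", class(out))
  out
}

#' @rdname new_population
#' @param pop A population object.
#' @export
validate_population <- function(pop) {
  w <- attr(pop, "grid_width")
  h <- attr(pop, "grid_height")
  if (is.null(w) || is.null(h)) {
    abort("Population lacks grid dimension attributes.", class = "extinctsim_pop_error")
  }
  if (nrow(pop) > 0) {
    if (any(pop$niche_x < 0L) || any(pop$niche_x >= w) ||
        any(pop$niche_y < 0L) || any(pop$niche_y >= h)) {
      abort("Niche coordinates fall outside the grid.", class = "extinctsim_pop_error")
    }
    if (any(pop$evolvability < 0) || any(pop$evolvability > 1)) {
      abort("Evolvability values must lie in [0, 1].", class = "extinctsim_pop_error")
    }
  }
  invisible(pop)
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d organisms, generation %d, grid %d x %d\n",
              nrow(x), attr(x, "generation"),
              attr(x, "grid_width"), attr(x, "grid_height")))
  NextMethod()
}

# linear niche key: y * width + x (0-based)
niche_key <- function(pop) {
  pop$niche_y * attr(pop, "grid_width") + pop$niche_x
}

# rebuild a population, preserving attributes, from a subset or new columns
pop_like <- function(pop, niche_x, niche_y, evolvability, generation = NULL) {
  new_population(niche_x, niche_y, evolvability,
                 generation %||% attr(pop, "generation"),
                 attr(pop, "grid_width"), attr(pop, "grid_height"))
}

#' Seed the founding population
#'
#' Places a single ancestral organism at the centre niche of the torus
#' (`floor(width / 2)`, `floor(height / 2)`) with the configured initial
#' evolvability, at generation 0.
#'
#' @param config A [sim_config()].
#' @return A `population` with one organism.
#' @examples
#' seed_population(sim_config(grid_width = 3, grid_height = 3, generations = 1))
#' @export
seed_population <- function(config) {
  validate_sim_config(config)
  new_population(config$grid_width %/% 2L, config$grid_height %/% 2L,
                 config$initial_evolvability,
                 generation = 0L,
                 grid_width = config$grid_width,
                 grid_height = config$grid_height)
}
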