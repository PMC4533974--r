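#' Simulation configuration
#'
#' Bundles every parameter of the limited-capacity niche model. Defaults
#' reproduce the full-scale study conditions: a 401 x 401 toroidal grid seeded
#' with one founder at the centre niche with evolvability 0.025; two offspring
#' per organism per (non-overlapping) generation; each offspring's niche shifts
#' to a random cardinal neighbour with probability equal to its parent's
#' evolvability; the evolvability value itself is perturbed with probability
#' 0.005 by a draw from Uniform(-0.0025, 0.0025), clamped to \[0, 1\]; runs
#' last 15000 generations. Extinction events, when scheduled, spare `severity`
#' randomly chosen occupied niches and remove everything else.
#'
#' The carrying capacity per niche is not pinned down by the model's source
#' description; it defaults to 10 and all headline effects are qualitative
#' across reasonable capacities.
#'
#' @param grid_width,grid_height Positive integers, torus dimensions.
#' @param niche_capacity Positive integer, maximum organisms per niche.
#' @param offspring_per_parent Positive integer, offspring per organism per
#'   generation (parents do not survive).
#' @param initial_evolvability Founder niche-shift probability in \[0, 1\].
#' @param evolvability_mutation_rate Probability that an offspring's
#'   evolvability is perturbed.
#' @param evolvability_perturbation_half_width Non-negative half-width `h` of
#'   the Uniform(-h, h) evolvability perturbation.
#' @param generations Positive integer, run horizon.
#' @param schedule An [extinction schedule][schedule_none].
#' @param severity Positive integer, occupied niches spared per extinction.
#' @param seed Integer RNG seed for the run, or `NULL` to use the current RNG
#'   state.
#' @param snapshot_generations Integer vector of generations at which to keep a
#'   full population snapshot in the run result (besides the final
#'   population, which is always kept).
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(grid_width = 11, grid_height = 11, generations = 50, seed = 1)
#' cfg$niche_capacity
#' @export
sim_config <- function(grid_width = 401L,
                       grid_height = 401L,
                       niche_capacity = 10L,
                       offspring_per_parent = 2L,
                       initial_evolvability = 0.025,
                       evolvability_mutation_rate = 0.005,
                       evolvability_perturbation_half_width = 0.0025,
                       generations = 15000L,
                       schedule = schedule_none(),
                       severity = 5L,
                       seed = NULL,
                       snapshot_generations = integer(0)) {
  cfg <- structure(list(
    grid_width = as.integer(grid_width),
    grid_height = as.integer(grid_height),
    niche_capacity = as.integer(niche_capacity),
    offspring_per_parent = as.integer(offspring_per_parent),
    initial_evolvability = as.numeric(initial_evolvability),
    evolvability_mutation_rate = as.numeric(evolvability_mutation_rate),
    evolvability_perturbation_half_width = as.numeric(evolvability_perturbation_half_width),
    generations = as.integer(generations),
    schedule = schedule,
    severity = as.integer(severity),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    snapshot_generations = as.integer(snapshot_generations)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(msg) abort(msg, class = "extinctsim_config_error")
  pos_int <- function(v) length(v) == 1L && !is.na(v) && v >= 1L
  prob <- function(v) length(v) == 1L && !is.na(v) && v >= 0 && v <= 1
  if (!pos_int(cfg$grid_width) || !pos_int(cfg$grid_height)) {
    fail("Grid dimensions must be positive integers.")
  }
  if (!pos_int(cfg$niche_capacity)) fail("`niche_capacity` must be >= 1.")
  if (!pos_int(cfg$offspring_per_parent)) fail("`offspring_per_parent` must be >= 1.")
  if (!pos_int(cfg$generations)) fail("`generations` must be >= 1.")
  if (!pos_int(cfg$severity)) fail("`severity` must be >= 1.")
  if (!prob(cfg$initial_evolvability)) fail("`initial_evolvability` must lie in [0, 1].")
  if (!prob(cfg$evolvability_mutation_rate)) fail("`evolvability_mutation_rate` must lie in [0, 1].")
  if (length(cfg$evolvability_perturbation_half_width) != 1L ||
      is.na(cfg$evolvability_perturbation_half_width) ||
      cfg$evolvability_perturbation_half_width < 0) {
    fail("`evolvability_perturbation_half_width` must be non-negative.")
  }
  if (!inherits(cfg$schedule, "extinction_schedule")) {
    fail("`schedule` must be an extinction_schedule object.")
  }
  if (any(cfg$snapshot_generations < 0) || anyNA(cfg$snapshot_generations)) {
    fail("`snapshot_generations` must be non-negative integers.")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  grid: %d x %d (toroidal), capacity %d per niche\n",
              x$grid_width, x$grid_height, x$niche_capacity))
  cat(sprintf("  founder evolvability %.4g; evolvability mutation rate %.4g, half-width %.4g\n",
              x$initial_evolvability, x$evolvability_mutation_rate,
              x$evolvability_perturbation_half_width))
  cat(sprintf("  %d offspring/parent, %d generations, severity %d\n",
              x$offspring_per_parent, x$generations, x$severity))
  cat("  schedule: ")
  print(x$schedule)
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Named configuration profiles
#'
#' `profile_paper()` is the full-scale setup (401 x 401 grid, 15000
#' generations) behind the headline results. `profile_desk()` is a reduced
#' scale suited to interactive work and continuous testing: a 101 x 101 grid
#' run for 3000 generations, which preserves the qualitative structure (the
#' grid saturates well before the horizon, leaving a long drift phase) at a
#' small fraction of the cost. Extinction intervals should be scaled
#' accordingly (e.g. 200/400/800 instead of 1000/2000/4000).
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
profile_desk <- function(...) {
  defaults <- list(grid_width = 101L, grid_height = 101L, niche_capacity = 10L,
                   generations = 3000L)
  over <- list(...)
  do.call(sim_config, utils::modifyList(defaults, over))
}

#' @rdname profile_desk
#' @export
profile_paper <- function(...) {
  do.call(sim_config, list(...))
}

#' Read a simulation configuration from a YAML file
#'
#' The YAML file mirrors [sim_config()] field for field. The schedule is given
#' by a `schedule` key (`"none"`, `"fixed"` or `"random_uniform"`) together
#' with `interval` (fixed) or `min_interval`/`max_interval` (random).
#'
#' @param path Path to a YAML file.
#' @param overrides Named list of field overrides (e.g. from CLI flags); they
#'   take precedence over file values.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  variant <- raw$schedule %||% "none"
  schedule <- switch(as.character(variant),
    none = schedule_none(),
    fixed = schedule_fixed(raw$interval),
    random_uniform = schedule_random(raw$min_interval, raw$max_interval),
    abort(sprintf("Unknown schedule variant '%s'.", variant),
          class = "extinctsim_config_error"))
  keep <- intersect(names(raw), setdiff(names(formals(sim_config)), "schedule"))
  do.call(sim_config, c(raw[keep], list(schedule = schedule)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
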