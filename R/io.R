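#' Write and read run artefacts
#'
#' `write_run_csv()` writes a run's per-generation series with header
#' `generation,avg_evolvability,occupied_niches,population_size`;
#' `read_run_csv()` reads it back to an identical tibble.
#' `write_population_csv()` writes a population snapshot with header
#' `niche_x,niche_y,evolvability`, one row per organism.
#' `write_heatmap_tsv()` writes a [heatmap grid][evolvability_heatmap] as a
#' headerless TSV matrix with empty cells as `NA`.
#'
#' @param result A `run_result`.
#' @param pop A `population`.
#' @param grid A `heatmap_grid`.
#' @param path Output file path.
#' @return `path` (or, for the reader, the tibble).
#' @export
write_run_csv <- function(result, path) {
  readr::write_csv(result$series, path)
  invisible(path)
}

#' @rdname write_run_csv
#' @export
read_run_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    generation = readr::col_integer(),
    avg_evolvability = readr::col_double(),
    occupied_niches = readr::col_integer(),
    population_size = readr::col_integer()))
}

#' @rdname write_run_csv
#' @export
write_population_csv <- function(pop, path) {
  readr::write_csv(tibble::as_tibble(pop)[, c("niche_x", "niche_y", "evolvability")],
                   path)
  invisible(path)
}

#' @rdname write_run_csv
#' @export
write_heatmap_tsv <- function(grid, path) {
  utils::write.table(unclass(grid), path, sep = "\t", na = "NA",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the full output set of a condition
#'
#' Writes, under `out_dir`:
#' \itemize{
#'   \item `run_<i>.csv` — each run's per-generation series;
#'   \item `run_<i>_extinctions.json` — each run's extinction generations as a
#'     JSON array;
#'   \item `final_populations.csv` — all runs' final populations pooled, with a
#'     leading `run` column;
#'   \item `heatmap_run1_gen<g>.tsv` — evolvability heatmaps of run 1 at each
#'     snapshot generation recorded in the run (set `snapshot_generations` in
#'     the config, e.g. `c(2000, generations)`, to mirror the usual snapshot
#'     figure); none if no snapshots were recorded;
#'   \item `summary.json` — condition name, per-run final average
#'     evolvabilities and their mean, ready for pairwise tests.
#' }
#' Re-emission from identical inputs is bit-identical.
#'
#' @param result A `condition_result`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_condition_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  emit <- function(f) files <<- c(files, f)
  for (i in seq_along(result$runs)) {
    r <- result$runs[[i]]
    f <- file.path(out_dir, sprintf("run_%d.csv", i))
    write_run_csv(r, f)
    emit(f)
    f <- file.path(out_dir, sprintf("run_%d_extinctions.json", i))
    jsonlite::write_json(r$extinction_events, f, digits = NA)
    emit(f)
  }
  pooled <- purrr::map_dfr(seq_along(result$runs), function(i) {
    tibble::tibble(run = i,
                   tibble::as_tibble(result$runs[[i]]$final_population))
  })
  f <- file.path(out_dir, "final_populations.csv")
  readr::write_csv(pooled, f)
  emit(f)
  r1 <- result$runs[[1]]
  snaps <- r1$snapshots
  for (g in names(snaps)) {
    f <- file.path(out_dir, sprintf("heatmap_run1_gen%s.tsv", g))
    write_heatmap_tsv(evolvability_heatmap(snaps[[g]]), f)
    emit(f)
  }
  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(condition = result$name,
         n_runs = length(result$runs),
         final_avg_evolvability = result$final_evolvability,
         mean_final_avg_evolvability = mean(result$final_evolvability),
         extinction_events = purrr::map(result$runs, "extinction_events")),
    f, auto_unbox = TRUE, digits = NA)
  emit(f)
  invisible(files)
}
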