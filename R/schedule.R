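#' Extinction schedules
#'
#' An extinction schedule decides at which generations a mass-extinction event
#' strikes. Three regimes are supported: no extinctions at all
#' (`schedule_none()`, the Control regime), events at a fixed interval
#' (`schedule_fixed()`), and events separated by random gaps drawn uniformly
#' from an inclusive integer range (`schedule_random()`). An event scheduled at
#' generation `g` is applied at the *start* of generation `g`, before
#' reproduction; the first event never falls on generation 0.
#'
#' @param interval Positive integer, generations between consecutive events.
#' @param min_interval,max_interval Positive integers with
#'   `min_interval <= max_interval`; each gap between events is drawn uniformly
#'   from the inclusive integer range `[min_interval, max_interval]`.
#' @return An object of class `extinction_schedule`.
#' @examples
#' event_generations(schedule_fixed(1000), horizon = 3000)
#' @export
schedule_none <- function() {
  structure(list(variant = "none"), class = "extinction_schedule")
}

#' @rdname schedule_none
#' @export
schedule_fixed <- function(interval) {
  if (!is.numeric(interval) || length(interval) != 1L || interval < 1 ||
      interval != as.integer(interval)) {
    abort("`interval` must be a single positive integer.", class = "extinctsim_config_error")
  }
  structure(list(variant = "fixed", interval = as.integer(interval)),
            class = "extinction_schedule")
}

#' @rdname schedule_none
#' @export
schedule_random <- function(min_interval, max_interval) {
  ok <- function(v) is.numeric(v) && length(v) == 1L && v >= 1 && v == as.integer(v)
  if (!ok(min_interval) || !ok(max_interval)) {
    abort("Interval bounds must be single positive integers.", class = "extinctsim_config_error")
  }
  if (min_interval > max_interval) {
    abort("`min_interval` must not exceed `max_interval`.", class = "extinctsim_config_error")
  }
  structure(list(variant = "random_uniform",
                 min_interval = as.integer(min_interval),
                 max_interval = as.integer(max_interval)),
            class = "extinction_schedule")
}

#' @export
print.extinction_schedule <- function(x, ...) {
  desc <- switch(x$variant,
    none = "none (no extinction events)",
    fixed = sprintf("fixed interval %d", x$interval),
    random_uniform = sprintf("random uniform intervals [%d, %d]",
                             x$min_interval, x$max_interval))
  cat("<extinction_schedule>", desc, "\n")
  invisible(x)
}

#' Generations at which extinction events occur
#'
#' Expands a schedule into the sorted list of event generations within a run
#' horizon. For the fixed variant these are the multiples of the interval; for
#' the random variant each gap is drawn uniformly from the inclusive integer
#' range, consuming the current R RNG state, so results are reproducible under
#' `set.seed()`. Events past the horizon are dropped.
#'
#' @param schedule An [extinction schedule][schedule_none].
#' @param horizon Positive integer, the number of generations in the run.
#' @return Strictly increasing integer vector of event generations in
#'   `[1, horizon]`; empty for the none variant.
#' @examples
#' event_generations(schedule_fixed(1000), 4000)
#' @export
event_generations <- function(schedule, horizon) {
  stopifnot(inherits(schedule, "extinction_schedule"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1) {
    abort("`horizon` must be a positive integer.", class = "extinctsim_config_error")
  }
  horizon <- as.integer(horizon)
  switch(schedule$variant,
    none = integer(0),
    fixed = if (schedule$interval > horizon) integer(0) else
      seq.int(schedule$interval, horizon, by = schedule$interval),
    random_uniform = {
      lo <- schedule$min_interval
      hi <- schedule$max_interval
      out <- integer(horizon %/% lo + 1L)
      n_out <- 0L
      g <- 0L
      repeat {
        g <- g + lo + sample.int(hi - lo + 1L, 1L) - 1L
        if (g > horizon) break
        n_out <- n_out + 1L
        out[n_out] <- g
      }
      out[seq_len(n_out)]
    })
}
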