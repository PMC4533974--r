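test_that("the founder sits at the centre niche with the configured evolvability", {
  pop <- seed_population(sim_config())
  expect_equal(nrow(pop), 1L)
  expect_equal(c(pop$niche_x, pop$niche_y), c(200L, 200L))
  expect_equal(pop$evolvability, 0.025)
  expect_equal(attr(pop, "generation"), 0L)

  odd <- seed_population(sim_config(grid_width = 3, grid_height = 3, generations = 1))
  expect_equal(c(odd$niche_x, odd$niche_y), c(1L, 1L))
  even <- seed_population(sim_config(grid_width = 4, grid_height = 4, generations = 1))
  expect_equal(c(even$niche_x, even$niche_y), c(2L, 2L))
})

test_that("niche mutation picks each cardinal neighbour uniformly", {
  set.seed(1)
  n <- 20000L
  moved <- mutate_niche(rep(200L, n), rep(200L, n), 401L, 401L)
  key <- paste(moved$niche_x, moved$niche_y)
  expect_setequal(unique(key), c("199 200", "201 200", "200 199", "200 201"))
  freq <- as.numeric(table(key)) / n
  # binomial CI around 1/4
  expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / n)))
})

test_that("niche mutation wraps on the torus and moves exactly one step", {
  set.seed(2)
  n <- 500L
  moved <- mutate_niche(rep(0L, n), rep(0L, n), 401L, 401L)
  expect_true(all(moved$niche_x %in% c(0L, 1L, 400L)))
  expect_true(all(moved$niche_y %in% c(0L, 1L, 400L)))
  d <- toroidal_distance(moved$niche_x, moved$niche_y, 0L, 0L, 401L, 401L,
                         method = "manhattan")
  expect_true(all(d == 1))
  # degenerate 1x1 grid wraps to itself
  self <- mutate_niche(0L, 0L, 1L, 1L)
  expect_equal(c(self$niche_x, self$niche_y), c(0L, 0L))
})

test_that("offspring shift niches at exactly the parental evolvability", {
  cfg <- tiny_config()
  frozen <- make_pop(rep(7L, 2000), rep(7L, 2000), rep(0, 2000))
  set.seed(3)
  kids <- make_offspring(frozen, cfg)
  expect_true(all(kids$niche_x == 7L & kids$niche_y == 7L))
  expect_true(all(kids$resident))

  half <- make_pop(rep(7L, 20000), rep(7L, 20000), rep(0.5, 20000))
  kids <- make_offspring(half, cfg)
  frac <- mean(!kids$resident)
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / 20000))
  # resident flag is consistent with the coordinates
  expect_equal(!kids$resident, kids$niche_x != 7L | kids$niche_y != 7L)
})

test_that("evolvability inheritance perturbs at the fixed rate and clamps to [0, 1]", {
  set.seed(4)
  n <- 20000L
  cfg <- tiny_config(evolvability_mutation_rate = 0.005)
  pop <- make_pop(rep(7L, n), rep(7L, n), rep(0.025, n))
  kids <- make_offspring(pop, cfg)
  frac_mutated <- mean(kids$evolvability != 0.025)
  expect_lt(abs(frac_mutated - 0.005), 4 * sqrt(0.005 * 0.995 / n))
  changed <- kids$evolvability[kids$evolvability != 0.025]
  expect_true(all(abs(changed - 0.025) <= 0.0025))

  # clamping at both bounds: perturbation always fires
  cfg1 <- tiny_config(evolvability_mutation_rate = 1)
  lo <- make_offspring(make_pop(rep(7L, 2000), rep(7L, 2000), rep(0.001, 2000)), cfg1)
  expect_true(all(lo$evolvability >= 0))
  expect_true(any(lo$evolvability == 0))
  hi <- make_offspring(make_pop(rep(7L, 2000), rep(7L, 2000), rep(0.9999, 2000)), cfg1)
  expect_true(all(hi$evolvability <= 1))
  expect_true(any(hi$evolvability == 1))
})

test_that("with no evolvability mutation the set of evolvability values never grows", {
  cfg <- tiny_config(evolvability_mutation_rate = 0, niche_capacity = 3L)
  pop <- make_pop(c(7L, 7L, 8L), c(7L, 8L, 7L), c(0.1, 0.3, 0.5))
  values <- c(0.1, 0.3, 0.5)
  set.seed(5)
  for (i in 1:30) {
    pop <- step_generation(pop, cfg)
    expect_true(all(pop$evolvability %in% values))
  }
})

test_that("residents fill a niche before immigrants", {
  cfg <- tiny_config(niche_capacity = 3L)
  cand <- make_candidates(rep(5L, 6), rep(5L, 6),
                          resident = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  set.seed(6)
  kept <- enforce_capacity(cand, cfg)
  expect_equal(nrow(kept), 3L)
  expect_true(all(kept$resident))

  under <- make_candidates(rep(5L, 3), rep(5L, 3), resident = c(TRUE, TRUE, FALSE))
  kept <- enforce_capacity(under, tiny_config(niche_capacity = 5L))
  expect_equal(nrow(kept), 3L)

  # immigrants fill only the slots residents leave free
  mixed <- make_candidates(rep(5L, 7), rep(5L, 7),
                           resident = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  kept <- enforce_capacity(mixed, tiny_config(niche_capacity = 4L))
  expect_equal(sum(kept$resident), 2L)
  expect_equal(sum(!kept$resident), 2L)
})

test_that("capacity discard is a uniform random subset within a class", {
  # 5 residents, capacity 2: each should survive with frequency 2/5
  cfg <- tiny_config(niche_capacity = 2L)
  reps <- 4000L
  counts <- numeric(5)
  set.seed(7)
  for (i in seq_len(reps)) {
    cand <- make_candidates(rep(5L, 5), rep(5L, 5), resident = rep(TRUE, 5),
                            ev = (1:5) / 10)
    kept <- enforce_capacity(cand, cfg)
    expect_equal(nrow(kept), 2L)
    counts[match(kept$evolvability, (1:5) / 10)] <- counts[match(kept$evolvability, (1:5) / 10)] + 1
  }
  freq <- counts / reps
  se <- sqrt(0.4 * 0.6 / reps)
  expect_true(all(abs(freq - 2 / 5) < 4 * se))
})

test_that("population growth follows min(offspring^t, capacity) in the frozen single-niche limit", {
  cfg <- tiny_config(initial_evolvability = 0, niche_capacity = 10L,
                     evolvability_mutation_rate = 0)
  pop <- seed_population(cfg)
  set.seed(8)
  for (t in 1:6) {
    pop <- step_generation(pop, cfg)
    expect_equal(nrow(pop), min(2^t, 10L))
    expect_equal(occupied_niche_count(pop), 1L)
  }
  expect_equal(attr(pop, "generation"), 6L)
})

test_that("stepping an empty population is an error", {
  empty <- make_pop(integer(0), integer(0), numeric(0))
  expect_error(step_generation(empty, tiny_config()),
               class = "extinctsim_empty_population")
  expect_error(apply_extinction(empty, 5), class = "extinctsim_empty_population")
})

test_that("maximal evolvability saturates a small grid", {
  # evolvability pinned at 1: every offspring shifts, and descendants flood
  # the whole 11x11 torus
  cfg <- sim_config(grid_width = 11, grid_height = 11, niche_capacity = 3,
                    initial_evolvability = 1, evolvability_mutation_rate = 0,
                    generations = 60, seed = 9)
  res <- run_simulation(cfg)
  occ <- res$series$occupied_niches
  expect_true(any(occ == 121L))
  first_full <- which(occ == 121L)[1]
  expect_true(all(diff(occ[seq_len(first_full)]) >= 0))
})

test_that("every niche respects capacity and coordinates stay on the torus", {
  cfg <- tiny_config(initial_evolvability = 0.4, niche_capacity = 4L,
                     generations = 40L,
                     snapshot_generations = c(5L, 10L, 20L, 40L))
  res <- run_simulation(cfg)
  for (snap in c(res$snapshots, list(res$final_population))) {
    counts <- table(paste(snap$niche_x, snap$niche_y))
    expect_true(all(counts <= 4L))
    expect_true(all(snap$niche_x >= 0L & snap$niche_x < 15L))
    expect_true(all(snap$niche_y >= 0L & snap$niche_y < 15L))
    expect_true(all(snap$evolvability >= 0 & snap$evolvability <= 1))
  }
  # series-level bound: population <= occupied niches x capacity
  expect_true(all(res$series$population_size <=
                  res$series$occupied_niches * cfg$niche_capacity))
})

test_that("extinction spares exactly `severity` occupied niches", {
  set.seed(10)
  # 20 occupied niches, 2 organisms each
  xs <- rep(0:19 %% 5L, each = 2)
  ys <- rep(0:19 %/% 5L, each = 2)
  pop <- make_pop(xs, ys, rep(0.025, 40))
  expect_equal(occupied_niche_count(pop), 20L)
  out <- apply_extinction(pop, 5)
  expect_equal(occupied_niche_count(out), 5L)

  small <- make_pop(c(0L, 1L, 2L), c(0L, 0L, 0L), rep(0.1, 3))
  expect_identical(apply_extinction(small, 5), small)
})

test_that("extinction sparing is uniform over occupied niches", {
  # 20 equally sized niches, severity 5: expected surviving fraction 5/20
  xs <- rep(0:19 %% 5L, each = 2)
  ys <- rep(0:19 %/% 5L, each = 2)
  reps <- 2000L
  set.seed(11)
  fracs <- vapply(seq_len(reps), function(i) {
    pop <- make_pop(xs, ys, rep(0.025, 40))
    nrow(apply_extinction(pop, 5)) / 40
  }, numeric(1))
  expect_equal(unique(fracs), 0.25) # equal niche sizes: fraction is exact
  # and each individual niche survives ~ 5/20 of the time
  set.seed(12)
  survived <- numeric(20)
  for (i in seq_len(reps)) {
    pop <- make_pop(xs, ys, rep(0.025, 40))
    out <- apply_extinction(pop, 5)
    keys <- unique(out$niche_y * 15L + out$niche_x)
    idx <- match(keys, ys[seq(1, 40, 2)] * 15L + xs[seq(1, 40, 2)])
    survived[idx] <- survived[idx] + 1
  }
  freq <- survived / reps
  expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / reps)))
})

test_that("runs are bit-identical under the same seed and log scheduled extinctions", {
  cfg <- tiny_config(schedule = schedule_fixed(25), generations = 100L, seed = 13L)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$final_population$evolvability, b$final_population$evolvability)
  expect_equal(a$extinction_events, c(25L, 50L, 75L, 100L))
  expect_equal(nrow(a$series), 101L)
  expect_true(all(a$extinction_log$occupied_after <= cfg$severity))

  none <- run_simulation(tiny_config(generations = 30L))
  expect_length(none$extinction_events, 0L)
})

test_that("one manual step matches the make_offspring + enforce_capacity pipeline", {
  cfg <- tiny_config(initial_evolvability = 0.3, niche_capacity = 3L)
  pop <- make_pop(rep(c(5L, 9L), each = 3), rep(c(5L, 9L), each = 3),
                  rep(0.3, 6))
  set.seed(14)
  stepped <- step_generation(pop, cfg)
  set.seed(14)
  parents <- pop[rep(seq_len(nrow(pop)), each = cfg$offspring_per_parent), ]
  survivors <- enforce_capacity(make_offspring(parents, cfg), cfg)
  expect_equal(nrow(stepped), nrow(survivors))
  expect_equal(stepped$niche_x, survivors$niche_x)
  expect_equal(stepped$niche_y, survivors$niche_y)
  expect_equal(stepped$evolvability, survivors$evolvability)
})
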