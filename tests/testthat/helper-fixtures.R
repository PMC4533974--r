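# Small shared fixtures, all built in code.

# tiny grid config for fast unit tests
tiny_config <- function(...) {
  defaults <- list(grid_width = 15L, grid_height = 15L, niche_capacity = 5L,
                   initial_evolvability = 0.1, generations = 100L, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# hand-built population on a given grid
make_pop <- function(x, y, ev, width = 15L, height = 15L, generation = 0L) {
  new_population(x, y, ev, generation, width, height)
}

# offspring tibble for capacity tests
make_candidates <- function(x, y, resident, ev = 0.025) {
  tibble::tibble(niche_x = as.integer(x), niche_y = as.integer(y),
                 evolvability = rep_len(ev, length(x)),
                 resident = resident)
}

# exact two-sided Mann-Whitney p by full enumeration (independent oracle)
mw_exact_oracle <- function(a, b) {
  n1 <- length(a)
  n <- n1 + length(b)
  rks <- rank(c(a, b))
  u_obs <- sum(rks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  uall <- colSums(matrix(rks[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  umin <- min(u_obs, n1 * length(b) - u_obs)
  list(u = u_obs, p = mean(uall <= umin | uall >= n1 * length(b) - umin))
}

# from-scratch mid-rank Pearson (independent oracle for Spearman's r)
spearman_r_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
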