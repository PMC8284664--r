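# shared fixtures: tiny deterministic blocks and parameter vectors

# a fixed 6-trial block on the grid, spanning both tasks
tiny_block <- function() {
  U <- rbind(c(1, 1, 6), c(3, 3, 6), c(2, 4, 6),
             c(5, 1, 6), c(4, 4, 6), c(1, 5, 6))
  trial_block(U,
              task = c(1L, 1L, 1L, 2L, 2L, 2L),
              decision = c(1L, 2L, 1L, 2L, 1L, 1L),
              reward = c(1L, 0L, 1L, 1L, 0L, 1L))
}

# a single-task block with given length, fixed seed
small_block <- function(n = 20, map_id = "Sub1", seed = 42,
                        stimuli = "grid") {
  set.seed(seed)
  generate_trials(reward_map(map_id), 1L, n, stimuli = stimuli)
}

random_theta <- function(spec, seed = 1) {
  set.seed(seed)
  stats::rnorm(param_layout(spec)$P)
}

# central finite differences of a scalar function of theta
fd_gradient <- function(f, theta, h = 1e-6) {
  vapply(seq_along(theta), function(i) {
    e <- numeric(length(theta)); e[i] <- h
    (f(theta + e) - f(theta - e)) / (2 * h)
  }, numeric(1))
}
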