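# Shared fixtures, all generated in code (no stored data).

# The four regional environments, generated once per test run.
test_envs <- generate_environment_set(seed = 42)

# A wet/dry archetype pair sharing a seed, used by paired-run oracles.
make_env_pair <- function(seed) {
  list(
    wet = environment_scenario(
      soil_archetype("type1"),
      generate_weather(climate_archetype("south"), seed = seed),
      label = "wet"),
    dry = environment_scenario(
      soil_archetype("type2"),
      generate_weather(climate_archetype("north"), seed = seed),
      label = "dry"))
}

# Random full coefficient vector within the default bounds.
random_coefficients <- function(space = default_parameter_space()) {
  do.call(rice_coefficients, as.list(space_runif_test(space)))
}

space_runif_test <- function(space) {
  stats::setNames(stats::runif(space$k, space$lower, space$upper),
                  space$names)
}

# Hand-built two-coefficient Morris trajectory with a chosen move order,
# for tests that need deterministic geometry.
manual_trajectory <- function(base, delta, order_idx, signs) {
  k <- length(base)
  points <- matrix(NA_real_, k + 1, k,
                   dimnames = list(NULL, names(base)))
  points[1, ] <- base
  steps <- numeric(k)
  for (m in seq_len(k)) {
    j <- order_idx[m]
    x <- points[m, ]
    steps[m] <- signs[m] * delta[j]
    x[j] <- x[j] + steps[m]
    points[m + 1, ] <- x
  }
  structure(list(points = points,
                 moves = data.frame(coefficient = names(base)[order_idx],
                                    step = steps, stringsAsFactors = FALSE),
                 base = base),
            class = "morris_trajectory")
}

# Mass-balance residual of a simulation run (mm).
water_residual <- function(res) {
  w <- res$water
  w$rain + w$init_store - w$final_store - w$et - w$drainage - w$runoff
}
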