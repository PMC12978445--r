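test_that("thermal time is the clamped mean-excess over the base", {
  expect_equal(thermal_time(22, 30, 9), 17)
  expect_equal(thermal_time(8, 10, 9), 0)
  expect_equal(thermal_time(4, 6, 9), 0)   # below base clamps, never negative
  expect_error(thermal_time(10, 8, 9), "tmax < tmin")
})

test_that("photothermal requirement adds delay only above the critical photoperiod", {
  expect_equal(photothermal_requirement(500, 12, 100, 13), 600)
  expect_equal(photothermal_requirement(500, 12, 100, 11.5), 500)
  for (dl in seq(8, 16, by = 0.5))
    expect_equal(photothermal_requirement(700, 12, 0, dl), 700)
  # never below P1
  set.seed(1)
  for (i in 1:50) {
    p1 <- runif(1, 100, 900)
    expect_gte(photothermal_requirement(p1, runif(1, 8, 16),
                                        runif(1, 0, 200), runif(1, 8, 16)),
               p1)
  }
})

test_that("water balance endpoints behave and conserve mass", {
  soil <- soil_archetype("type1")
  ll <- soil$SLLL * soil$depth * 10
  dul <- soil$SDUL * soil$depth * 10
  sat <- soil$SSAT * soil$depth * 10

  at_ll <- water_balance_step(ll, rain = 0, et_demand = 5, soil)
  expect_equal(at_ll$actual_et, 0)
  expect_equal(at_ll$stress, 0)

  at_dul <- water_balance_step(dul, rain = 0, et_demand = 5, soil)
  expect_equal(at_dul$stress, 1)
  expect_equal(at_dul$actual_et, 5)

  flood <- water_balance_step(dul, rain = 500, et_demand = 5, soil)
  expect_lte(flood$store, sat + 1e-9)
  expect_gt(flood$runoff, 0)
  resid <- dul + 500 - flood$store - flood$actual_et - flood$drainage -
    flood$runoff
  expect_lt(abs(resid), 1e-9)

  expect_error(water_balance_step(ll - 5, 0, 1, soil), "bounds")
  expect_error(water_balance_step(sat + 5, 0, 1, soil), "bounds")
})

test_that("water balance step conserves mass and respects bounds on random inputs", {
  set.seed(11)
  soil <- soil_archetype("type2")
  ll <- soil$SLLL * soil$depth * 10
  sat <- soil$SSAT * soil$depth * 10
  for (i in 1:500) {
    s0 <- runif(1, ll, sat)
    rain <- rexp(1, 1 / 8) * rbinom(1, 1, 0.5)
    dem <- runif(1, 0, 9)
    wb <- water_balance_step(s0, rain, dem, soil)
    expect_lt(abs(s0 + rain - wb$store - wb$actual_et - wb$drainage -
                    wb$runoff), 1e-9)
    expect_gte(wb$store, ll - 1e-9)
    expect_lte(wb$store, sat + 1e-9)
    expect_gte(wb$stress, 0); expect_lte(wb$stress, 1)
    expect_lte(wb$actual_et, dem + 1e-9)
  }
})

test_that("sterility ramps cover the endpoints and the midpoint", {
  expect_equal(sterility_fraction(c(30, 31, 32), c(22, 23, 22), 35, 12), 0)
  expect_equal(sterility_fraction(rep(41, 5), rep(22, 5), 35, 12), 1)
  expect_equal(sterility_fraction(37.5, 22, 35, 12), 0.5)  # midpoint of heat ramp
  expect_equal(sterility_fraction(30, 10, 35, 12), 0.5)    # midpoint of cold ramp
  # combined independent risks
  expect_equal(sterility_fraction(37.5, 10, 35, 12), 1 - 0.5 * 0.5)
  expect_error(sterility_fraction(numeric(0), numeric(0), 35, 12), "empty")
})

test_that("paired runs respond to coefficients in the documented direction", {
  env <- test_envs$env1
  base <- rice_coefficients()

  r0 <- simulate_rice(base, env)
  r_p1 <- simulate_rice(merge_coefficients(base, c(P1 = base[["P1"]] + 100)), env)
  expect_gt(r_p1$anthesis, r0$anthesis)

  r_g3 <- simulate_rice(merge_coefficients(base, c(G3 = base[["G3"]] + 0.4)), env)
  expect_gt(r_g3$tillers, r0$tillers)

  r_p5 <- simulate_rice(merge_coefficients(base, c(P5 = base[["P5"]] + 150)), env)
  expect_gte(r_p5$maturity, r0$maturity)

  # photoperiod delay: longer days than P2O with a sensitive genotype
  r_p2r <- simulate_rice(merge_coefficients(base, c(P2O = 10, P2R = 150)), env)
  r_p2r0 <- simulate_rice(merge_coefficients(base, c(P2O = 10, P2R = 0)), env)
  expect_gte(r_p2r$anthesis, r_p2r0$anthesis)
})

test_that("flowering-window heat reduces grain number", {
  env <- test_envs$env2  # hot northern climate
  tolerant <- simulate_rice(rice_coefficients(THOT = 40), env)
  sensitive <- simulate_rice(rice_coefficients(THOT = 32), env)
  expect_gt(sensitive$sterility, tolerant$sterility)
  expect_lt(sensitive$grains, tolerant$grains)
})

test_that("a dry environment yields less than its wet counterpart", {
  pair <- make_env_pair(7)
  cv <- rice_coefficients()
  wet <- simulate_rice(cv, pair$wet)
  dry <- simulate_rice(cv, pair$dry)
  expect_lt(dry$yield, wet$yield)
  expect_lt(dry$biomass, wet$biomass)
  expect_true(is.finite(dry$HI) && is.finite(dry$WUE))
})

test_that("a season too cold to flower returns a flagged zero-yield result", {
  arctic <- climate_archetype("south")
  arctic$tmin <- 4; arctic$tmax <- 12; arctic$tavg <- 8
  env <- environment_scenario(soil_archetype("type1"),
                              generate_weather(arctic, seed = 3),
                              label = "cold")
  res <- simulate_rice(rice_coefficients(), env)
  expect_true(res$failed)
  expect_identical(res$yield, 0)
  expect_true(is.na(res$anthesis))
  expect_equal(hi_wue_fitness(res)$fitness, 0)
})

test_that("outputs are sane and water closes on random genotype x environment draws", {
  set.seed(99)
  space <- default_parameter_space()
  for (i in 1:200) {
    cv <- random_coefficients(space)
    env <- test_envs[[(i %% 4) + 1]]
    res <- simulate_rice(cv, env)
    expect_gte(res$HI, 0); expect_lt(res$HI, 1)
    expect_lte(res$yield, res$biomass + 1e-9)
    expect_true(all(unlist(res[c("biomass", "yield", "grains", "tillers",
                                 "cum_et", "WUE")]) >= 0))
    if (!res$failed) expect_gt(res$maturity, res$anthesis)
    if (res$cum_et > 0) expect_equal(res$WUE, res$yield / res$cum_et)
    expect_lt(abs(water_residual(res)), 1e-6)
  }
})

test_that("the simulator is deterministic", {
  cv <- rice_coefficients()
  a <- simulate_rice(cv, test_envs$env3)
  b <- simulate_rice(cv, test_envs$env3)
  expect_identical(a, b)
})
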