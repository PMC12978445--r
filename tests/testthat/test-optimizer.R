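test_that("WUE normalization is clamped min-max between the physiological bounds", {
  expect_equal(wue_normalize(2), 0)
  expect_equal(wue_normalize(15), 1)
  expect_equal(wue_normalize(6.17), (6.17 - 2) / 13)
  expect_equal(wue_normalize(0), 0)    # clamp below
  expect_equal(wue_normalize(40), 1)   # clamp above
})

test_that("the HI-WUE fitness composes the two efficiency axes", {
  mk <- function(HI, WUE, failed = FALSE)
    structure(list(HI = HI, WUE = WUE, failed = failed, cum_et = 100),
              class = "simulation_result")
  expect_equal(hi_wue_fitness(mk(0, 2))$fitness, 0)
  expect_equal(hi_wue_fitness(mk(1, 15))$fitness, 2)
  expect_equal(hi_wue_fitness(mk(0.54, 6.17))$fitness, 0.54 + (6.17 - 2) / 13,
               tolerance = 1e-12)  # 0.8608 on the printed values
  expect_equal(hi_wue_fitness(mk(0.5, 10, failed = TRUE))$fitness, 0)
})

test_that("roulette probabilities are fitness-proportional", {
  set.seed(31)
  # (3,1) -> (0.75, 0.25), checked empirically within 3 sigma on the first
  # parent column (the second column's marginal is perturbed by the
  # documented one-shot self-mating redraw)
  draws <- roulette_select(c(3, 1), 20000)[, 1]
  p_hat <- mean(draws == 1)
  se <- sqrt(0.75 * 0.25 / length(draws))
  expect_lt(abs(p_hat - 0.75), 3 * se)

  # uniform fitness -> uniform probabilities
  draws <- roulette_select(c(1, 1, 1, 1), 20000)[, 1]
  expect_true(all(abs(tabulate(draws, 4) / length(draws) - 0.25) <
                    3 * sqrt(0.25 * 0.75 / length(draws))))

  # all-zero fitness falls back to uniform rather than erroring
  draws <- as.vector(roulette_select(c(0, 0, 0), 3000))
  expect_setequal(unique(draws), 1:3)

  expect_error(roulette_select(numeric(0), 1), "empty")
  expect_error(roulette_select(c(-1, 2), 1), "negative")
})

test_that("arithmetic crossover mixes convexly", {
  a <- c(P1 = 100, G2 = 0.02)
  b <- c(P1 = 200, G2 = 0.03)
  expect_equal(arithmetic_crossover(a, b, lambda = 1)[[1]], a)
  expect_equal(arithmetic_crossover(a, b, lambda = 1)[[2]], b)
  mid <- arithmetic_crossover(a, b, lambda = 0.5)
  expect_equal(mid[[1]], c(P1 = 150, G2 = 0.025))
  expect_equal(mid[[1]], mid[[2]])

  set.seed(41)
  sp <- default_parameter_space(ga_coefficients())
  for (i in 1:2000) {
    pa <- space_runif_test(sp); pb <- space_runif_test(sp)
    kids <- arithmetic_crossover(pa, pb)
    for (kid in kids) {
      expect_true(all(kid >= sp$lower - 1e-12))
      expect_true(all(kid <= sp$upper + 1e-12))
    }
  }
})

test_that("adaptive mutation respects probability, weights and bounds", {
  sp <- default_parameter_space(ga_coefficients())
  x <- (sp$lower + sp$upper) / 2

  cfg0 <- ga_config(Thr_mut = 0, space = sp)
  set.seed(51)
  expect_identical(adaptive_mutate(x, cfg0), x)

  # all weight on P5: only P5 ever mutates
  w <- stats::setNames(c(0, 1, 0, 0, 0, 0, 0, 0), sp$names)
  w["P5"] <- 1; w[setdiff(sp$names, "P5")] <- 0
  cfg1 <- ga_config(Thr_mut = 1, space = sp, weights = w)
  set.seed(52)
  for (i in 1:2000) {
    y <- adaptive_mutate(x, cfg1)
    changed <- names(which(y != x))
    expect_true(length(changed) <= 1)
    if (length(changed)) expect_identical(changed, "P5")
    expect_true(all(y >= sp$lower & y <= sp$upper))
  }
})

test_that("GA runs are deterministic, feasible, bounded and elitist-monotone", {
  sp <- default_parameter_space(ga_coefficients())
  rng <- sp$upper - sp$lower
  xstar <- sp$lower + 0.3 * rng
  obj <- function(x) max(0, 2 - sum(((x - xstar) / rng)^2))
  cfg <- ga_config(Num_P = 15, Num_ind = 8, seed = 9)

  r1 <- run_ga(config = cfg, objective = obj)
  r2 <- run_ga(config = cfg, objective = obj)
  expect_identical(r1$archive, r2$archive)

  expect_equal(nrow(r1$archive), 15 * 8)
  expect_true(all(r1$archive$fitness >= 0 & r1$archive$fitness <= 2))
  for (nm in sp$names) {
    expect_true(all(r1$archive[[nm]] >= sp$lower[nm] - 1e-9))
    expect_true(all(r1$archive[[nm]] <= sp$upper[nm] + 1e-9))
  }
  expect_true(all(diff(r1$best_trace) >= -1e-12))
})

test_that("without variation operators an identical population stays fixed", {
  sp <- default_parameter_space(ga_coefficients())
  x0 <- (sp$lower + sp$upper) / 2
  # crossover of identical parents is the identity; mutation off
  kids <- arithmetic_crossover(x0, x0)
  expect_equal(kids[[1]], x0)
  expect_equal(kids[[2]], x0)
  cfg <- ga_config(Thr_mut = 0, space = sp)
  set.seed(3)
  expect_identical(adaptive_mutate(x0, cfg), x0)
})

test_that("the GA recovers a known optimum on a concave objective", {
  sp <- default_parameter_space(ga_coefficients())
  rng <- sp$upper - sp$lower
  set.seed(1005)
  xstar <- sp$lower + runif(8, 0.1, 0.9) * rng
  obj <- function(x) max(0, 2 - sum(((x - xstar) / rng)^2))
  run <- run_ga(config = ga_config(seed = 5), objective = obj)
  expect_true(all(abs(run$best - xstar) / rng <= 0.05))
})

test_that("convergence generation finds the first near-final generation", {
  mk <- function(trace) list(best_trace = trace)
  expect_equal(convergence_generation(mk(c(0.5, 0.9, 1.0)), 0.95), 3)
  expect_equal(convergence_generation(mk(rep(0.7, 6))), 1)
  # monotone trace: result non-increasing in frac
  set.seed(61)
  for (i in 1:20) {
    trace <- cumsum(abs(rnorm(15)))
    gens <- vapply(c(0.5, 0.8, 0.95, 1), function(f)
      convergence_generation(mk(trace), f), numeric(1))
    expect_true(all(diff(gens) >= 0))
  }
})

test_that("GA runs export an archive CSV and JSON summary", {
  sp <- default_parameter_space(ga_coefficients())
  obj <- function(x) max(0, 2 - sum(((x - (sp$lower + sp$upper) / 2) /
                                       (sp$upper - sp$lower))^2))
  run <- run_ga(config = ga_config(Num_P = 4, Num_ind = 4, seed = 2),
                objective = obj)
  a_path <- withr::local_tempfile(fileext = ".csv")
  s_path <- withr::local_tempfile(fileext = ".json")
  write_ga_run(run, a_path, s_path)
  arch <- read.csv(a_path)
  expect_equal(nrow(arch), 16)
  expect_true(all(c("generation", "fitness", sp$names) %in% names(arch)))
  summ <- jsonlite::fromJSON(s_path)
  expect_equal(summ$best_fitness, run$best_fitness)
  expect_equal(summ$settings$Num_P, 4)
})
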