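#' Genetic-algorithm configuration
#'
#' Defaults follow the production settings of the ideotype search: 40
#' generations, population 15, mutation probability 0.7, and water-use
#' efficiency normalized between the physiological bounds 2 and 15
#' kg/ha/mm reported for aerobic rice under drought adaptation.
#'
#' @param Num_P generations (>= 1).
#' @param Num_ind population size (>= 2).
#' @param Thr_mut per-individual mutation probability in `[0, 1]`.
#' @param WUEmin,WUEmax WUE normalization bounds (kg/ha/mm), `WUEmin < WUEmax`.
#' @param elitism keep the best-so-far individual in the population.
#' @param seed integer RNG seed for the run.
#' @param space search bounds: a [parameter_space()] over the coefficients
#'   being optimized (default: the eight of [ga_coefficients()]).
#' @param weights optional per-coefficient sensitivity weights steering the
#'   adaptive mutation (e.g. max RSI from [replicate_screening()]); uniform
#'   when `NULL`.
#' @param mut_sd_frac mutation noise sd as a fraction of the coefficient range.
#' @param selection_window apply classical fitness windowing before the
#'   roulette draw: selection weights are `fitness - min(fitness)` (uniform
#'   fallback when all are equal). Without it selection pressure vanishes once
#'   the population fitness plateaus; disable to get raw
#'   fitness-proportional selection.
#' @param selection_power exponent applied to the windowed selection weights
#'   (Goldberg-style power scaling). 1 is plain proportional selection on the
#'   windowed fitness; the default 2 sharpens selection pressure enough for
#'   the population to refine the optimum within the 40 x 15 evaluation
#'   budget.
#' @param mut_anneal linearly shrink the mutation scale over the generations,
#'   from `mut_sd_frac` down to `0.2 * mut_sd_frac` in the last generation.
#'   Off by default: with single-gene mutation, late big kicks are what
#'   rescue a coordinate stuck far from its optimum.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(Num_P = 40, Num_ind = 15, Thr_mut = 0.7,
                      WUEmin = 2, WUEmax = 15, elitism = TRUE, seed = 1,
                      space = default_parameter_space(ga_coefficients()),
                      weights = NULL, mut_sd_frac = 0.1,
                      selection_window = TRUE, selection_power = 2,
                      mut_anneal = FALSE) {
  stopifnot(Num_P >= 1, Num_ind >= 2, Thr_mut >= 0, Thr_mut <= 1,
            WUEmin < WUEmax, inherits(space, "parameter_space"))
  if (!is.null(weights)) weights <- weights[space$names]
  structure(as.list(environment()), class = "ga_config")
}

#' Normalize water-use efficiency to [0, 1]
#'
#' Linear min-max scaling between the configured physiological bounds,
#' clamped outside them.
#'
#' @param WUE water-use efficiency (kg/ha/mm).
#' @param config a [ga_config()].
#' @return value(s) in `[0, 1]`.
#' @examples
#' wue_normalize(6.17)  # (6.17 - 2) / 13
#' @export
wue_normalize <- function(WUE, config = ga_config()) {
  pmin(1, pmax(0, (WUE - config$WUEmin) / (config$WUEmax - config$WUEmin)))
}

#' Combined harvest-index / water-use-efficiency fitness
#'
#' The scalar fitness of a simulated genotype: harvest index plus normalized
#' WUE, giving each resource-efficiency axis equal weight and a theoretical
#' range of `[0, 2]`. Flagged simulator failures (crops that never flowered)
#' receive fitness 0.
#'
#' @param result a `simulation_result`.
#' @param config a [ga_config()].
#' @return list of class `fitness_record`: `HI`, `WUE`, `WUEnorm`, `fitness`.
#' @export
hi_wue_fitness <- function(result, config = ga_config()) {
  if (isTRUE(result$failed)) {
    rec <- list(HI = result$HI, WUE = result$WUE, WUEnorm = 0, fitness = 0)
  } else {
    wn <- wue_normalize(result$WUE, config)
    rec <- list(HI = result$HI, WUE = result$WUE, WUEnorm = wn,
                fitness = result$HI + wn)
  }
  structure(rec, class = "fitness_record")
}

#' Roulette-wheel parent selection
#'
#' Samples parent pairs with replacement, probability proportional to fitness;
#' an all-zero fitness vector falls back to uniform sampling. Self-mating is
#' allowed but re-drawn once per pair.
#'
#' @param fitnesses non-negative fitness values, one per individual.
#' @param n_pairs number of parent pairs to draw.
#' @return integer matrix `n_pairs x 2` of parent indices.
#' @export
roulette_select <- function(fitnesses, n_pairs) {
  n <- length(fitnesses)
  if (!n) stop("roulette_select: empty population")
  if (any(fitnesses < 0)) stop("roulette_select: negative fitness")
  prob <- if (sum(fitnesses) > 0) fitnesses / sum(fitnesses) else rep(1 / n, n)
  pairs <- matrix(sample.int(n, 2 * n_pairs, replace = TRUE, prob = prob),
                  ncol = 2)
  same <- pairs[, 1] == pairs[, 2]
  if (any(same))
    pairs[same, 2] <- sample.int(n, sum(same), replace = TRUE, prob = prob)
  pairs
}

#' Arithmetic crossover
#'
#' One mixing weight `lambda ~ Uniform(0, 1)` is drawn per mating and applied
#' coordinate-wise: offspring are `lambda a + (1 - lambda) b` and its mirror.
#' Convexity keeps offspring within any box bounds containing the parents.
#'
#' @param a,b parent coefficient vectors (equal length, same names).
#' @param lambda optional fixed mixing weight in `[0, 1]`; drawn uniformly
#'   when `NULL`.
#' @return list of two offspring vectors.
#' @export
arithmetic_crossover <- function(a, b, lambda = NULL) {
  if (is.null(lambda)) lambda <- stats::runif(1)
  list(lambda * a + (1 - lambda) * b,
       (1 - lambda) * a + lambda * b)
}

#' Adaptive single-gene mutation
#'
#' With probability `Thr_mut`, one coefficient is picked (probability
#' proportional to its sensitivity weight; uniform if none are configured)
#' and Gaussian noise with sd `mut_sd_frac` of that coefficient's range is
#' added, then clipped to the bounds.
#'
#' @param x individual (named vector over `config$space$names`).
#' @param config a [ga_config()].
#' @return mutated individual, always within bounds.
#' @export
adaptive_mutate <- function(x, config) {
  if (stats::runif(1) >= config$Thr_mut) return(x)
  sp <- config$space
  w <- config$weights
  prob <- if (is.null(w) || all(w <= 0)) NULL else w / sum(w)
  j <- sample.int(sp$k, 1, prob = prob)
  range_j <- sp$upper[j] - sp$lower[j]
  x[j] <- x[j] + stats::rnorm(1, 0, config$mut_sd_frac * range_j)
  x[j] <- min(sp$upper[j], max(sp$lower[j], x[j]))
  x
}

#' Run the genetic algorithm
#'
#' Generational GA with elitism over the configured coefficient space:
#' initialize uniformly within bounds, then per generation evaluate all
#' individuals, select parents by roulette wheel, recombine with arithmetic
#' crossover, apply adaptive mutation, and (with elitism) re-insert the
#' best-so-far individual over the worst offspring. Every evaluation is
#' archived. The run is deterministic for a given `config$seed`.
#'
#' By default individuals are evaluated by simulating them in `env` (the
#' non-searched coefficients fixed at `base`) and scoring with
#' [hi_wue_fitness()]; pass `objective` to optimize an arbitrary function
#' instead (used for oracle tests).
#'
#' @param env an [environment_scenario()] (ignored when `objective` given).
#' @param config a [ga_config()].
#' @param base full coefficient set completing the searched subset.
#' @param sim_config simulator constants.
#' @param objective optional `function(x) -> fitness_record | numeric`.
#' @return list of class `ga_run`: `archive` (data.frame: generation, the
#'   coefficients, HI, WUE, fitness), `best` (named vector), `best_fitness`,
#'   `best_trace` and `mean_trace` (per-generation best/mean fitness),
#'   `n_evaluations`, `config`.
#' @export
run_ga <- function(env = NULL, config = ga_config(),
                   base = rice_coefficients(),
                   sim_config = crop_model_config(), objective = NULL) {
  sp <- config$space
  if (is.null(objective)) {
    if (is.null(env)) stop("run_ga: need an environment or an objective")
    objective <- function(x) {
      res <- try(simulate_rice(merge_coefficients(base, x), env, sim_config),
                 silent = TRUE)
      if (inherits(res, "try-error"))
        return(list(HI = 0, WUE = 0, fitness = 0))
      hi_wue_fitness(res, config)
    }
  }
  score <- function(x) {
    f <- objective(x)
    if (is.numeric(f)) f <- list(HI = NA_real_, WUE = NA_real_, fitness = f)
    f
  }

  set.seed(config$seed)
  pop <- t(replicate(config$Num_ind, space_runif(sp)))
  colnames(pop) <- sp$names

  archive <- vector("list", config$Num_P)
  best_trace <- mean_trace <- numeric(config$Num_P)
  best <- NULL
  best_fitness <- -Inf

  for (g in seq_len(config$Num_P)) {
    recs <- apply(pop, 1, score)
    fit <- vapply(recs, `[[`, numeric(1), "fitness")
    gen_best <- which.max(fit)
    if (fit[gen_best] > best_fitness) {
      best_fitness <- fit[gen_best]
      best <- pop[gen_best, ]
    }
    archive[[g]] <- data.frame(
      generation = g, pop,
      HI = vapply(recs, `[[`, numeric(1), "HI"),
      WUE = vapply(recs, `[[`, numeric(1), "WUE"),
      fitness = fit, row.names = NULL)
    best_trace[g] <- if (config$elitism) best_fitness else fit[gen_best]
    mean_trace[g] <- mean(fit)

    if (g == config$Num_P) break
    sel_fit <- if (config$selection_window) fit - min(fit) else fit
    sel_fit <- sel_fit^config$selection_power
    pairs <- roulette_select(sel_fit, ceiling(config$Num_ind / 2))
    offspring <- matrix(NA_real_, 0, sp$k)
    for (p in seq_len(nrow(pairs))) {
      kids <- arithmetic_crossover(pop[pairs[p, 1], ], pop[pairs[p, 2], ])
      offspring <- rbind(offspring, kids[[1]], kids[[2]])
    }
    offspring <- offspring[seq_len(config$Num_ind), , drop = FALSE]
    gen_cfg <- config
    if (config$mut_anneal)
      gen_cfg$mut_sd_frac <- config$mut_sd_frac *
        (1 - 0.8 * (g - 1) / max(1, config$Num_P - 1))
    offspring <- t(apply(offspring, 1, adaptive_mutate, config = gen_cfg))
    colnames(offspring) <- sp$names
    if (config$elitism) offspring[config$Num_ind, ] <- best
    pop <- offspring
  }

  structure(list(archive = do.call(rbind, archive), best = best,
                 best_fitness = best_fitness, best_trace = best_trace,
                 mean_trace = mean_trace,
                 n_evaluations = config$Num_P * config$Num_ind,
                 config = config),
            class = "ga_run")
}

#' @export
print.ga_run <- function(x, ...) {
  cat(sprintf(
    "GA run: %d generations x %d individuals (%d evaluations), best fitness %.4f\n",
    x$config$Num_P, x$config$Num_ind, x$n_evaluations, x$best_fitness))
  print(round(x$best, 4))
  invisible(x)
}

#' Generation at which the run converged
#'
#' Smallest generation whose best fitness reaches `frac` of the final best
#' fitness.
#'
#' @param run a [run_ga()] result (or any list with `best_trace`).
#' @param frac convergence fraction (default 0.95).
#' @return 1-based generation index.
#' @export
convergence_generation <- function(run, frac = 0.95) {
  trace <- run$best_trace
  stopifnot(length(trace) >= 1)
  target <- frac * trace[length(trace)]
  which(trace >= target)[1]
}

#' Export a GA run
#'
#' Writes the full evaluation archive as CSV and a JSON summary (best
#' individual, best fitness, convergence generation, seed and settings).
#'
#' @param run a [run_ga()] result.
#' @param archive_path,summary_path output paths (either may be `NULL`).
#' @export
write_ga_run <- function(run, archive_path = NULL, summary_path = NULL) {
  if (!is.null(archive_path))
    utils::write.csv(run$archive, archive_path, row.names = FALSE)
  if (!is.null(summary_path))
    jsonlite::write_json(
      list(best = as.list(run$best), best_fitness = run$best_fitness,
           convergence_generation = convergence_generation(run),
           n_evaluations = run$n_evaluations,
           seed = run$config$seed,
           settings = list(Num_P = run$config$Num_P,
                           Num_ind = run$config$Num_ind,
                           Thr_mut = run$config$Thr_mut,
                           WUEmin = run$config$WUEmin,
                           WUEmax = run$config$WUEmax)),
      summary_path, auto_unbox = TRUE, digits = NA)
  invisible(run)
}
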