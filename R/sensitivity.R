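#' Build one Morris trajectory
#'
#' Draws a random base point within bounds, then perturbs one coefficient at a
#' time (in a random order, with a random sign) by that coefficient's step
#' `delta`, yielding `k + 1` points where consecutive points differ in exactly
#' one coordinate. A step that would leave the bounds is reflected (its sign
#' flipped) rather than clipped, so the step magnitude is preserved exactly.
#'
#' Uses the caller's RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param space a [parameter_space()].
#' @return list of class `morris_trajectory`: `points` (a `(k+1) x k` matrix),
#'   `moves` (data.frame with `coefficient`, `step`), `base` (the base point).
#' @export
build_trajectory <- function(space) {
  k <- space$k
  order_idx <- sample.int(k)
  signs <- sample(c(-1, 1), k, replace = TRUE)
  # draw each base coordinate within the interval where its intended step is
  # feasible (as in grid-based Morris designs), so |delta| is always realized
  sign_for <- integer(k)
  sign_for[order_idx] <- signs
  base <- stats::setNames(numeric(k), space$names)
  for (j in seq_len(k)) {
    if (sign_for[j] > 0)
      base[j] <- stats::runif(1, space$lower[j], space$upper[j] - space$delta[j])
    else
      base[j] <- stats::runif(1, space$lower[j] + space$delta[j], space$upper[j])
  }
  points <- matrix(NA_real_, nrow = k + 1, ncol = k,
                   dimnames = list(NULL, space$names))
  points[1, ] <- base
  steps <- numeric(k)
  for (m in seq_len(k)) {
    j <- order_idx[m]
    step <- signs[m] * space$delta[j]
    x <- points[m, ]
    if (x[j] + step > space$upper[j] || x[j] + step < space$lower[j])
      step <- -step  # reflect to stay feasible (delta <= range guarantees one side)
    x[j] <- x[j] + step
    points[m + 1, ] <- x
    steps[m] <- step
  }
  structure(list(points = points,
                 moves = data.frame(coefficient = space$names[order_idx],
                                    step = steps,
                                    stringsAsFactors = FALSE),
                 base = base),
            class = "morris_trajectory")
}

#' Elementary effects of one trajectory
#'
#' For the i-th move of the trajectory (which perturbed one coefficient), the
#' elementary effect on each output channel is the raw output change
#' `Y(x(i)) - Y(x(i-1))`; the step-normalized effect (change per unit step) is
#' stored alongside.
#'
#' @param traj a [build_trajectory()] result.
#' @param outputs a `(k+1) x n_channels` numeric matrix of model outputs, one
#'   row per trajectory point (column names are the channel names), or a list
#'   of `simulation_result` objects which is converted via [result_channels()].
#' @return data.frame of class `elementary_effects` with columns
#'   `coefficient`, `channel`, `dY` (raw change, sign preserved), `dY_norm`
#'   (`dY / |step|`).
#' @export
elementary_effects <- function(traj, outputs) {
  if (is.list(outputs) && !is.matrix(outputs))
    outputs <- do.call(rbind, lapply(outputs, result_channels))
  outputs <- as.matrix(outputs)
  k <- nrow(traj$moves)
  if (nrow(outputs) != k + 1)
    stop("elementary_effects: need one output row per trajectory point")
  if (is.null(colnames(outputs)))
    colnames(outputs) <- paste0("y", seq_len(ncol(outputs)))
  dY <- outputs[-1, , drop = FALSE] - outputs[-(k + 1), , drop = FALSE]
  out <- data.frame(
    coefficient = rep(traj$moves$coefficient, times = ncol(outputs)),
    channel = rep(colnames(outputs), each = k),
    dY = as.vector(dY),
    dY_norm = as.vector(dY) / rep(abs(traj$moves$step), times = ncol(outputs)),
    stringsAsFactors = FALSE)
  class(out) <- c("elementary_effects", "data.frame")
  out
}

#' Relative Sensitivity Index for one output channel
#'
#' For each coefficient, the mean absolute elementary effect divided by the
#' maximum absolute effect observed across *all* coefficients for that channel
#' (pooled maximum). A channel on which no coefficient has any effect gets RSI
#' 0 for every coefficient. Values lie in `[0, 1]`: 0 means no influence, 1
#' means every effect of that coefficient equals the largest observed change.
#'
#' @param effects an [elementary_effects()] data.frame (possibly pooled over
#'   several trajectories).
#' @param channel output channel name.
#' @param coefficients optional coefficient ordering for the result.
#' @return named numeric vector of RSI values.
#' @export
rsi <- function(effects, channel, coefficients = NULL) {
  e <- effects[effects$channel == channel, , drop = FALSE]
  if (!nrow(e)) stop("rsi: no effects for channel ", channel)
  if (is.null(coefficients)) coefficients <- unique(e$coefficient)
  M <- max(abs(e$dY))
  v <- vapply(coefficients, function(p) {
    d <- abs(e$dY[e$coefficient == p])
    if (!length(d)) stop("rsi: no effects for coefficient ", p)
    if (M == 0) 0 else mean(d) / M
  }, numeric(1))
  stats::setNames(v, coefficients)
}

# internal: one full screening replicate -> coefficient x channel RSI matrix
morris_replicate <- function(space, model, r) {
  eff <- vector("list", r)
  for (t in seq_len(r)) {
    traj <- build_trajectory(space)
    rows <- apply(traj$points, 1, model, simplify = FALSE)
    outputs <- do.call(rbind, rows)
    eff[[t]] <- elementary_effects(traj, outputs)
  }
  eff <- do.call(rbind, eff)
  channels <- unique(eff$channel)
  sapply(channels, function(ch) rsi(eff, ch, space$names))
}

#' Replicated Morris screening with confidence intervals
#'
#' Runs `reps` independent screening replicates (each with `r` randomized
#' trajectories, i.e. `r * (k + 1)` model evaluations) and summarises the RSI
#' of every coefficient x channel cell by its replicate mean, standard
#' deviation and Student-t 95% confidence half-width (`reps - 1` degrees of
#' freedom), with CI bounds clipped to `[0, 1]`.
#'
#' @param space a [parameter_space()].
#' @param model function mapping a named coefficient vector to a named numeric
#'   vector of output channels (wrap the simulator with
#'   [sensitivity_model()]).
#' @param r trajectories per replicate (default 10).
#' @param reps replicates (default 20; must be >= 2 for CIs).
#' @param seed integer seed; replicate i uses `seed + i - 1`.
#' @return list of class `rsi_matrix`: matrices `mean`, `sd`, `ci95`
#'   (half-width) and the `[0,1]`-clipped `lower`/`upper` CI bounds
#'   (coefficient x channel), plus `reps`, `r`, `seed`.
#' @export
replicate_screening <- function(space, model, r = 10, reps = 20, seed = 1) {
  stopifnot(reps >= 2, r >= 1)
  mats <- vector("list", reps)
  for (i in seq_len(reps)) {
    set.seed(seed + i - 1)
    mats[[i]] <- morris_replicate(space, model, r)
  }
  arr <- simplify2array(mats)  # k x channels x reps
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), stats::sd)
  ci <- stats::qt(0.975, df = reps - 1) * s / sqrt(reps)
  structure(list(mean = m, sd = s, ci95 = ci,
                 lower = pmax(0, m - ci), upper = pmin(1, m + ci),
                 reps = reps, r = r, seed = seed),
            class = "rsi_matrix")
}

#' @export
print.rsi_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("RSI matrix: %d replicates x %d trajectories (seed %d)\n",
              x$reps, x$r, x$seed))
  print(round(x$mean, digits))
  invisible(x)
}

#' Select coefficients for optimization
#'
#' Ranks coefficients by their maximum mean RSI across output channels,
#' keeps the top `n_keep`, and always drops coefficients whose maximum RSI is
#' below `min_rsi` (the rule that excludes inert cold-stress thresholds in
#' warm environments). Ties are broken by the declared coefficient order.
#'
#' @param matrix an [replicate_screening()] result.
#' @param n_keep how many coefficients to keep (default 8).
#' @param min_rsi exclusion threshold on the max RSI (default 0.05).
#' @return character vector of selected coefficients, ranked.
#' @export
select_targets <- function(matrix, n_keep = 8, min_rsi = 0.05) {
  score <- apply(matrix$mean, 1, max)
  ord <- order(-score, seq_along(score))  # stable: declared order breaks ties
  sel <- rownames(matrix$mean)[ord]
  sel <- sel[score[ord] >= min_rsi]
  utils::head(sel, n_keep)
}

#' Export an RSI matrix as tidy CSV
#'
#' One row per coefficient x channel with replicate mean, sd and 95% CI
#' half-width (layout mirrors a supplementary sensitivity table).
#'
#' @param matrix an [replicate_screening()] result.
#' @param path output CSV path.
#' @export
write_rsi_csv <- function(matrix, path) {
  df <- expand.grid(coefficient = rownames(matrix$mean),
                    output = colnames(matrix$mean),
                    stringsAsFactors = FALSE)
  df$mean <- as.vector(matrix$mean)
  df$sd <- as.vector(matrix$sd)
  df$ci95 <- as.vector(matrix$ci95)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Wrap the simulator as a sensitivity model
#'
#' Fixes an environment (and the non-searched coefficients at `base`) and
#' returns the function of a coefficient vector that [replicate_screening()]
#' expects.
#'
#' @param env an [environment_scenario()].
#' @param base full coefficient set supplying values not present in the input
#'   vector.
#' @param config simulator constants.
#' @return function(named numeric) -> named numeric of six output channels.
#' @export
sensitivity_model <- function(env, base = rice_coefficients(),
                              config = crop_model_config()) {
  force(env); force(base); force(config)
  function(x) result_channels(simulate_rice(merge_coefficients(base, x),
                                            env, config))
}
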