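#' Climate archetypes of the study region
#'
#' Two printed climate profiles: the humid southern zone (higher rainfall and
#' humidity, moderate temperatures) and the drought-prone northern zone (44%
#' lower seasonal rainfall, drier and hotter air). Wet-season spans follow
#' regional climatology (south roughly June--October, north July--September).
#'
#' @param label `"south"` (type 1) or `"north"` (type 2).
#' @return list of class `climate_archetype`: `label`, mean `tmin`, `tmax`,
#'   `tavg` (deg C), `rh` (%), `srad` mean and sd (MJ/m2/day), seasonal
#'   precipitation total `precip` (mm), `wet_span` (days).
#' @export
climate_archetype <- function(label = c("south", "north")) {
  label <- match.arg(label)
  a <- switch(label,
    south = list(tmin = 22.19, tmax = 30.60, tavg = 26.39, rh = 80.33,
                 srad_mean = 19.16, srad_sd = 3.44, precip = 917,
                 wet_span = 120),
    # northern srad sd is not printed; mirror the southern value
    north = list(tmin = 22.51, tmax = 33.04, tavg = 27.78, rh = 67.98,
                 srad_mean = 19.62, srad_sd = 3.5, precip = 513.24,
                 wet_span = 75))
  structure(c(list(label = label), a), class = "climate_archetype")
}

#' Soil archetypes of the study region
#'
#' Type 1 (eastern): finer texture, intermediate water retention. Type 2:
#' sandy, fast draining, low retention.
#'
#' @param label `"type1"` or `"type2"`.
#' @return a [soil_profile()] with a `label` attribute.
#' @export
soil_archetype <- function(label = c("type1", "type2")) {
  label <- match.arg(label)
  s <- switch(label,
    type1 = soil_profile(depth = 40, SLLL = 0.16, SDUL = 0.29, SSAT = 0.44,
                         SSKS = 0.75, clay = 26.33, silt = 30.53,
                         SBDM = 1.50, SLHW = 5.91),
    type2 = soil_profile(depth = 40, SLLL = 0.11, SDUL = 0.23, SSAT = 0.40,
                         SSKS = 1.09, clay = 12, silt = 20, sand = 56.59,
                         SBDM = 1.55, SLHW = 5.87))
  attr(s, "label") <- label
  s
}

#' Vapor pressure deficit from mean temperature and humidity
#'
#' Tetens saturation curve: `es = 0.6108 exp(17.27 T / (T + 237.3))` kPa,
#' `vpd = es (1 - rh/100)`.
#'
#' @param tavg mean air temperature (deg C).
#' @param rh relative humidity (%), in `[0, 100]`.
#' @return list of class `climate_summary`: `tavg`, `rh`, `es`, `vpd` (kPa).
#' @examples
#' vpd(27.78, 67.98)$vpd  # about 1.19 kPa
#' @export
vpd <- function(tavg, rh) {
  if (any(rh < 0 | rh > 100)) stop("vpd: rh outside [0, 100]")
  es <- 0.6108 * exp(17.27 * tavg / (tavg + 237.3))
  structure(list(tavg = tavg, rh = rh, es = es, vpd = es * (1 - rh / 100)),
            class = "climate_summary")
}

#' Generate a synthetic daily weather series
#'
#' Temperatures are Gaussian around the archetype means (sd 1.5 deg C, with
#' `tmax >= tmin` enforced by resampling); solar radiation is Gaussian with
#' the archetype mean/sd clipped at zero; humidity is Gaussian clipped to
#' `[0, 100]`. Rain occurs only within the wet-season span, driven by a
#' two-state wet/dry occurrence chain; intensities are exponential draws
#' modulated by a sinusoidal seasonal envelope (monsoon onset and retreat)
#' and rescaled so the seasonal total matches the archetype total exactly.
#'
#' @param archetype a [climate_archetype()].
#' @param n_days series length (>= 120, default 160).
#' @param seed integer seed; the generator is a pure function of
#'   (archetype, n_days, seed).
#' @param latitude latitude for day length (default 12.5).
#' @return a [weather_series()].
#' @export
generate_weather <- function(archetype, n_days = 160, seed = 1,
                             latitude = 12.5) {
  stopifnot(inherits(archetype, "climate_archetype"), n_days >= 120)
  set.seed(seed)
  a <- archetype

  tmin <- stats::rnorm(n_days, a$tmin, 1.5)
  tmax <- stats::rnorm(n_days, a$tmax, 1.5)
  bad <- which(tmax < tmin)
  while (length(bad)) {
    tmin[bad] <- stats::rnorm(length(bad), a$tmin, 1.5)
    tmax[bad] <- stats::rnorm(length(bad), a$tmax, 1.5)
    bad <- which(tmax < tmin)
  }

  srad <- pmax(0, stats::rnorm(n_days, a$srad_mean, a$srad_sd))
  rh <- pmin(100, pmax(0, stats::rnorm(n_days, a$rh, 5)))
  wind <- pmax(0.1, stats::rnorm(n_days, 1.8, 0.6))

  span <- min(a$wet_span, n_days)
  p_wd <- 0.35; p_ww <- 0.65  # wet-after-dry / wet-after-wet
  wet <- logical(span)
  wet[1] <- stats::runif(1) < 0.5
  for (d in 2:span)
    wet[d] <- stats::runif(1) < (if (wet[d - 1]) p_ww else p_wd)
  if (!any(wet)) wet[sample.int(span, 1)] <- TRUE
  rain <- numeric(n_days)
  mean_int <- a$precip / max(1, sum(wet))
  envelope <- sin(pi * (seq_len(span) - 0.5) / span)  # monsoon onset/retreat
  rain[seq_len(span)][wet] <- stats::rexp(sum(wet), rate = 1 / mean_int) *
    envelope[wet]
  rain <- rain * a$precip / sum(rain)  # match the seasonal total exactly

  weather_series(data.frame(tmin = tmin, tmax = tmax, srad = srad, rh = rh,
                            wind = wind, rain = rain),
                 latitude = latitude)
}

#' Generate a random cultivar panel
#'
#' Coefficients drawn uniformly within bounds, group labels assigned
#' cyclically; an optional known coefficient vector can be planted into the
#' panel for recovery tests.
#'
#' @param n number of cultivars (>= 1).
#' @param space bounds over the eight panel coefficients.
#' @param groups labels recycled over entries.
#' @param seed integer seed.
#' @param plant optional named coefficient vector inserted as entry
#'   `"planted"`.
#' @return a [cultivar_panel()].
#' @export
generate_panel <- function(n = 21,
                           space = default_parameter_space(ga_coefficients()),
                           groups = c("indica", "japonica", "hybrid"),
                           seed = 1, plant = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  m <- t(replicate(n, space_runif(space)))
  df <- data.frame(name = sprintf("CV%02d", seq_len(n)),
                   group = rep_len(groups, n), m,
                   stringsAsFactors = FALSE)
  if (!is.null(plant)) {
    row <- data.frame(name = "planted", group = "hybrid",
                      t(as.numeric(plant[space$names])))
    names(row)[-(1:2)] <- space$names
    df <- rbind(df, row)
  }
  cultivar_panel(df)
}

#' The four representative environments of the region
#'
#' Crosses the two climate archetypes with soil water-retention levels to
#' mirror the four environments that cover 89% of the cultivation area:
#' Env 1 wet climate x high retention (SDUL 0.30), Env 2 dry x medium (0.28),
#' Env 3 wet x medium (0.29), Env 4 dry x low (0.23); area weights 0.30,
#' 0.18, 0.21, 0.20.
#'
#' @param seed integer seed; environment i uses `seed + i - 1` for its
#'   weather draw.
#' @param n_days weather series length.
#' @return named list of four [environment_scenario()] objects.
#' @export
generate_environment_set <- function(seed = 1, n_days = 160) {
  south <- climate_archetype("south")
  north <- climate_archetype("north")
  soils <- list(
    env1 = soil_profile(depth = 40, SLLL = 0.17, SDUL = 0.30, SSAT = 0.44,
                        SSKS = 0.75, clay = 26.33, silt = 30.53, SBDM = 1.50),
    env2 = soil_profile(depth = 40, SLLL = 0.15, SDUL = 0.28, SSAT = 0.42,
                        SSKS = 0.90, clay = 20, silt = 28, SBDM = 1.52),
    env3 = soil_profile(depth = 40, SLLL = 0.16, SDUL = 0.29, SSAT = 0.44,
                        SSKS = 0.75, clay = 26.33, silt = 30.53, SBDM = 1.50),
    env4 = soil_profile(depth = 40, SLLL = 0.11, SDUL = 0.23, SSAT = 0.40,
                        SSKS = 1.09, clay = 12, silt = 20, sand = 56.59,
                        SBDM = 1.55))
  climates <- list(south, north, south, north)
  weights <- c(0.30, 0.18, 0.21, 0.20)
  out <- lapply(1:4, function(i) {
    environment_scenario(
      soils[[i]],
      generate_weather(climates[[i]], n_days = n_days, seed = seed + i - 1),
      label = paste0("env", i), weight = weights[i])
  })
  names(out) <- paste0("env", 1:4)
  out
}
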