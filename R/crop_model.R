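#' Surrogate growth-model constants
#'
#' All tunable constants of the surrogate simulator live here. They are design
#' choices of this package, not calibrated values: the full CERES-Rice source
#' is not reproduced, only the qualitative physiology its genetic coefficients
#' are documented to control.
#'
#' @param tbase base temperature below which no thermal time accrues (deg C).
#' @param rue radiation-use efficiency (g dry matter per MJ intercepted).
#' @param k_leaf canopy light-interception rate per appeared leaf; interception
#'   is `1 - exp(-k_leaf * leaves)`.
#' @param base_density baseline tiller density (tillers/m2) before the `G3`
#'   tillering response.
#' @param panicle_span thermal span of the panicle-development phase between
#'   panicle initiation and anthesis (GDD). 450 GDD gives 100--120 day cycles
#'   at regional temperatures, matching observed rainfed rice.
#' @param heat_ramp width of the linear heat-sterility ramp above `THOT` (deg C).
#' @param cold_ramp width of the linear cold-sterility ramp below `TCLDF` (deg C).
#' @param tcldp_slope additive panicle-phase delay per deg C of daily minimum
#'   below `TCLDP` (GDD per deg C per day).
#' @param raw_frac readily-available-water fraction `p` of the LL--DUL store
#'   below which transpiration is restricted.
#' @param et_alpha radiation-to-reference-ET coefficient; reference ET is
#'   `0.408 * et_alpha * srad` mm/day.
#' @param kc_min crop-coefficient floor at zero canopy; demand scales from
#'   `kc_min` to 1 with canopy interception.
#' @param fill_frac fraction of daily assimilate that can be loaded into grain.
#' @param fill_stress_exp exponent on the water-stress factor for grain
#'   filling; >1 encodes that reproductive processes are more drought
#'   sensitive than vegetative growth.
#' @param max_hi hard cap on harvest index (keeps `HI < 1` for any input).
#' @param season_cap maximum simulated season length (days).
#' @param flower_window half-width of the sterility window around anthesis
#'   (days).
#' @return A named list of constants.
#' @export
crop_model_config <- function(tbase = 9, rue = 1.1, k_leaf = 0.12,
                              base_density = 150, panicle_span = 450,
                              heat_ramp = 5, cold_ramp = 4, tcldp_slope = 10,
                              raw_frac = 0.6, et_alpha = 1.1, kc_min = 0.3,
                              fill_frac = 0.85, fill_stress_exp = 3,
                              max_hi = 0.62, season_cap = 160,
                              flower_window = 5) {
  as.list(environment())
}

#' Daily thermal time
#'
#' Growing-degree-day increment: the daily mean temperature in excess of the
#' base temperature, floored at zero.
#'
#' @param tmin,tmax daily minimum and maximum temperature (deg C), `tmax >= tmin`.
#' @param tbase base temperature (deg C).
#' @return GDD increment (deg C day), never negative.
#' @examples
#' thermal_time(22, 30, 9)  # 17
#' @export
thermal_time <- function(tmin, tmax, tbase = 9) {
  if (any(tmax < tmin)) stop("thermal_time: tmax < tmin (malformed weather)")
  pmax(0, (tmin + tmax) / 2 - tbase)
}

#' Photothermal requirement for panicle initiation
#'
#' Effective thermal time that must accumulate before panicle initiation:
#' `P1` plus the photoperiod-induced delay `P2R` per hour of daylength above
#' the critical photoperiod `P2O`.
#'
#' @param P1 base thermal requirement (GDD).
#' @param P2O critical photoperiod (hours, in (0,24)).
#' @param P2R delay (GDD per hour above `P2O`).
#' @param daylength photoperiod of the day (hours).
#' @return effective GDD requirement, `>= P1`.
#' @export
photothermal_requirement <- function(P1, P2O, P2R, daylength) {
  stopifnot(P2O > 0, P2O < 24)
  P1 + P2R * pmax(0, daylength - P2O)
}

#' One day of the bucket water balance
#'
#' Single-layer store over the rooting depth. Rain is added (excess above
#' saturation leaves as runoff), transpiration is extracted at
#' `stress * et_demand` where the stress factor ramps linearly from 0 at the
#' wilting-point store to 1 once the readily available fraction `p` of the
#' LL--DUL store is held, and water above field capacity drains toward it at a
#' rate bounded by `SSKS`. The balance is exact:
#' `store' = store + rain - actual_et - drainage - runoff`.
#'
#' @param store current store (mm over the rooting depth), within
#'   `[SLLL, SSAT] * depth * 10`.
#' @param rain rain of the day (mm).
#' @param et_demand potential crop transpiration demand (mm).
#' @param soil a [soil_profile()].
#' @param p readily-available-water fraction (default 0.6).
#' @return list with `store`, `actual_et`, `drainage`, `runoff`, `stress`.
#' @export
water_balance_step <- function(store, rain, et_demand, soil, p = 0.6) {
  ll <- soil$SLLL * soil$depth * 10
  dul <- soil$SDUL * soil$depth * 10
  sat <- soil$SSAT * soil$depth * 10
  if (store < ll - 1e-8 || store > sat + 1e-8)
    stop("water_balance_step: store outside [wilting, saturation] bounds")

  store1 <- store + rain
  runoff <- max(0, store1 - sat)
  store1 <- min(store1, sat)

  stress <- min(1, max(0, (store1 - ll) / (p * (dul - ll))))
  actual_et <- min(stress * et_demand, store1 - ll)
  store1 <- store1 - actual_et

  drain_cap <- soil$SSKS * 24 * 10  # cm/h -> mm/day
  drainage <- min(max(0, store1 - dul), drain_cap)
  store1 <- store1 - drainage

  list(store = store1, actual_et = actual_et, drainage = drainage,
       runoff = runoff, stress = stress)
}

#' Spikelet sterility from temperature extremes in the flowering window
#'
#' Heat sterility ramps linearly on daily maxima from 0 at `THOT` to 1 at
#' `THOT + heat_ramp`; cold sterility ramps on daily minima from 0 at `TCLDF`
#' to 1 at `TCLDF - cold_ramp`. Daily terms are averaged over the window and
#' combined as independent risks, `1 - (1 - heat)(1 - cold)`.
#'
#' @param window_tmax,window_tmin daily maxima and minima over the flowering
#'   window (deg C), non-empty.
#' @param THOT,TCLDF sterility thresholds (deg C).
#' @param heat_ramp,cold_ramp ramp widths (deg C).
#' @return sterile fraction in `[0, 1]`.
#' @export
sterility_fraction <- function(window_tmax, window_tmin, THOT, TCLDF,
                               heat_ramp = 5, cold_ramp = 4) {
  if (!length(window_tmax) || !length(window_tmin))
    stop("sterility_fraction: empty flowering window (phenology failure)")
  heat <- mean(pmin(1, pmax(0, (window_tmax - THOT) / heat_ramp)))
  cold <- mean(pmin(1, pmax(0, (TCLDF - window_tmin) / cold_ramp)))
  1 - (1 - heat) * (1 - cold)
}

#' Environment scenario
#'
#' One soil profile plus one daily weather series plus management: the "E" of
#' the G-by-E interaction.
#'
#' @param soil a [soil_profile()].
#' @param weather a [weather_series()].
#' @param sowing index of the sowing day within `weather` (default 1).
#' @param label scenario name.
#' @param weight optional area weight of the environment within the region.
#' @return list of class `environment_scenario`.
#' @export
environment_scenario <- function(soil, weather, sowing = 1, label = "env",
                                 weight = NA_real_) {
  stopifnot(inherits(soil, "soil_profile"), inherits(weather, "weather_series"),
            sowing >= 1, sowing <= nrow(weather))
  structure(list(soil = soil, weather = weather, sowing = sowing,
                 label = label, weight = weight),
            class = "environment_scenario")
}

#' Simulate one genotype in one environment
#'
#' Daily-loop surrogate of a process-based rice model. Thermal time drives
#' phenology (vegetative phase until the photothermal requirement is met,
#' then a fixed-span panicle phase delayed by cold minima below `TCLDP`, then
#' `P5` GDD of grain filling); leaves appear every `PHINT` GDD and set a
#' saturating light-interception factor; biomass accrues as
#' RUE x radiation x interception x water stress; tillering responds to `G3`,
#' canopy and vegetative water status; grain number follows `G1` x tillers,
#' discounted by thermal sterility (`THOT`, `TCLDF`) and flowering-window
#' stress; grain filling is limited both by the sink (`grains * G2`) and by
#' the (more drought-sensitive) assimilate supply during the filling window.
#'
#' A run that never reaches anthesis within the season cap is returned flagged
#' (`failed = TRUE`) with zero yield rather than raising an error, so
#' optimization can penalize it.
#'
#' @param coeffs a [rice_coefficients()] vector.
#' @param env an [environment_scenario()].
#' @param config constants from [crop_model_config()].
#' @return list of class `simulation_result`: `biomass`, `yield` (kg/ha),
#'   `grains`, `tillers` (per m2), `anthesis`, `maturity` (days after sowing),
#'   `cum_et` (mm), `HI`, `WUE` (kg/ha/mm), `sterility`, `failed`, plus a
#'   `water` list with the mass-balance components (`rain`, `init_store`,
#'   `final_store`, `et`, `drainage`, `runoff`).
#' @examples
#' env <- generate_environment_set(seed = 1)[[1]]
#' res <- simulate_rice(rice_coefficients(), env)
#' c(yield = res$yield, HI = res$HI, WUE = res$WUE)
#' @export
simulate_rice <- function(coeffs, env, config = crop_model_config()) {
  validate_coefficients(coeffs)
  wx <- env$weather[env$sowing:nrow(env$weather), , drop = FALSE]
  n <- min(nrow(wx), config$season_cap)
  soil <- env$soil

  store <- soil$SDUL * soil$depth * 10  # sow at field capacity
  init_store <- store
  cum <- c(rain = 0, et = 0, drain = 0, runoff = 0)

  phase <- 1L  # 1 vegetative, 2 panicle, 3 grain fill, 4 mature
  gdd_phase <- 0
  pan_req <- config$panicle_span
  leaves <- 0
  biomass <- 0
  anthesis <- NA_integer_
  maturity <- NA_integer_
  pi_canopy <- NA_real_
  stress_day <- numeric(n)
  fill_supply <- 0
  gdd_fill <- 0
  last_day <- n

  for (d in seq_len(n)) {
    gdd <- thermal_time(wx$tmin[d], wx$tmax[d], config$tbase)
    if (phase < 3L) leaves <- leaves + gdd / coeffs[["PHINT"]]
    canopy <- 1 - exp(-config$k_leaf * leaves)

    et0 <- 0.408 * config$et_alpha * wx$srad[d]
    demand <- et0 * (config$kc_min + (1 - config$kc_min) * canopy)
    wb <- water_balance_step(store, wx$rain[d], demand, soil,
                             p = config$raw_frac)
    store <- wb$store
    cum <- cum + c(wx$rain[d], wb$actual_et, wb$drainage, wb$runoff)
    stress_day[d] <- wb$stress

    assim <- config$rue * wx$srad[d] * canopy * wb$stress * 10  # kg/ha/day
    biomass <- biomass + assim

    if (phase == 1L) {
      gdd_phase <- gdd_phase + gdd
      req <- photothermal_requirement(coeffs[["P1"]], coeffs[["P2O"]],
                                      coeffs[["P2R"]], wx$daylength[d])
      if (gdd_phase >= req) {
        phase <- 2L
        gdd_phase <- 0
        pi_canopy <- canopy
      }
    } else if (phase == 2L) {
      pan_req <- pan_req +
        config$tcldp_slope * max(0, coeffs[["TCLDP"]] - wx$tmin[d])
      gdd_phase <- gdd_phase + gdd
      if (gdd_phase >= pan_req) {
        phase <- 3L
        anthesis <- d
      }
    } else if (phase == 3L) {
      gdd_fill <- gdd_fill + gdd
      fill_supply <- fill_supply +
        config$fill_frac * config$rue * wx$srad[d] * canopy *
          wb$stress^config$fill_stress_exp * 10
      if (gdd_fill >= coeffs[["P5"]]) {
        phase <- 4L
        maturity <- d
        last_day <- d
        break
      }
    }
  }

  failed <- is.na(anthesis)
  if (is.na(maturity)) maturity <- last_day

  if (failed) {
    tillers <- 0; grains <- 0; yield <- 0; sterility <- 0
  } else {
    veg_stress <- mean(stress_day[seq_len(max(1, anthesis - 1))])
    tillers <- config$base_density *
      (1 + coeffs[["G3"]] * pi_canopy * veg_stress)
    win <- max(1, anthesis - config$flower_window):
      min(last_day, anthesis + config$flower_window)
    sterility <- sterility_fraction(wx$tmax[win], wx$tmin[win],
                                    coeffs[["THOT"]], coeffs[["TCLDF"]],
                                    config$heat_ramp, config$cold_ramp)
    fl_stress <- mean(stress_day[win])
    grains <- coeffs[["G1"]] * tillers * (1 - sterility) * fl_stress
    yield <- min(grains * coeffs[["G2"]] * 10,  # g/m2 -> kg/ha
                 fill_supply,
                 config$max_hi * biomass)
  }

  structure(list(
    biomass = biomass, yield = yield, grains = grains, tillers = tillers,
    anthesis = if (failed) NA_integer_ else anthesis, maturity = maturity,
    cum_et = cum[["et"]],
    HI = if (biomass > 0) yield / biomass else 0,
    WUE = if (cum[["et"]] > 0) yield / cum[["et"]] else 0,
    sterility = sterility, failed = failed,
    water = list(rain = cum[["rain"]], init_store = init_store,
                 final_store = store, et = cum[["et"]],
                 drainage = cum[["drain"]], runoff = cum[["runoff"]])),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    paste0("Simulation result: yield %.0f kg/ha, biomass %.0f kg/ha, ",
           "HI %.3f, WUE %.2f kg/ha/mm\n",
           "  anthesis day %s, maturity day %d, ET %.0f mm, sterility %.2f%s\n"),
    x$yield, x$biomass, x$HI, x$WUE,
    ifelse(is.na(x$anthesis), "NA", x$anthesis), x$maturity, x$cum_et,
    x$sterility, if (x$failed) " [FAILED: never flowered]" else ""))
  invisible(x)
}

#' Output channels screened by the sensitivity layer
#'
#' @param res a `simulation_result`.
#' @return named numeric vector: biomass, yield, grains, tillers, anthesis,
#'   maturity (a failed run reports anthesis as the season cap).
#' @export
result_channels <- function(res) {
  c(biomass = res$biomass, yield = res$yield, grains = res$grains,
    tillers = res$tillers,
    anthesis = if (is.na(res$anthesis)) res$maturity else res$anthesis,
    maturity = res$maturity)
}
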