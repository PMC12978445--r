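#' Single-layer soil profile
#'
#' The simulator's bucket water balance needs a rooting depth and the four
#' hydraulic constants: wilting point `SLLL`, field capacity (drained upper
#' limit) `SDUL`, saturation `SSAT` (all cm3/cm3) and saturated hydraulic
#' conductivity `SSKS` (cm/h). Texture, bulk density, organic carbon,
#' nitrogen, pH and coarse fraction are carried as metadata.
#'
#' @param depth rooting depth (cm).
#' @param SLLL,SDUL,SSAT volumetric water contents, `0 < SLLL < SDUL < SSAT < 1`.
#' @param SSKS saturated hydraulic conductivity (cm/h), positive.
#' @param clay,silt,sand texture (g/kg), metadata.
#' @param SBDM bulk density (g/cm3), metadata.
#' @param SLOC,SLNI,SLHW,SLCF organic carbon, nitrogen, pH, coarse fraction,
#'   metadata.
#' @return A list of class `soil_profile`.
#' @export
soil_profile <- function(depth = 40, SLLL = 0.16, SDUL = 0.29, SSAT = 0.44,
                         SSKS = 0.75, clay = 26.33, silt = 30.53, sand = NA,
                         SBDM = 1.50, SLOC = NA, SLNI = NA, SLHW = NA,
                         SLCF = NA) {
  if (!(SLLL > 0 && SLLL < SDUL && SDUL < SSAT && SSAT < 1))
    stop("soil_profile: need 0 < SLLL < SDUL < SSAT < 1")
  if (depth <= 0) stop("soil_profile: depth must be positive")
  if (SSKS <= 0) stop("soil_profile: SSKS must be positive")
  structure(list(depth = depth, SLLL = SLLL, SDUL = SDUL, SSAT = SSAT,
                 SSKS = SSKS, clay = clay, silt = silt, sand = sand,
                 SBDM = SBDM, SLOC = SLOC, SLNI = SLNI, SLHW = SLHW,
                 SLCF = SLCF),
            class = "soil_profile")
}

#' @export
print.soil_profile <- function(x, ...) {
  cat(sprintf(
    "Soil profile: depth %.0f cm, SLLL %.3f, SDUL %.3f, SSAT %.3f, SSKS %.2f cm/h\n",
    x$depth, x$SLLL, x$SDUL, x$SSAT, x$SSKS))
  invisible(x)
}

#' Pedotransfer estimation of soil hydraulic properties
#'
#' Simplified Saxton--Rawls (2006) regressions mapping texture and organic
#' matter to wilting point (1500 kPa), field capacity (33 kPa), saturation and
#' saturated conductivity. Sand and clay are mass fractions of the fine earth;
#' organic matter is in percent.
#'
#' @param sand,clay fractions in `[0,1]` with `sand + clay <= 1`.
#' @param om organic matter (%), default 1.5.
#' @return list with `SLLL`, `SDUL`, `SSAT` (cm3/cm3) and `SSKS` (cm/h),
#'   satisfying `SLLL < SDUL < SSAT`.
#' @references Saxton, K.E. and Rawls, W.J. (2006) Soil water characteristic
#'   estimates by texture and organic matter for hydrologic solutions.
#'   Soil Science Society of America Journal 70:1569-1578.
#' @export
pedotransfer <- function(sand, clay, om = 1.5) {
  if (any(sand < 0) || any(clay < 0) || any(om < 0))
    stop("pedotransfer: inputs must be non-negative")
  if (any(sand + clay > 1)) stop("pedotransfer: sand + clay must be <= 1")
  S <- sand; C <- clay; OM <- om

  t1500 <- -0.024 * S + 0.487 * C + 0.006 * OM +
    0.005 * S * OM - 0.013 * C * OM + 0.068 * S * C + 0.031
  th1500 <- t1500 + (0.14 * t1500 - 0.02)

  t33 <- -0.251 * S + 0.195 * C + 0.011 * OM +
    0.006 * S * OM - 0.027 * C * OM + 0.452 * S * C + 0.299
  th33 <- t33 + (1.283 * t33^2 - 0.374 * t33 - 0.015)

  ts33 <- 0.278 * S + 0.034 * C + 0.022 * OM -
    0.018 * S * OM - 0.027 * C * OM - 0.584 * S * C + 0.078
  th_s33 <- ts33 + (0.636 * ts33 - 0.107)

  th_sat <- th33 + th_s33 - 0.097 * S + 0.043

  # guard the regression tails so the physical ordering always holds
  th1500 <- pmax(th1500, 0.01)
  th33 <- pmax(th33, th1500 + 0.01)
  th_sat <- pmin(pmax(th_sat, th33 + 0.01), 0.60)

  lambda <- (log(th33) - log(th1500)) / (log(1500) - log(33))
  ks_mmh <- 1930 * (th_sat - th33)^(3 - lambda)  # mm/h

  list(SLLL = th1500, SDUL = th33, SSAT = th_sat,
       SSKS = pmax(ks_mmh / 10, 1e-4))
}

#' Read and write soil profiles
#'
#' CSV (one row, columns named as the [soil_profile()] fields) or JSON,
#' selected by extension.
#'
#' @param path file ending in `.csv` or `.json`.
#' @return `read_soil()` returns a [soil_profile()].
#' @export
read_soil <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    row <- jsonlite::fromJSON(path)
  } else {
    row <- utils::read.csv(path, stringsAsFactors = FALSE)[1, ]
  }
  keep <- intersect(names(formals(soil_profile)), names(row))
  do.call(soil_profile, lapply(row[keep], as.numeric))
}

#' @rdname read_soil
#' @param soil a [soil_profile()].
#' @export
write_soil <- function(soil, path) {
  df <- as.data.frame(unclass(soil))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(df), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
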