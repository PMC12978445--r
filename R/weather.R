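#' Daily weather series
#'
#' Construct and validate the daily weather table the simulator consumes.
#' Columns: `tmin`, `tmax` (deg C), `srad` (MJ/m2/day), `rh` (%), `wind`
#' (m/s), `rain` (mm/day) and `daylength` (hours). If `daylength` is absent it
#' is computed from `latitude` and day of year via the solar-declination
#' formula.
#'
#' @param data data.frame with at least `tmin`, `tmax`, `srad`, `rh`, `wind`,
#'   `rain`; optionally `daylength` and `doy`.
#' @param latitude site latitude in decimal degrees, used only when
#'   `daylength` must be computed. Default 12.5 (Casamance).
#' @param doy_start day of year of the first record (default 152, early June,
#'   the regional sowing window).
#' @return A data.frame of class `weather_series` with a `latitude` attribute.
#' @export
weather_series <- function(data, latitude = 12.5, doy_start = 152) {
  need <- c("tmin", "tmax", "srad", "rh", "wind", "rain")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("weather_series: missing column(s) ",
                         paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  if (!"doy" %in% names(data))
    data$doy <- ((doy_start - 1 + seq_len(nrow(data)) - 1) %% 365) + 1
  if (!"daylength" %in% names(data))
    data$daylength <- day_length(latitude, data$doy)
  validate_weather(data)
  structure(data, class = c("weather_series", "data.frame"),
            latitude = latitude)
}

validate_weather <- function(data) {
  if (any(data$tmax < data$tmin))
    stop("weather_series: tmax < tmin on day(s) ",
         paste(utils::head(which(data$tmax < data$tmin), 5), collapse = ", "))
  if (any(data$rain < 0)) stop("weather_series: negative rain")
  if (any(data$srad < 0)) stop("weather_series: negative solar radiation")
  if (any(data$rh < 0 | data$rh > 100)) stop("weather_series: rh outside [0,100]")
  if (any(data$daylength <= 0 | data$daylength >= 24))
    stop("weather_series: daylength outside (0,24)")
  invisible(data)
}

#' Astronomical day length
#'
#' Day length in hours from latitude and day of year, using the standard
#' solar-declination formula (declination -23.45 cos(2 pi (doy + 10) / 365);
#' day length 24/pi acos(-tan(lat) tan(decl))), with the hour-angle argument
#' clamped for polar latitudes.
#'
#' @param latitude decimal degrees (positive north).
#' @param doy day of year (1--365).
#' @return numeric vector of hours in (0, 24).
#' @export
day_length <- function(latitude, doy) {
  phi <- latitude * pi / 180
  decl <- -23.45 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  h <- -tan(phi) * tan(decl)
  h <- pmin(1, pmax(-1, h))
  24 / pi * acos(h)
}

#' Read and write DSSAT-style weather files
#'
#' A minimal dialect of the DSSAT `.WTH` format: a `*WEATHER DATA` title line,
#' an `@INSI LAT LONG ELEV` station header, then an `@DATE SRAD TMAX TMIN RAIN
#' RH WIND` table with `DATE` as `YYDDD`. Values are whitespace separated;
#' files written by [write_wth()] round-trip through [read_wth()].
#'
#' @param path file path.
#' @return [read_wth()] returns a [weather_series()].
#' @export
read_wth <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr_i <- grep("^@INSI", lines)
  if (!length(hdr_i)) stop("read_wth: no @INSI station header in ", path)
  hdr <- strsplit(trimws(lines[hdr_i[1] + 1]), "\\s+")[[1]]
  latitude <- as.numeric(hdr[2])
  tab_i <- grep("^@DATE", lines)
  if (!length(tab_i)) stop("read_wth: no @DATE table header in ", path)
  cols <- strsplit(sub("^@", "", trimws(lines[tab_i[1]])), "\\s+")[[1]]
  body <- lines[(tab_i[1] + 1):length(lines)]
  rec <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  rec <- as.data.frame(rec)
  names(rec) <- cols
  doy <- rec$DATE %% 1000
  weather_series(
    data.frame(tmin = rec$TMIN, tmax = rec$TMAX, srad = rec$SRAD,
               rh = rec$RH, wind = rec$WIND, rain = rec$RAIN, doy = doy),
    latitude = latitude)
}

#' @rdname read_wth
#' @param wx a [weather_series()].
#' @param station 4-character station code written into the header.
#' @param year 2-digit year used to form the `YYDDD` date stamp.
#' @export
write_wth <- function(wx, path, station = "SYNT", year = 13) {
  lat <- attr(wx, "latitude")
  if (is.null(lat)) lat <- 12.5
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("*WEATHER DATA : %s synthetic series", station),
               "@INSI      LAT     LONG  ELEV",
               sprintf("%4s %8.3f %8.3f %5.0f", station, lat, -15.0, 20)),
             con)
  writeLines("@DATE  SRAD  TMAX  TMIN  RAIN    RH  WIND", con)
  date <- year * 1000 + wx$doy
  writeLines(sprintf("%05d %5.1f %5.1f %5.1f %5.1f %5.1f %5.2f",
                     date, wx$srad, wx$tmax, wx$tmin, wx$rain, wx$rh,
                     wx$wind),
             con)
  invisible(path)
}

#' Read and write weather as plain CSV
#'
#' CSV twin of the `.WTH` dialect with columns `doy, tmin, tmax, srad, rh,
#' wind, rain` (and optionally `daylength`).
#'
#' @param path file path.
#' @param latitude latitude used to recompute day length when the column is
#'   absent.
#' @return [read_weather_csv()] returns a [weather_series()].
#' @export
read_weather_csv <- function(path, latitude = 12.5) {
  weather_series(utils::read.csv(path), latitude = latitude)
}

#' @rdname read_weather_csv
#' @param wx a [weather_series()].
#' @export
write_weather_csv <- function(wx, path) {
  utils::write.csv(
    wx[, c("doy", "tmin", "tmax", "srad", "rh", "wind", "rain", "daylength")],
    path, row.names = FALSE)
  invisible(path)
}
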