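#' Genetic coefficient vector of a rice genotype
#'
#' Bundles the eleven coefficients through which the growth simulator sees a
#' genotype: phenological development (`P1`, `P2O`, `P2R`, `P5`), source--sink
#' partitioning (`PHINT`, `G1`, `G2`, `G3`) and thermal stress thresholds
#' (`THOT`, `TCLDP`, `TCLDF`).
#'
#' @param P1 thermal time from emergence to panicle initiation (GDD, deg C day).
#' @param P2O critical photoperiod below which development is unaffected by
#'   daylength (hours, in (0, 24)).
#' @param P2R photoperiod-induced delay per hour of daylength above `P2O`
#'   (GDD / hour).
#' @param P5 grain-filling duration (GDD).
#' @param PHINT phyllochron interval: thermal time between successive leaf
#'   appearances (GDD / leaf).
#' @param G1 spikelets per panicle (dimensionless scaling count).
#' @param G2 potential single-grain weight (g).
#' @param G3 tillering coefficient (dimensionless, roughly 0--2).
#' @param THOT daily-maximum temperature above which heat sterility sets in
#'   (deg C).
#' @param TCLDP daily-minimum temperature below which panicle development is
#'   delayed (deg C).
#' @param TCLDF daily-minimum temperature below which cold sterility sets in
#'   (deg C).
#' @return A named numeric vector of class `rice_coefficients`.
#' @examples
#' cv <- rice_coefficients(P1 = 560, P5 = 350)
#' cv["P5"]
#' @export
rice_coefficients <- function(P1 = 560, P2O = 11.7, P2R = 50, P5 = 350,
                              PHINT = 83, G1 = 60, G2 = 0.025, G3 = 1.0,
                              THOT = 36.5, TCLDP = 15, TCLDF = 12) {
  x <- c(P1 = P1, P2O = P2O, P2R = P2R, P5 = P5, PHINT = PHINT,
         G1 = G1, G2 = G2, G3 = G3, THOT = THOT, TCLDP = TCLDP,
         TCLDF = TCLDF)
  validate_coefficients(x)
  structure(x, class = "rice_coefficients")
}

coefficient_names <- function() names(rice_coefficients())

validate_coefficients <- function(x) {
  need <- c("P1", "P2O", "P2R", "P5", "PHINT", "G1", "G2", "G3",
            "THOT", "TCLDP", "TCLDF")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing coefficient(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(x[need]))) stop("coefficients must be finite")
  pos <- c("P1", "P2O", "P2R", "P5", "PHINT", "G1", "G2", "G3")
  if (any(x[pos] < 0)) stop("coefficient(s) ",
                            paste(pos[x[pos] < 0], collapse = ", "),
                            " must be non-negative")
  if (x["P2O"] <= 0 || x["P2O"] >= 24) stop("P2O must lie in (0, 24) hours")
  if (x["G2"] <= 0) stop("G2 must be positive")
  invisible(x)
}

# Merge a (partial, named) vector of searched coefficients into a full set.
# Used by the optimizer, which searches 8 of the 11 coefficients.
merge_coefficients <- function(base, partial) {
  x <- unclass(base)
  x[names(partial)] <- as.numeric(partial)
  structure(x, class = "rice_coefficients")
}

#' @export
print.rice_coefficients <- function(x, ...) {
  cat("Rice genetic coefficients:\n")
  print(unclass(x))
  invisible(x)
}

#' Read or write coefficient sets
#'
#' Coefficient sets are stored as CSV (one row per genotype, columns `name`
#' plus the eleven coefficients) or as JSON (an array of named objects); the
#' format is picked from the file extension.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return `read_coefficients()` returns a named list of
#'   [rice_coefficients()]; `write_coefficients()` returns `path` invisibly.
#' @export
read_coefficients <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(nrow(rows)), function(i) {
    do.call(rice_coefficients,
            as.list(rows[i, coefficient_names(), drop = TRUE]))
  })
  names(out) <- rows$name
  out
}

#' @rdname read_coefficients
#' @param sets named list of [rice_coefficients()].
#' @export
write_coefficients <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s) as.data.frame(t(unclass(s)))))
  df <- cbind(name = names(sets), df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
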