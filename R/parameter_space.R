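#' Bounded search space over genetic coefficients
#'
#' A `parameter_space` holds, for an ordered set of coefficients, the lower and
#' upper bound and the Morris step size `delta` (all in the coefficient's own
#' units). It is shared by the sensitivity layer (trajectory construction) and
#' the optimizer (search bounds).
#'
#' @param names character vector of coefficient identifiers (order matters).
#' @param lower,upper numeric bounds, one per coefficient, `lower < upper`.
#' @param delta Morris step size per coefficient; defaults to a quarter of the
#'   range, and must satisfy `0 < delta <= upper - lower`.
#' @return An object of class `parameter_space`: a list with elements `names`,
#'   `lower`, `upper`, `delta` (all named by coefficient) and `k`, the number
#'   of coefficients.
#' @seealso [default_parameter_space()]
#' @export
parameter_space <- function(names, lower, upper, delta = NULL) {
  names <- as.character(names)
  k <- length(names)
  stopifnot(k >= 1, !anyDuplicated(names),
            length(lower) == k, length(upper) == k)
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("parameter_space: bounds must be finite")
  if (any(lower >= upper))
    stop("parameter_space: lower must be strictly below upper")
  if (is.null(delta)) delta <- (upper - lower) / 4
  delta <- rep_len(as.numeric(delta), k)
  if (any(delta <= 0) || any(delta > upper - lower))
    stop("parameter_space: delta must be in (0, upper - lower]")
  structure(
    list(names = names,
         lower = stats::setNames(lower, names),
         upper = stats::setNames(upper, names),
         delta = stats::setNames(delta, names),
         k = k),
    class = "parameter_space")
}

# Default physiological bounds for the 11 coefficients. Derived from ranges
# used when calibrating rice cultivars of contrasting cycle length; step size
# is a quarter of the range.
.default_bounds <- data.frame(
  name  = c("P1", "P2O", "P2R", "P5", "PHINT", "G1", "G2", "G3",
            "THOT", "TCLDP", "TCLDF"),
  lower = c(400, 10.0,   5, 150, 55, 40, 0.015, 0.5, 32, 12, 10),
  upper = c(1100, 14.0, 200, 650, 95, 85, 0.035, 1.5, 40, 18, 16),
  stringsAsFactors = FALSE)

#' Default coefficient bounds
#'
#' Ships the package's documented default bounds for all 11 genetic
#' coefficients (thermal times in GDD, `P2O` in hours, `G2` in g, thresholds
#' in deg C), or any ordered subset of them.
#'
#' @param coefficients which coefficients to include, in order.
#' @return A [parameter_space()].
#' @examples
#' sp <- default_parameter_space()
#' sp$k  # 11
#' ga_sp <- default_parameter_space(ga_coefficients())
#' @export
default_parameter_space <- function(coefficients = .default_bounds$name) {
  i <- match(coefficients, .default_bounds$name)
  if (anyNA(i)) stop("unknown coefficient(s): ",
                     paste(coefficients[is.na(i)], collapse = ", "))
  b <- .default_bounds[i, ]
  parameter_space(b$name, b$lower, b$upper)
}

#' The eight coefficients searched by the optimizer
#'
#' Thermal-stress thresholds (THOT, TCLDP, TCLDF) are excluded from the search
#' space because their influence is context dependent (near zero in warm
#' environments); the remaining eight drive phenology and source--sink
#' partitioning.
#' @return character vector of length 8.
#' @export
ga_coefficients <- function() {
  c("P1", "P5", "P2R", "PHINT", "P2O", "G1", "G2", "G3")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("Parameter space over", x$k, "coefficient(s)\n")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.parameter_space <- function(x, ...) {
  data.frame(name = x$names, lower = unname(x$lower),
             upper = unname(x$upper), delta = unname(x$delta),
             stringsAsFactors = FALSE)
}

# internal: check a point (named or ordered vector) lies within bounds
space_contains <- function(space, x, tol = 1e-9) {
  x <- as.numeric(x[space$names])
  all(x >= space$lower - tol) && all(x <= space$upper + tol)
}

# internal: uniform draw within bounds (uses the caller's RNG stream)
space_runif <- function(space) {
  stats::setNames(stats::runif(space$k, space$lower, space$upper),
                  space$names)
}
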