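#' Bounded six-dimensional parameter hypercube
#'
#' Defines the sampling ranges for the six rate constants, in the fixed order
#' `sigma, d, lam, tau, delta, gamma`. Each range is `c(lower, upper)` with
#' `0 <= lower <= upper`.
#'
#' @param sigma,d,lam,tau,delta,gamma numeric length-2 vectors
#'   `c(lower, upper)`.
#' @return An object of class `parameter_space`: a 6 x 2 matrix with rows
#'   named by parameter and columns `lower`, `upper`.
#' @seealso [default_parameter_space()] for the calibrated ranges,
#'   [explore_parameter_space()] for the screening procedure.
#' @export
parameter_space <- function(sigma = c(0, 1), d = c(0, 1), lam = c(0, 1),
                            tau = c(0.012, 1), delta = c(0, 1),
                            gamma = c(0.2248, 1)) {
  args <- list(sigma = sigma, d = d, lam = lam, tau = tau, delta = delta,
               gamma = gamma)
  if (any(vapply(args, length, integer(1L)) != 2L)) {
    stop("each range must be c(lower, upper)", call. = FALSE)
  }
  ranges <- rbind(sigma = sigma, d = d, lam = lam, tau = tau, delta = delta,
                  gamma = gamma)
  colnames(ranges) <- c("lower", "upper")
  if (any(!is.finite(ranges))) stop("ranges must be finite", call. = FALSE)
  if (any(ranges[, "lower"] < 0)) {
    stop("lower bounds must be >= 0", call. = FALSE)
  }
  if (any(ranges[, "lower"] > ranges[, "upper"])) {
    stop("each lower bound must not exceed its upper bound", call. = FALSE)
  }
  structure(ranges, class = "parameter_space")
}

#' Calibrated "realistic" parameter ranges
#'
#' The fixed six-dimensional hypercube used for all sensitivity analyses:
#' transcription `sigma` in \[0.012, 2.0\], mRNA diffusion `d` in \[0, 1.5\],
#' mRNA decay `lam` in \[0, 0.8\], translation `tau` in \[0.125, 1.0\],
#' protein diffusion `delta` in \[0, 1.5\] and protein decay `gamma` in
#' \[0.4, 0.9\] (all per minute). These are the ranges obtained from the
#' saturation/undetectability screening of parameter space.
#'
#' @return A [parameter_space()] object.
#' @export
default_parameter_space <- function() {
  parameter_space(sigma = c(0.012, 2.0), d = c(0.0, 1.5), lam = c(0.0, 0.8),
                  tau = c(0.125, 1.0), delta = c(0.0, 1.5),
                  gamma = c(0.4, 0.9))
}

#' Seed ranges for the parameter-space screen
#'
#' The starting hypercube of the iterative exploration procedure:
#' `sigma, d, lam, delta` in \[0, 1\], `tau` in \[0.012, 1\] and `gamma` in
#' \[0.2248, 1\] (non-zero lower bounds taken from earlier model estimates).
#'
#' @return A [parameter_space()] object.
#' @export
seed_parameter_space <- function() {
  parameter_space()
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("6-D parameter hypercube (rates per minute):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Map unit-hypercube coordinates into a parameter space
#'
#' Applies the per-column affine map `lower + u * (upper - lower)`.
#'
#' @param unit_points matrix of coordinates in `[0, 1]`, one column per
#'   parameter (6 columns).
#' @param space a [parameter_space()].
#' @return Matrix of the same shape in parameter units, columns named by
#'   parameter.
#' @export
scale_to_space <- function(unit_points, space) {
  stopifnot(inherits(space, "parameter_space"))
  u <- as.matrix(unit_points)
  if (ncol(u) != nrow(space)) {
    stop("'unit_points' must have one column per parameter (",
         nrow(space), ")", call. = FALSE)
  }
  if (any(u < 0 | u > 1)) {
    stop("unit coordinates must lie in [0, 1]", call. = FALSE)
  }
  lower <- space[, "lower"]
  width <- space[, "upper"] - space[, "lower"]
  scaled <- sweep(sweep(u, 2L, width, "*"), 2L, lower, "+")
  colnames(scaled) <- rownames(space)
  scaled
}

#' Sobol design over a parameter space
#'
#' Draws the first `n_points` Sobol points in the 6-D unit hypercube and maps
#' them onto `space`. The design is deterministic: the same `n_points`
#' reproduces the same matrices exactly.
#'
#' @param n_points design size.
#' @param space a [parameter_space()].
#' @return An object of class `sobol_design`: a list with `unit`
#'   (`n_points` x 6, in `[0,1)`), `scaled` (same shape, parameter units) and
#'   `space`.
#' @export
sobol_design <- function(n_points, space = default_parameter_space()) {
  stopifnot(inherits(space, "parameter_space"))
  unit <- sobol_sequence(n_points, nrow(space))
  colnames(unit) <- rownames(space)
  structure(list(unit = unit, scaled = scale_to_space(unit, space),
                 space = space),
            class = "sobol_design")
}

#' @export
print.sobol_design <- function(x, ...) {
  cat(sprintf("Sobol design: %d points in %d dimensions\n",
              nrow(x$unit), ncol(x$unit)))
  invisible(x)
}
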