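#' Define the coil-placement search space
#'
#' The search space is a disc of radius `radius` (mm) in the tangential
#' coil-placement plane, centred on the expected muscle representation,
#' crossed with a range of coil rotation angles (degrees). All search,
#' evaluation and simulation routines in the package operate inside this
#' space.
#'
#' @param center Length-2 numeric, physical anchor of the disc in mm.
#'   Informational only: all coordinates handled by the package are relative
#'   to this centre.
#' @param radius Disc radius R in mm. The default of 28.5 mm gives a
#'   3 mm / 20-degree test grid of roughly 2,800 points
#'   (see [build_test_grid()]).
#' @param theta_range Length-2 numeric, ordered range of coil rotation
#'   angles in degrees.
#' @return An object of class `"search_space"`.
#' @examples
#' sp <- search_space()
#' sp$radius
#' @export
search_space <- function(center = c(0, 0), radius = 28.5,
                         theta_range = c(0, 180)) {
  stopifnot(length(center) == 2, is.finite(center))
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a positive scalar (mm)")
  if (length(theta_range) != 2L || theta_range[1] >= theta_range[2])
    stop("'theta_range' must be an ordered pair of angles (degrees)")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 theta_range = as.numeric(theta_range)),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("Coil search space: disc radius %.1f mm, theta in [%g, %g] deg\n",
              x$radius, x$theta_range[1], x$theta_range[2]))
  invisible(x)
}

#' Construct stimulation parameters
#'
#' A stimulation parameter triple s = (x, y, theta): coil offset in mm
#' relative to the search-space centre and coil rotation angle in degrees.
#' Vectorised: returns a data frame with one row per point.
#'
#' @param x,y Coil offsets in mm.
#' @param theta Coil rotation angle(s) in degrees.
#' @param space Optional [search_space()]; when supplied the points are
#'   validated against it.
#' @return A data frame with columns `x`, `y`, `theta`.
#' @export
stimulation_params <- function(x, y, theta, space = NULL) {
  s <- data.frame(x = as.numeric(x), y = as.numeric(y),
                  theta = as.numeric(theta))
  if (anyNA(s) || any(!is.finite(as.matrix(s))))
    stop("stimulation parameters must be finite")
  if (!is.null(space)) assert_in_space(s, space)
  s
}

assert_in_space <- function(s, space, tol = 1e-8) {
  r2 <- s$x^2 + s$y^2
  if (any(r2 > space$radius^2 * (1 + tol)))
    stop("point(s) outside the search disc (x^2 + y^2 > R^2)")
  if (any(s$theta < space$theta_range[1] - tol |
          s$theta > space$theta_range[2] + tol))
    stop("theta outside the allowed rotation range")
  invisible(s)
}

#' Map physical coil parameters to normalized kernel coordinates
#'
#' The GP kernel uses one isotropic length scale over (x, y, theta), which
#' mixes millimetres and degrees. Coordinates are therefore mapped to a
#' normalized cube before kernel evaluation: x/R, y/R and
#' (theta - theta_min)/(theta_max - theta_min) scaled to span one unit,
#' so the isotropic length scale acts in comparable units.
#'
#' @param s Data frame with columns `x`, `y`, `theta` (see
#'   [stimulation_params()]).
#' @param space A [search_space()].
#' @return Numeric matrix with columns `x`, `y`, `theta` in normalized units.
#' @export
normalize_coords <- function(s, space) {
  th0 <- space$theta_range[1]
  thw <- diff(space$theta_range)
  cbind(x = s$x / space$radius,
        y = s$y / space$radius,
        theta = (s$theta - th0) / thw)
}

# Uniform draws on the disc x theta box. Latin-hypercube base when lhs = TRUE
# (space filling for designs/candidate sets), plain runif otherwise.
sample_space <- function(space, n, lhs = TRUE) {
  u <- if (lhs) lhs::randomLHS(n, 3) else matrix(stats::runif(3 * n), ncol = 3)
  rad <- space$radius * sqrt(u[, 1])      # area-uniform radius
  phi <- 2 * pi * u[, 2]
  th <- space$theta_range[1] + diff(space$theta_range) * u[, 3]
  data.frame(x = rad * cos(phi), y = rad * sin(phi), theta = th)
}

# Project a raw (x, y, theta) vector onto the space: radial clip to the disc,
# box clip for theta.
project_to_space <- function(x, y, theta, space) {
  r <- sqrt(x^2 + y^2)
  scl <- ifelse(r > space$radius, space$radius / r, 1)
  data.frame(x = x * scl, y = y * scl,
             theta = pmin(pmax(theta, space$theta_range[1]),
                          space$theta_range[2]))
}

# Axial (180-degree periodic) angular distance in degrees, in [0, 90] for a
# 180-degree axis.
axial_angle_diff <- function(a, b, period = 180) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}
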