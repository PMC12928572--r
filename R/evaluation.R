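#' Build the circular evaluation grid
#'
#' Cartesian lattice of stimulation locations at `spacing` mm kept inside
#' the disc, crossed with rotation angles from the lower to the upper end
#' of the angle range inclusive at `angle_step` intervals. At the defaults
#' (28.5 mm radius, 3 mm, 20 degrees) this yields roughly 2,800 test
#' points.
#'
#' @param space A [search_space()].
#' @param spacing Lattice spacing in mm.
#' @param angle_step Angular step in degrees; must divide the angle range.
#' @return An object of class `"test_grid"`: a data frame (`x`, `y`,
#'   `theta`) with attributes `spacing`, `angle_step`, `radius`.
#' @export
build_test_grid <- function(space, spacing = 3, angle_step = 20) {
  stopifnot(spacing > 0)
  if (diff(space$theta_range) %% angle_step != 0)
    stop("angle_step must divide the rotation range")
  m <- floor(space$radius / spacing)
  xy <- expand.grid(x = spacing * (-m:m), y = spacing * (-m:m))
  xy <- xy[xy$x^2 + xy$y^2 <= space$radius^2, ]
  angles <- seq(space$theta_range[1], space$theta_range[2], by = angle_step)
  g <- merge(xy, data.frame(theta = angles))
  g <- g[order(g$x, g$y, g$theta), ]
  rownames(g) <- NULL
  structure(g, spacing = spacing, angle_step = angle_step,
            radius = space$radius, class = c("test_grid", "data.frame"))
}

#' Normalized root-mean-square error between two response maps
#'
#' sqrt(mean(((mu_GT(s) - mu_hat(s)) / mu_GT(s))^2)) over the test grid,
#' where both mu's are the plug-in predicted response maps (see
#' [predicted_response()]). The pointwise denominator is floored at
#' `floor_frac` of the grid maximum of mu_GT so the relative error stays
#' finite where the ground-truth map is silent.
#'
#' @param gt Ground-truth `"warped_gp"` model.
#' @param fitted Fitted `"warped_gp"` model to evaluate.
#' @param grid A [build_test_grid()] grid.
#' @param floor_frac Denominator floor as a fraction of max mu_GT.
#' @return Scalar NRMSE (dimensionless, >= 0).
#' @export
nrmse <- function(gt, fitted, grid, floor_frac = 0.05) {
  if (is.null(grid) || nrow(grid) == 0L) stop("empty test grid")
  nrmse_values(predicted_response(gt, grid),
               predicted_response(fitted, grid), floor_frac)
}

nrmse_values <- function(mu_gt, mu_fit, floor_frac = 0.05) {
  denom <- pmax(mu_gt, floor_frac * max(mu_gt))
  sqrt(mean(((mu_gt - mu_fit) / denom)^2))
}

#' Center of gravity of the top-responding map region
#'
#' Selects the `ceiling(top_frac * n)` grid points with the highest
#' predicted response and returns their response-weighted mean x and
#' y, and the response-weighted circular mean of theta under the
#' 180-degree axial convention (angles are doubled, averaged as unit
#' vectors, halved, and mapped back to \[0, 180)).
#'
#' @param model A fitted `"warped_gp"`.
#' @param grid A [build_test_grid()] grid.
#' @param top_frac Fraction of highest-responding grid points to keep.
#' @return Named numeric vector `c(x, y, theta)`.
#' @export
center_of_gravity <- function(model, grid, top_frac = 0.1) {
  cog_values(grid, predicted_response(model, grid), top_frac)
}

cog_values <- function(grid, mu, top_frac = 0.1) {
  stopifnot(top_frac > 0, top_frac <= 1)
  if (all(mu <= 0)) stop("all responses are zero: center of gravity undefined")
  k <- ceiling(top_frac * nrow(grid))
  top <- order(mu, decreasing = TRUE)[seq_len(k)]
  w <- mu[top]
  ang2 <- 2 * grid$theta[top] * pi / 180      # axial angles -> full circle
  mean_ang <- atan2(sum(w * sin(ang2)), sum(w * cos(ang2))) / 2 * 180 / pi
  c(x = sum(w * grid$x[top]) / sum(w),
    y = sum(w * grid$y[top]) / sum(w),
    theta = mean_ang %% 180)
}

#' Spatial and angular distances between ground-truth and fitted hotspots
#'
#' d_xy is the Euclidean distance (mm) between the two centers of gravity;
#' d_theta is the axial angular difference (degrees, in \[0, 90\]) between
#' the two CoG angles. Both are symmetric in the two models.
#'
#' @param gt,fitted `"warped_gp"` models to compare.
#' @param grid A [build_test_grid()] grid.
#' @param top_frac Top-response fraction used for both CoGs.
#' @return Named numeric vector `c(d_xy, d_theta)`.
#' @export
hotspot_distances <- function(gt, fitted, grid, top_frac = 0.1) {
  cg <- center_of_gravity(gt, grid, top_frac)
  cf <- center_of_gravity(fitted, grid, top_frac)
  c(d_xy = unname(sqrt((cg["x"] - cf["x"])^2 + (cg["y"] - cf["y"])^2)),
    d_theta = unname(axial_angle_diff(cg["theta"], cf["theta"])))
}
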