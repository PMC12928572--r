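#' Parameters of a synthetic subject's latent MEP field
#'
#' Describes a synthetic motor map used to generate (coil configuration,
#' MEP amplitude) trials in place of recorded data: a spatial Gaussian bump
#' around the true hotspot, modulated by an axial Gaussian tuning curve in
#' the coil rotation angle.
#'
#' @param hotspot_xy Length-2 numeric, true hotspot location (mm).
#' @param hotspot_theta True preferred coil rotation angle (degrees).
#' @param peak_amplitude A, peak MEP amplitude at the hotspot (arbitrary
#'   units, mV-like).
#' @param spatial_scale lambda_s, spatial tuning width in mm.
#' @param angular_scale lambda_theta, angular tuning width in degrees.
#' @param orientation_depth rho in \[0, 1\]: 0 = response independent of
#'   coil angle, 1 = response vanishes at the orthogonal angle.
#' @param noise_cv Coefficient of variation of multiplicative trial-to-trial
#'   MEP noise.
#' @param n_trials Number of (configuration, response) pairs recorded for
#'   the subject.
#' @return An object of class `"subject_params"`.
#' @export
synthetic_subject_params <- function(hotspot_xy = c(0, 0),
                                     hotspot_theta = 90,
                                     peak_amplitude = 1,
                                     spatial_scale = 7,
                                     angular_scale = 30,
                                     orientation_depth = 0.8,
                                     noise_cv = 0.5,
                                     n_trials = 300) {
  stopifnot(length(hotspot_xy) == 2, peak_amplitude > 0, spatial_scale > 0,
            angular_scale > 0, orientation_depth >= 0,
            orientation_depth <= 1, noise_cv >= 0, n_trials >= 1)
  structure(list(hotspot_xy = as.numeric(hotspot_xy),
                 hotspot_theta = hotspot_theta,
                 peak_amplitude = peak_amplitude,
                 spatial_scale = spatial_scale,
                 angular_scale = angular_scale,
                 orientation_depth = orientation_depth,
                 noise_cv = noise_cv, n_trials = n_trials),
            class = "subject_params")
}

#' Noiseless latent MEP amplitude of a synthetic subject
#'
#' r(s) = A * exp(-((x - x*)^2 + (y - y*)^2) / (2 lambda_s^2)) *
#' \[(1 - rho) + rho * exp(-d_theta^2 / (2 lambda_theta^2))\], where
#' d_theta is the axial (180-degree periodic) difference to the preferred
#' angle.
#'
#' @param params A [synthetic_subject_params()] object.
#' @param s Data frame of stimulation points (`x`, `y`, `theta`).
#' @return Numeric vector of noiseless amplitudes.
#' @export
latent_response <- function(params, s) {
  d2 <- (s$x - params$hotspot_xy[1])^2 + (s$y - params$hotspot_xy[2])^2
  dth <- axial_angle_diff(s$theta, params$hotspot_theta)
  ang <- (1 - params$orientation_depth) +
    params$orientation_depth * exp(-dth^2 / (2 * params$angular_scale^2))
  params$peak_amplitude * exp(-d2 / (2 * params$spatial_scale^2)) * ang
}

#' Build a synthetic ground-truth subject
#'
#' Draws `n_trials` coil configurations quasi-uniformly over the space,
#' generates stochastic responses r_i = max(0, r_true(s_i) (1 + cv e_i))
#' with standard-normal e_i, fits the ground-truth warped GP on all pairs,
#' and records the ground-truth hotspot (argmax of the fitted posterior
#' mean). The fitted GP, not the latent field, is the response oracle used
#' everywhere downstream, mirroring a map fitted to a real recording.
#'
#' @param params A [synthetic_subject_params()] object.
#' @param seed Integer seed.
#' @param space A [search_space()].
#' @param fit_opts [gp_fit_options()] for the ground-truth fit.
#' @return An object of class `"gt_subject"`: `params`, `trials`,
#'   `gt_model`, `gt_hotspot`, `seed`.
#' @export
make_synthetic_subject <- function(params, seed, space = search_space(),
                                   fit_opts = gp_fit_options(seed = seed)) {
  stopifnot(inherits(params, "subject_params"))
  trials <- withr::with_seed(seed, {
    s <- sample_space(space, params$n_trials, lhs = TRUE)
    eps <- stats::rnorm(params$n_trials)
    r <- pmax(0, latent_response(params, s) * (1 + params$noise_cv * eps))
    cbind(s, response = r)
  })
  gt <- tryCatch(fit_gp(trials, space, opts = fit_opts),
                 error = function(e)
                   stop("ground-truth GP fit failed (A = ",
                        params$peak_amplitude, ", lambda_s = ",
                        params$spatial_scale, ", cv = ", params$noise_cv,
                        "): ", conditionMessage(e)))
  structure(list(params = params, trials = trials, gt_model = gt,
                 gt_hotspot = estimate_hotspot(gt, space), seed = seed,
                 space = space),
            class = "gt_subject")
}

#' Build a subject from a recorded trial CSV
#'
#' Fits the ground-truth warped GP to an existing trial log (see
#' [read_trials()]) so the same simulation pipeline runs on recorded data.
#'
#' @param trials Data frame with columns `x`, `y`, `theta`, `response`.
#' @param space A [search_space()].
#' @param fit_opts [gp_fit_options()].
#' @return A `"gt_subject"` with `params = NULL`.
#' @export
subject_from_trials <- function(trials, space = search_space(),
                                fit_opts = gp_fit_options()) {
  gt <- fit_gp(trials, space, opts = fit_opts)
  structure(list(params = NULL, trials = trials, gt_model = gt,
                 gt_hotspot = estimate_hotspot(gt, space), seed = NA,
                 space = space),
            class = "gt_subject")
}

#' @export
print.gt_subject <- function(x, ...) {
  cat(sprintf("Ground-truth subject: %d trials, hotspot (%.1f, %.1f) mm at %.0f deg\n",
              nrow(x$trials), x$gt_hotspot$x, x$gt_hotspot$y,
              x$gt_hotspot$theta))
  invisible(x)
}

#' Simulate a stochastic MEP response from the ground truth
#'
#' Draws one response from the ground-truth posterior predictive: in warped
#' space z ~ N(mu_z(s), var_z(s) + sigma_eps^2), returned as r = z^2, which
#' is nonnegative by construction. Repeated calls at the same point give
#' independent draws, matching trial-to-trial MEP variability.
#'
#' @param subject A `"gt_subject"`.
#' @param s Data frame of stimulation points (one response per row).
#' @param seed Optional seed; `NULL` draws from the ambient RNG stream.
#' @return Numeric vector of simulated amplitudes.
#' @export
simulate_response <- function(subject, s, seed = NULL) {
  post <- gp_posterior(subject$gt_model, s)
  sd_pred <- sqrt(post$var_warped + subject$gt_model$kernel$noise_var)
  draw <- function() stats::rnorm(nrow(s), post$mean_warped, sd_pred)^2
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Response oracle for the closed-loop search
#'
#' Convenience wrapper turning a subject into the `oracle` argument of
#' [run_search()].
#'
#' @param subject A `"gt_subject"`.
#' @return Function mapping a one-row stimulation data frame to one
#'   stochastic amplitude draw.
#' @export
subject_oracle <- function(subject) {
  function(s) simulate_response(subject, s)
}

#' Gain of free coil rotation over the fixed 45-degree convention
#'
#' Ratio of the maximum predicted response across all coil angles to the
#' maximum at a fixed rotation angle, both taken over a dense grid of the
#' ground-truth plug-in posterior-mean map. A ratio of 1.3 means a 30% larger maximum
#' expected MEP when the rotation angle is optimized rather than fixed.
#'
#' @param subject A `"gt_subject"`.
#' @param space A [search_space()] (defaults to the subject's).
#' @param fixed_theta The conventional fixed rotation angle, degrees.
#' @param spacing,angle_step Grid resolution (mm, degrees).
#' @return The scalar ratio (>= 1 up to numerical tolerance, since the
#'   fixed-angle grid is a subset of the full grid).
#' @export
fixed_angle_ratio <- function(subject, space = subject$space,
                              fixed_theta = 45, spacing = 1, angle_step = 5) {
  grid <- hotspot_grid(space, spacing = spacing, angle_step = angle_step)
  mu_all <- predicted_response(subject$gt_model, grid)
  xy <- unique(grid[, c("x", "y")])
  g45 <- data.frame(xy, theta = fixed_theta)
  mu_45 <- predicted_response(subject$gt_model, g45)
  r45 <- max(mu_45)
  if (r45 <= 0) stop("degenerate field: zero maximum at the fixed angle")
  max(mu_all) / r45
}

#' Generate the default synthetic subject ensemble
#'
#' An ensemble of orientation-tuned synthetic subjects standing in for a
#' recorded cohort: preferred angles drawn uniformly on \[20, 160\] degrees,
#' hotspots uniform in the inner 60% of the disc, peak amplitudes uniform
#' on \[0.5, 1.5\] a.u.; tuning widths, orientation depth and noise level
#' from `base_params`.
#'
#' @param n_subjects Ensemble size.
#' @param seed Integer seed (subject seeds are derived from it).
#' @param space A [search_space()].
#' @param base_params Template [synthetic_subject_params()]; per-subject
#'   hotspot location/angle and peak amplitude are randomized around it.
#' @param fit_opts [gp_fit_options()] passed to each ground-truth fit.
#' @return List of `"gt_subject"` objects.
#' @export
make_subject_ensemble <- function(n_subjects = 8, seed = 1,
                                  space = search_space(),
                                  base_params = synthetic_subject_params(),
                                  fit_opts = NULL) {
  draws <- withr::with_seed(seed, {
    u <- stats::runif(n_subjects)                 # radial position
    phi <- stats::runif(n_subjects, 0, 2 * pi)
    data.frame(
      r = 0.6 * space$radius * sqrt(u),
      phi = phi,
      theta_star = stats::runif(n_subjects, 20, 160),
      A = stats::runif(n_subjects, 0.5, 1.5))
  })
  lapply(seq_len(n_subjects), function(i) {
    p <- base_params
    p$hotspot_xy <- c(draws$r[i] * cos(draws$phi[i]),
                      draws$r[i] * sin(draws$phi[i]))
    p$hotspot_theta <- draws$theta_star[i]
    p$peak_amplitude <- draws$A[i]
    sub_seed <- as.integer((seed + 104729 * i) %% 2147483647)
    fo <- if (is.null(fit_opts)) gp_fit_options(seed = sub_seed) else fit_opts
    make_synthetic_subject(p, seed = sub_seed, space = space, fit_opts = fo)
  })
}
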