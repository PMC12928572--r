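#' Space-filling k-means initialization points
#'
#' Draws 4,000 uniform samples from the disc x angle-range space, clusters
#' them with k-means in normalized coordinates (so the angle participates
#' in the spread on an equal footing), and returns the k centroids mapped
#' back to physical units. Deterministic given `seed`.
#'
#' @param space A [search_space()].
#' @param k Number of initialization points.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return Data frame of k stimulation points (`x`, `y`, `theta`).
#' @export
kmeans_init <- function(space, k, seed = NULL) {
  if (k < 1) stop("k must be >= 1")
  run <- function() {
    pts <- sample_space(space, 4000, lhs = FALSE)
    Xn <- normalize_coords(pts, space)
    # Hartigan-Wong can report spurious Quick-TRANSfer non-convergence on
    # large uniform clouds; the centroids are still a valid space-filling
    # design, which is all the initialization needs
    km <- suppressWarnings(
      stats::kmeans(Xn, centers = k, nstart = 5, iter.max = 50))
    ctr <- km$centers
    th0 <- space$theta_range[1]
    out <- data.frame(x = ctr[, "x"] * space$radius,
                      y = ctr[, "y"] * space$radius,
                      theta = th0 + ctr[, "theta"] * diff(space$theta_range))
    rownames(out) <- NULL
    project_to_space(out$x, out$y, out$theta, space)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Configuration of one closed-loop hotspot search
#'
#' @param budget Total number of stimuli N (initialization included).
#' @param init_k Number of k-means initialization stimuli (0 = none; the
#'   loop then starts from a single uniformly random stimulus, since the
#'   surrogate needs at least one observation before informed proposals).
#' @param acquisition An [acquisition_spec()].
#' @param seed Integer seed; the whole run (initialization, hyperparameter
#'   restarts, proposals, stochastic responses drawn through the oracle) is
#'   reproducible given it.
#' @param space A [search_space()].
#' @param stopping Optional list `(window, tolerance)`: stop early when the
#'   fitted hyperparameters stagnate (see [stopping_check()]).
#' @param fit_opts A [gp_fit_options()] used for every refit.
#' @param init_points Optional precomputed initialization points (data frame
#'   `x`, `y`, `theta`), e.g. shared across acquisition conditions in a
#'   benchmark; overrides `init_k` point generation but must have `init_k`
#'   rows.
#' @return An object of class `"search_config"`.
#' @export
search_config <- function(budget = 40, init_k = 10,
                          acquisition = acquisition_spec("ts"), seed = 1,
                          space = search_space(), stopping = NULL,
                          fit_opts = gp_fit_options(), init_points = NULL) {
  if (init_k < 0) stop("init_k must be >= 0")
  if (budget < max(init_k, 1)) stop("budget must cover the initialization")
  if (!is.null(init_points) && nrow(init_points) != init_k)
    stop("init_points must have exactly init_k rows")
  if (is.null(acquisition$tau)) acquisition$tau <- budget / 3
  structure(list(budget = budget, init_k = init_k, acquisition = acquisition,
                 seed = seed, space = space, stopping = stopping,
                 fit_opts = fit_opts, init_points = init_points),
            class = "search_config")
}

#' Run the closed-loop hotspot search
#'
#' Implements the full loop: deliver the k-means initialization stimuli,
#' then iterate fit GP on all trials -> propose the next stimulation
#' parameters -> stimulate (query the response oracle) -> append, refitting
#' the hyperparameters after every sample, until the budget is reached or
#' the stopping criterion fires. The hotspot estimate is the argmax of the
#' final posterior mean response.
#'
#' @param oracle Function mapping a one-row stimulation data frame to a
#'   nonnegative response amplitude; may be stochastic (it is called inside
#'   the run's seeded RNG stream).
#' @param config A [search_config()].
#' @param hotspot Compute `hotspot_estimate` from the final model (a dense
#'   grid scan; skip when only the trace or CoG metrics are needed).
#' @return An object of class `"hotspot_search"`: `trials` (with `is_init`
#'   flag), the final `model`, `hotspot_estimate`, a per-step `trace`
#'   (proposal, response, acquisition name, beta_n, refitted
#'   hyperparameters), `stopped_early`, and the `config`.
#' @export
run_search <- function(oracle, config, hotspot = TRUE) {
  stopifnot(inherits(config, "search_config"))
  withr::with_seed(config$seed, run_search_impl(oracle, config, hotspot))
}

run_search_impl <- function(oracle, config, hotspot = TRUE) {
  space <- config$space
  spec <- config$acquisition
  init <- if (config$init_k > 0) {
    if (is.null(config$init_points)) kmeans_init(space, config$init_k)
    else config$init_points
  } else NULL

  trials <- data.frame(x = numeric(0), y = numeric(0), theta = numeric(0),
                       response = numeric(0), is_init = logical(0))
  trace <- list()
  model <- NULL
  n_prop <- 0L
  stopped <- FALSE

  for (i in seq_len(config$budget)) {
    if (i <= config$init_k) {
      s <- init[i, , drop = FALSE]
      is_init <- TRUE
      beta_n <- NA_real_
    } else {
      is_init <- FALSE
      if (nrow(trials) == 0L) {
        s <- propose_next(NULL, acquisition_spec("random"), space,
                          step_n = n_prop)
        beta_n <- NA_real_
      } else {
        s <- propose_next(model, spec, space, step_n = n_prop)
        beta_n <- spec$beta0 * exp(-n_prop / spec$tau)
      }
      n_prop <- n_prop + 1L
    }
    r <- tryCatch(oracle(s), error = function(e) e)
    if (inherits(r, "error")) {
      warning("response oracle failed at stimulus ", i, ": ",
              conditionMessage(r), "; returning partial result")
      res <- finalize_search(trials, model, trace, config, stopped,
                             aborted = TRUE, hotspot = hotspot)
      return(res)
    }
    trials <- rbind(trials,
                    data.frame(x = s$x, y = s$y, theta = s$theta,
                               response = r, is_init = is_init))
    refit <- i >= max(config$init_k, 1L)
    if (refit) {
      model <- fit_gp(trials, space, opts = config$fit_opts,
                      init = if (!is.null(model)) model$kernel)
    }
    trace[[i]] <- data.frame(
      step = i, x = s$x, y = s$y, theta = s$theta, response = r,
      is_init = is_init,
      acquisition = if (is_init) "init" else spec$name, beta_n = beta_n,
      amplitude = if (refit) model$kernel$amplitude else NA_real_,
      length_scale = if (refit) model$kernel$length_scale else NA_real_,
      noise_var = if (refit) model$kernel$noise_var else NA_real_)
    if (!is.null(config$stopping) && i > config$init_k) {
      hyper <- do.call(rbind, trace)
      hyper <- hyper[!is.na(hyper$amplitude),
                     c("amplitude", "length_scale", "noise_var")]
      if (stopping_check(hyper, config$stopping$window,
                         config$stopping$tolerance)) {
        stopped <- TRUE
        break
      }
    }
  }
  finalize_search(trials, model, trace, config, stopped, aborted = FALSE,
                  hotspot = hotspot)
}

finalize_search <- function(trials, model, trace, config, stopped, aborted,
                            hotspot = TRUE) {
  hot <- if (hotspot && !is.null(model)) estimate_hotspot(model, config$space)
  structure(list(trials = trials, model = model, hotspot_estimate = hot,
                 trace = do.call(rbind, trace), stopped_early = stopped,
                 aborted = aborted, config = config),
            class = "hotspot_search")
}

#' @export
print.hotspot_search <- function(x, ...) {
  cat(sprintf("Hotspot search: %d stimuli (%d init), acquisition '%s'%s\n",
              nrow(x$trials), sum(x$trials$is_init),
              x$config$acquisition$name,
              if (x$stopped_early) ", stopped early" else ""))
  if (!is.null(x$hotspot_estimate))
    cat(sprintf("  estimated hotspot: x = %.1f mm, y = %.1f mm, theta = %.0f deg\n",
                x$hotspot_estimate$x, x$hotspot_estimate$y,
                x$hotspot_estimate$theta))
  invisible(x)
}

#' Estimate the motor hotspot from a fitted model
#'
#' Returns the argmax of the plug-in predicted response map (see
#' [predicted_response()]) over a dense grid (1 mm spatial, 5 degree
#' angular), refined by a local continuous polish.
#' On a flat (prior-only) surface the tie-break is the grid origin: grid
#' points are ordered by distance from the centre, then angle.
#'
#' @param model A fitted `"warped_gp"`.
#' @param space A [search_space()].
#' @return One-row data frame (`x`, `y`, `theta`).
#' @export
estimate_hotspot <- function(model, space) {
  grid <- hotspot_grid(space)
  mu <- predicted_response(model, grid)
  start <- as.numeric(grid[which.max(mu), ])
  neg <- function(xyt) -max(posterior_raw(model, xyt)[["mu"]], 0)^2
  res <- tryCatch(stats::optim(start, neg, method = "Nelder-Mead",
                               control = list(maxit = 60)),
                  error = function(e) list(par = start, value = neg(start)))
  if (res$value > -max(mu)) res$par <- start   # polish must not lose ground
  project_to_space(res$par[1], res$par[2], res$par[3], space)
}

# Dense (1 mm, 5 degree) grid over the space, ordered centre-out so that the
# flat-surface argmax tie-break is the origin at the lowest angle.
hotspot_grid <- function(space, spacing = 1, angle_step = 5) {
  m <- floor(space$radius / spacing)
  xy <- expand.grid(x = spacing * (-m:m), y = spacing * (-m:m))
  xy <- xy[xy$x^2 + xy$y^2 <= space$radius^2, ]
  angles <- seq(space$theta_range[1], space$theta_range[2], by = angle_step)
  g <- merge(xy, data.frame(theta = angles))
  g <- g[order(g$x^2 + g$y^2, g$theta, g$x, g$y), ]
  rownames(g) <- NULL
  g
}

#' Hyperparameter-stagnation stopping criterion
#'
#' Fires when every kernel hyperparameter has a relative range below
#' `tolerance` over the last `window` refits. Returns `FALSE` when fewer
#' than `window` refits are available (insufficient evidence).
#'
#' @param trace_hyper Data frame with one row per refit and columns
#'   `amplitude`, `length_scale`, `noise_var`.
#' @param window Number of most recent refits to examine.
#' @param tolerance Maximum relative change regarded as stagnation.
#' @return Logical.
#' @export
stopping_check <- function(trace_hyper, window, tolerance) {
  if (is.null(trace_hyper) || nrow(trace_hyper) < window) return(FALSE)
  recent <- utils::tail(trace_hyper, window)
  rel <- vapply(c("amplitude", "length_scale", "noise_var"), function(col) {
    v <- recent[[col]]
    (max(v) - min(v)) / max(min(v), 1e-12)
  }, numeric(1))
  all(rel < tolerance)
}
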