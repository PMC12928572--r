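#' Configure a simulation benchmark
#'
#' A benchmark runs the closed-loop search for every combination of
#' synthetic subject, acquisition condition and random seed, and records
#' NRMSE and CoG distances at checkpoints along the way. Within one
#' (subject, seed) pair the k-means initialization points are generated
#' once and shared across all conditions with the same `init_k`, so
#' acquisition functions are compared from identical starting data.
#'
#' @param n_subjects Number of synthetic subjects in the ensemble.
#' @param n_seeds Random seeds per (subject, condition).
#' @param budget Total stimuli per run.
#' @param conditions List of conditions, each a list
#'   `(acquisition = <name>, init_k = <count>)`.
#' @param seed Global seed; subject and run seeds are derived from it.
#' @param space A [search_space()].
#' @param base_params Template [synthetic_subject_params()] for the
#'   ensemble.
#' @param checkpoint_every Metric checkpoint interval in stimuli (the final
#'   stimulus is always a checkpoint); use `budget` for final-only.
#' @param grid_spacing,grid_angle_step Test-grid resolution (mm, degrees).
#' @return An object of class `"benchmark_config"`.
#' @export
benchmark_config <- function(n_subjects = 4, n_seeds = 10, budget = 40,
                             conditions = list(
                               list(acquisition = "ts", init_k = 10),
                               list(acquisition = "random", init_k = 10)),
                             seed = 1, space = search_space(),
                             base_params = synthetic_subject_params(),
                             checkpoint_every = 5,
                             grid_spacing = 3, grid_angle_step = 20) {
  stopifnot(n_seeds >= 1, n_subjects >= 1)
  for (cn in conditions) {
    acquisition_spec(cn$acquisition)        # validates the name
    if (cn$init_k > budget) stop("condition init_k exceeds the budget")
  }
  structure(list(n_subjects = n_subjects, n_seeds = n_seeds, budget = budget,
                 conditions = conditions, seed = seed, space = space,
                 base_params = base_params,
                 checkpoint_every = checkpoint_every,
                 grid_spacing = grid_spacing,
                 grid_angle_step = grid_angle_step),
            class = "benchmark_config")
}

#' Run a simulation benchmark
#'
#' @param config A [benchmark_config()].
#' @param subjects Optional prebuilt list of `"gt_subject"` objects (e.g.
#'   reused across studies); defaults to [make_subject_ensemble()] under
#'   the config's seed and subject parameters.
#' @param verbose Print per-run progress to stderr.
#' @return An object of class `"hotspot_benchmark"`: `records` (one row
#'   per checkpoint of every run: subject, acquisition, init_k, seed,
#'   n_stimuli, nrmse, d_xy_mm, d_theta_deg), `failures`, `subjects`,
#'   `searches` (final search per run) and the `config`.
#' @export
run_benchmark <- function(config, subjects = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  if (is.null(subjects))
    subjects <- make_subject_ensemble(config$n_subjects, seed = config$seed,
                                      space = config$space,
                                      base_params = config$base_params)
  grid <- build_test_grid(config$space, config$grid_spacing,
                          config$grid_angle_step)
  checkpoints <- sort(unique(c(
    seq(config$checkpoint_every, config$budget,
        by = config$checkpoint_every), config$budget)))

  records <- list()
  failures <- list()
  searches <- list()
  init_ks <- unique(vapply(config$conditions, `[[`, numeric(1), "init_k"))
  for (i in seq_along(subjects)) {
    sub <- subjects[[i]]
    mu_gt <- predicted_response(sub$gt_model, grid)
    cog_gt <- cog_values(grid, mu_gt)
    for (j in seq_len(config$n_seeds)) {
      run_seed <- as.integer((config$seed + 7919 * i + 15331 * j) %%
                               2147483647)
      shared_init <- lapply(stats::setNames(init_ks[init_ks > 0],
                                            init_ks[init_ks > 0]),
                            function(k) kmeans_init(config$space, k,
                                                    seed = run_seed))
      for (cn in config$conditions) {
        tag <- sprintf("s%02d_%s_k%d_seed%d", i, cn$acquisition,
                       cn$init_k, j)
        if (verbose)
          message(sprintf("[run %s] run_seed = %d", tag, run_seed))
        cfg <- search_config(
          budget = config$budget, init_k = cn$init_k,
          acquisition = acquisition_spec(cn$acquisition),
          seed = run_seed, space = config$space,
          fit_opts = gp_fit_options(seed = run_seed),
          init_points = if (cn$init_k > 0)
            shared_init[[as.character(cn$init_k)]])
        res <- tryCatch(run_search(subject_oracle(sub), cfg,
                                   hotspot = FALSE),
                        error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <-
            list(run = tag, message = conditionMessage(res))
          next
        }
        searches[[tag]] <- res
        for (n_stim in checkpoints[checkpoints >= max(cn$init_k, 1)]) {
          m <- model_at_step(res, n_stim)
          if (is.null(m)) next
          mu_fit <- predicted_response(m, grid)
          cog_fit <- cog_values(grid, mu_fit)
          records[[length(records) + 1L]] <- data.frame(
            subject = i, af = cn$acquisition, init_k = cn$init_k,
            seed = j, n_stimuli = n_stim,
            nrmse = nrmse_values(mu_gt, mu_fit),
            d_xy_mm = sqrt(sum((cog_gt[c("x", "y")] -
                                  cog_fit[c("x", "y")])^2)),
            d_theta_deg = axial_angle_diff(cog_gt["theta"],
                                           cog_fit["theta"]))
        }
      }
    }
  }
  structure(list(records = do.call(rbind, records), failures = failures,
                 subjects = subjects, searches = searches, config = config),
            class = "hotspot_benchmark")
}

# Reconstruct the fitted model after n_stim stimuli of a finished search
# from its trace (trials so far + the hyperparameters refitted at that
# step). NULL when no refit had happened yet.
model_at_step <- function(search, n_stim) {
  tr <- search$trace
  if (is.null(tr) || n_stim > nrow(tr)) return(NULL)
  row <- tr[n_stim, ]
  if (is.na(row$amplitude)) return(NULL)
  make_gp(search$trials[seq_len(n_stim), ],
          kernel_params(row$amplitude, row$length_scale, row$noise_var),
          search$config$space)
}

#' @export
print.hotspot_benchmark <- function(x, ...) {
  cat(sprintf("Hotspot benchmark: %d records, %d failures\n",
              if (is.null(x$records)) 0L else nrow(x$records),
              length(x$failures)))
  invisible(x)
}

#' Summarize benchmark records
#'
#' Per (acquisition, init_k, n_stimuli): mean, median, SD and twice the
#' standard error of the mean of each metric; plus quartiles of the
#' final-checkpoint distributions.
#'
#' @param result A `"hotspot_benchmark"` (or its `records` data frame).
#' @return List with data frames `by_checkpoint` and `final`.
#' @export
summarize_benchmark <- function(result) {
  records <- if (inherits(result, "hotspot_benchmark")) result$records
             else result
  if (is.null(records) || nrow(records) == 0L) stop("no benchmark records")
  metrics <- c("nrmse", "d_xy_mm", "d_theta_deg")
  key <- interaction(records$af, records$init_k, records$n_stimuli,
                     drop = TRUE)
  by_checkpoint <- do.call(rbind, lapply(split(records, key), function(d) {
    out <- data.frame(af = d$af[1], init_k = d$init_k[1],
                      n_stimuli = d$n_stimuli[1], n_runs = nrow(d))
    for (m in metrics) {
      v <- d[[m]]
      out[[paste0(m, "_mean")]] <- mean(v)
      out[[paste0(m, "_median")]] <- stats::median(v)
      out[[paste0(m, "_sd")]] <- stats::sd(v)
      out[[paste0(m, "_sem2")]] <- if (nrow(d) > 1)
        2 * stats::sd(v) / sqrt(nrow(d)) else 0
    }
    out
  }))
  by_checkpoint <- by_checkpoint[order(by_checkpoint$af,
                                       by_checkpoint$init_k,
                                       by_checkpoint$n_stimuli), ]
  rownames(by_checkpoint) <- NULL
  fin <- records[records$n_stimuli == max(records$n_stimuli), ]
  final <- do.call(rbind, lapply(
    split(fin, interaction(fin$af, fin$init_k, drop = TRUE)), function(d) {
      out <- data.frame(af = d$af[1], init_k = d$init_k[1], n_runs = nrow(d))
      for (m in metrics) {
        q <- stats::quantile(d[[m]], c(0.25, 0.5, 0.75), names = FALSE)
        out[[paste0(m, "_q25")]] <- q[1]
        out[[paste0(m, "_median")]] <- q[2]
        out[[paste0(m, "_q75")]] <- q[3]
      }
      out
    }))
  rownames(final) <- NULL
  list(by_checkpoint = by_checkpoint, final = final)
}

#' Export a Fig-3-style sampling trace
#'
#' Writes a CSV with one row per stimulus (step, x, y, theta, response,
#' is_init) plus one row for the ground-truth hotspot and one for the
#' estimated hotspot, sufficient to re-draw quiver plots of the sampling
#' pattern.
#'
#' @param search A `"hotspot_search"` result.
#' @param subject The `"gt_subject"` the search ran against.
#' @param path Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
export_sampling_trace <- function(search, subject, path) {
  tr <- search$trace
  rows <- data.frame(kind = "stimulus", step = tr$step, x = tr$x, y = tr$y,
                     theta = tr$theta, response = tr$response,
                     is_init = tr$is_init)
  hs <- rbind(
    data.frame(kind = "gt_hotspot", step = NA, x = subject$gt_hotspot$x,
               y = subject$gt_hotspot$y, theta = subject$gt_hotspot$theta,
               response = NA, is_init = NA),
    data.frame(kind = "estimated_hotspot", step = NA,
               x = search$hotspot_estimate$x, y = search$hotspot_estimate$y,
               theta = search$hotspot_estimate$theta, response = NA,
               is_init = NA))
  out <- rbind(rows, hs)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
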