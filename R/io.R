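#' Read a trial log CSV
#'
#' Trial logs use the schema `x_mm,y_mm,theta_deg,mep`: one row per
#' stimulus, UTF-8, '.' decimal separator.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `x`, `y`, `theta`, `response`.
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("x_mm", "y_mm", "theta_deg", "mep")
  if (!all(need %in% names(d)))
    stop("trial CSV must have header: ", paste(need, collapse = ","))
  out <- data.frame(x = d$x_mm, y = d$y_mm, theta = d$theta_deg,
                    response = d$mep)
  if (any(out$response < 0)) stop("trial CSV contains negative MEP amplitudes")
  out
}

#' Write a trial log CSV
#'
#' @param trials Data frame with columns `x`, `y`, `theta`, `response`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(
    data.frame(x_mm = trials$x, y_mm = trials$y, theta_deg = trials$theta,
               mep = trials$response),
    path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a search result
#'
#' Writes the trial log as CSV and the per-step trace (proposals,
#' acquisition name, beta_n, refitted hyperparameters, seed) as JSON.
#'
#' @param search A `"hotspot_search"` result.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_search_result <- function(search, csv_path, json_path) {
  write_trials(search$trials, csv_path)
  payload <- list(
    seed = search$config$seed,
    acquisition = search$config$acquisition$name,
    budget = search$config$budget,
    init_k = search$config$init_k,
    stopped_early = search$stopped_early,
    hotspot_estimate = as.list(search$hotspot_estimate),
    trace = search$trace)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(c(csv_path, json_path))
}

#' Serialize a subject ensemble
#'
#' Writes one trial CSV per subject plus a JSON manifest holding the
#' generating parameters, seeds, fitted ground-truth hyperparameters and
#' hotspots.
#'
#' @param subjects List of `"gt_subject"` objects.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_subject_ensemble <- function(subjects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    csv <- file.path(dir, sprintf("subject_%02d_trials.csv", i))
    write_trials(s$trials, csv)
    list(subject = i, trials_csv = basename(csv), seed = s$seed,
         params = if (is.null(s$params)) NULL else unclass(s$params),
         gt_kernel = unclass(s$gt_model$kernel)[c("amplitude", "length_scale",
                                                  "noise_var")],
         gt_hotspot = as.list(s$gt_hotspot))
  })
  path <- file.path(dir, "ensemble_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a benchmark configuration file
#'
#' YAML with optional keys `n_subjects`, `budget`, `init_k`, `n_seeds`,
#' `seed`, `radius`, `conditions` (list of `{acquisition, init_k}`), and a
#' `subject` block overriding [synthetic_subject_params()] fields. Missing
#' keys fall back to [benchmark_config()] defaults.
#'
#' @param path Path to a YAML config file.
#' @return A [benchmark_config()] object.
#' @export
read_benchmark_config <- function(path) {
  y <- yaml::read_yaml(path)
  sp <- do.call(synthetic_subject_params,
                y$subject %||% list())
  space <- search_space(radius = y$radius %||% 28.5)
  conds <- y$conditions %||% list(list(acquisition = "ts", init_k = 10))
  conds <- lapply(conds, function(cn)
    list(acquisition = cn$acquisition, init_k = cn$init_k %||% 10))
  benchmark_config(
    n_subjects = y$n_subjects %||% 4,
    n_seeds = y$n_seeds %||% 10,
    budget = y$budget %||% 40,
    conditions = conds,
    seed = y$seed %||% 1,
    space = space,
    base_params = sp,
    checkpoint_every = y$checkpoint_every %||% 5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
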