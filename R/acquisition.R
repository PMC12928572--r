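#' Specify an acquisition function for the closed-loop search
#'
#' @param name One of `"ucb"`, `"ei"`, `"ts"`, `"kg"`, `"mve"`, `"random"`
#'   (case-insensitive). `"random"` is the uniform-sampling baseline.
#' @param beta0 UCB exploration weight at step 0; the schedule is
#'   beta_n = beta0 * exp(-n / tau), decaying towards pure exploitation.
#' @param tau UCB decay constant in steps; `NULL` resolves to budget / 3
#'   when the search config is known.
#' @param mc_budget Monte-Carlo fantasy-draw count for the knowledge
#'   gradient (also the draw budget for entropy estimates); must be >= 100.
#' @param candidate_count Size of the quasi-uniform candidate set used by
#'   the set-based functions (TS, KG, MVE) and as the inner discretization
#'   for KG/MVE; must be >= 50.
#' @param mve_max_samples Number of posterior max-value samples used by
#'   max-value entropy search.
#' @param seed Optional integer seed for the function's internal draws;
#'   `NULL` uses the ambient RNG stream (the closed loop seeds that stream).
#' @return An object of class `"acquisition_spec"`.
#' @export
acquisition_spec <- function(name, beta0 = 4, tau = NULL, mc_budget = 128,
                             candidate_count = 200, mve_max_samples = 32,
                             seed = NULL) {
  name <- tolower(name)
  allowed <- c("ucb", "ei", "ts", "kg", "mve", "random")
  if (!name %in% allowed)
    stop("unknown acquisition function '", name, "'; use one of: ",
         paste(allowed, collapse = ", "))
  if (name %in% c("kg", "mve") && mc_budget < 100)
    stop("mc_budget must be >= 100 for KG/MVE")
  if (candidate_count < 50) stop("candidate_count must be >= 50")
  structure(list(name = name, beta0 = beta0, tau = tau,
                 mc_budget = mc_budget, candidate_count = candidate_count,
                 mve_max_samples = mve_max_samples, seed = seed),
            class = "acquisition_spec")
}

#' Upper confidence bound
#'
#' UCB(s) = mu_z(s) + beta_n^(1/2) sigma_z(s) in warped space, with the
#' exploration weight decaying as beta_n = beta0 * exp(-n / tau).
#'
#' @param post Posterior summary from [gp_posterior()].
#' @param step_n Iteration index (number of proposals already made).
#' @param schedule List with elements `beta0` and `tau`.
#' @return UCB value per query point.
#' @export
ucb_value <- function(post, step_n, schedule = list(beta0 = 4, tau = 10)) {
  stopifnot(step_n >= 0)
  beta_n <- schedule$beta0 * exp(-step_n / schedule$tau)
  post$mean_warped + sqrt(beta_n) * sqrt(post$var_warped)
}

#' Expected improvement over the incumbent
#'
#' Closed-form EI in warped space:
#' (mu - r*) Phi(u) + sigma phi(u), u = (mu - r*) / sigma, reducing to
#' max(mu - r*, 0) where sigma = 0. The incumbent r* is the best *warped*
#' observed response.
#'
#' @param post Posterior summary from [gp_posterior()].
#' @param r_star Incumbent: the largest warped observed response.
#' @return EI value per query point.
#' @export
ei_value <- function(post, r_star) {
  stopifnot(is.finite(r_star))
  mu <- post$mean_warped
  sg <- sqrt(post$var_warped)
  out <- pmax(mu - r_star, 0)
  pos <- sg > 0
  if (any(pos)) {
    u <- (mu[pos] - r_star) / sg[pos]
    out[pos] <- (mu[pos] - r_star) * stats::pnorm(u) + sg[pos] * stats::dnorm(u)
  }
  out
}

#' Thompson sampling over a candidate set
#'
#' Draws one joint realization of the GP posterior over the candidates and
#' returns the index of its maximum (ties broken by lowest index).
#'
#' @param model A fitted `"warped_gp"`.
#' @param candidates Data frame of candidate points (`x`, `y`, `theta`).
#' @param seed Optional seed for the single joint draw.
#' @return Integer index of the selected candidate.
#' @export
thompson_select <- function(model, candidates, seed = NULL) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("Thompson sampling needs a nonempty candidate set")
  draw <- sample_posterior_functions(model, candidates, n_draws = 1,
                                     seed = seed)
  which.max(drop(draw))
}

# Inner discretization for KG/MVE: quasi-uniform space points plus the
# current training locations.
acq_discretization <- function(model, space, n_points) {
  disc <- sample_space(space, n_points, lhs = TRUE)
  if (!is.null(model$trials) && nrow(model$trials) > 0L)
    disc <- rbind(disc, model$trials[, c("x", "y", "theta")])
  disc
}

# Vectorized KG over a set of candidates, sharing the discretization and the
# standard-normal fantasy draws (common random numbers across candidates).
kg_values_impl <- function(model, candidates, disc, zdraws) {
  mu_n <- gp_posterior(model, disc)$mean_warped
  base_max <- max(mu_n)
  both <- rbind(disc, candidates)
  S <- posterior_cov(model, both)
  nd <- nrow(disc)
  vapply(seq_len(nrow(candidates)), function(j) {
    cj <- nd + j
    v_y <- max(S[cj, cj], 0) + model$kernel$noise_var
    if (v_y < 1e-12) return(0)
    b <- S[seq_len(nd), cj] / sqrt(v_y)
    # fantasy posterior means: mu_n + b * z for each draw
    mean(apply(outer(b, zdraws) + mu_n, 2, max)) - base_max
  }, numeric(1))
}

#' Knowledge gradient of a candidate stimulation point
#'
#' Monte-Carlo estimate of the expected increase in the maximum of the
#' posterior mean after observing the candidate (fantasy observations drawn
#' from the predictive distribution; inner maximization over a quasi-uniform
#' discretization of the space plus the training points).
#'
#' @param model A fitted `"warped_gp"`.
#' @param candidate One-row data frame (`x`, `y`, `theta`).
#' @param space A [search_space()].
#' @param mc_opts An [acquisition_spec()] supplying `mc_budget`,
#'   `candidate_count` (discretization size) and `seed`.
#' @param disc Optional explicit inner discretization (data frame `x`,
#'   `y`, `theta`); defaults to a seeded quasi-uniform set plus the
#'   training points.
#' @return Scalar KG estimate (nonnegative up to Monte-Carlo noise).
#' @export
kg_value <- function(model, candidate, space,
                     mc_opts = acquisition_spec("kg"), disc = NULL) {
  if (mc_opts$mc_budget < 100) stop("mc_budget must be >= 100 for KG")
  run <- function() {
    if (is.null(disc))
      disc <- acq_discretization(model, space, mc_opts$candidate_count)
    z <- stats::rnorm(mc_opts$mc_budget)
    kg_values_impl(model, candidate, disc, z)
  }
  if (is.null(mc_opts$seed)) run() else withr::with_seed(mc_opts$seed, run())
}

# MES over candidates given f* samples: per-sample truncated-Gaussian
# entropy reduction, averaged. gamma = (f* - mu) / sigma.
mve_values_impl <- function(post, fstar) {
  sg <- sqrt(post$var_warped)
  vapply(seq_along(post$mean_warped), function(i) {
    if (sg[i] < 1e-9) return(0)
    g <- pmax((fstar - post$mean_warped[i]) / sg[i], -5)
    Phi <- stats::pnorm(g)
    mean(g * stats::dnorm(g) / (2 * Phi) - log(Phi))
  }, numeric(1))
}

#' Max-value entropy search value of a candidate
#'
#' MES approximates the expected reduction in entropy of the global maximum
#' f*. Samples of f* are obtained as maxima of joint posterior draws over a
#' quasi-uniform discretization; the conditional entropy term uses the
#' truncated-Gaussian closed form, so the value per f* sample is
#' gamma phi(gamma) / (2 Phi(gamma)) - log Phi(gamma) with
#' gamma = (f* - mu(s)) / sigma(s).
#'
#' @inheritParams kg_value
#' @return Scalar MES estimate (nonnegative up to sampling noise).
#' @export
mve_value <- function(model, candidate, space,
                      mc_opts = acquisition_spec("mve"), disc = NULL) {
  if (mc_opts$mc_budget < 100) stop("mc_budget must be >= 100 for MVE")
  run <- function() {
    if (is.null(disc))
      disc <- acq_discretization(model, space, mc_opts$candidate_count)
    draws <- sample_posterior_functions(model, disc,
                                        n_draws = mc_opts$mve_max_samples)
    fstar <- apply(draws, 1, max)
    mve_values_impl(gp_posterior(model, candidate), fstar)
  }
  if (is.null(mc_opts$seed)) run() else withr::with_seed(mc_opts$seed, run())
}

# Fast warped-posterior evaluation at one raw (x, y, theta) point: the
# same projection + Eq-style posterior as gp_posterior, but without
# data-frame plumbing. The continuous acquisition maximization calls this
# thousands of times per proposal.
posterior_raw <- function(model, xyt) {
  sp <- model$space
  r <- sqrt(xyt[1]^2 + xyt[2]^2)
  if (r > sp$radius) xyt[1:2] <- xyt[1:2] * sp$radius / r
  th <- min(max(xyt[3], sp$theta_range[1]), sp$theta_range[2])
  q <- c(xyt[1] / sp$radius, xyt[2] / sp$radius,
         (th - sp$theta_range[1]) / diff(sp$theta_range))
  a <- model$kernel$amplitude
  if (is.null(model$Xn)) return(c(mu = 0, var = a))
  d2 <- (model$Xn[, 1] - q[1])^2 + (model$Xn[, 2] - q[2])^2 +
    (model$Xn[, 3] - q[3])^2
  ks <- a * exp(-d2 / (2 * model$kernel$length_scale^2))
  V <- backsolve(model$chol, ks, transpose = TRUE)
  c(mu = sum(ks * model$alpha), var = min(max(a - sum(V^2), 0), a))
}

#' Propose the next stimulation parameters
#'
#' Maximizes the configured acquisition surface over the search space.
#' UCB/EI use multi-start bounded continuous maximization (16 seeded
#' starts); TS selects the argmax of one posterior draw over a seeded
#' quasi-uniform candidate set; KG/MVE score the candidate set and polish
#' the best candidate with one local simplex refinement; RANDOM draws
#' uniformly. The returned point always lies inside the space.
#'
#' @param model A fitted `"warped_gp"` (ignored for `"random"`).
#' @param spec An [acquisition_spec()].
#' @param space A [search_space()].
#' @param step_n Iteration index used by the UCB schedule.
#' @param seed Optional seed; `NULL` uses the ambient RNG stream.
#' @return One-row data frame (`x`, `y`, `theta`).
#' @export
propose_next <- function(model, spec, space, step_n = 0, seed = NULL) {
  run <- function() propose_next_impl(model, spec, space, step_n)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  assert_in_space(out, space)
  out
}

propose_next_impl <- function(model, spec, space, step_n) {
  tau <- if (is.null(spec$tau)) 10 else spec$tau
  if (spec$name == "random") {
    return(sample_space(space, 1, lhs = FALSE))
  }
  if (spec$name %in% c("ucb", "ei")) {
    acq <- if (spec$name == "ucb") {
      beta_n <- spec$beta0 * exp(-step_n / tau)
      function(p) p[["mu"]] + sqrt(beta_n) * sqrt(p[["var"]])
    } else {
      r_star <- max(c(-Inf, sqrt(model$trials$response)))
      function(p) {
        sg <- sqrt(p[["var"]])
        if (sg <= 0) return(max(p[["mu"]] - r_star, 0))
        u <- (p[["mu"]] - r_star) / sg
        (p[["mu"]] - r_star) * stats::pnorm(u) + sg * stats::dnorm(u)
      }
    }
    neg <- function(xyt) -acq(posterior_raw(model, xyt))
    starts <- sample_space(space, 16, lhs = TRUE)
    lower <- c(-space$radius, -space$radius, space$theta_range[1])
    upper <- c(space$radius, space$radius, space$theta_range[2])
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      res <- tryCatch(
        stats::optim(as.numeric(starts[i, ]), neg, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 40)),
        error = function(e) list(par = as.numeric(starts[i, ]),
                                 value = neg(as.numeric(starts[i, ]))))
      if (is.null(best) || res$value < best$value) best <- res
    }
    return(project_to_space(best$par[1], best$par[2], best$par[3], space))
  }

  candidates <- sample_space(space, spec$candidate_count, lhs = TRUE)
  if (spec$name == "ts") {
    idx <- thompson_select(model, candidates)
    return(candidates[idx, , drop = FALSE])
  }

  # KG / MVE: score the candidate set, then one local polish
  disc <- acq_discretization(model, space, spec$candidate_count)
  if (spec$name == "kg") {
    z <- stats::rnorm(spec$mc_budget)
    vals <- kg_values_impl(model, candidates, disc, z)
    score1 <- function(xyt) {
      s <- project_to_space(xyt[1], xyt[2], xyt[3], space)
      -kg_values_impl(model, s, disc, z)
    }
  } else {
    draws <- sample_posterior_functions(model, disc,
                                        n_draws = spec$mve_max_samples)
    fstar <- apply(draws, 1, max)
    vals <- mve_values_impl(gp_posterior(model, candidates), fstar)
    score1 <- function(xyt) {
      s <- project_to_space(xyt[1], xyt[2], xyt[3], space)
      -mve_values_impl(gp_posterior(model, s), fstar)
    }
  }
  start <- as.numeric(candidates[which.max(vals), ])
  res <- tryCatch(
    stats::optim(start, score1, method = "Nelder-Mead",
                 control = list(maxit = 25)),
    error = function(e) list(par = start))
  project_to_space(res$par[1], res$par[2], res$par[3], space)
}
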