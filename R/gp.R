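#' Construct a warped GP model from trials and fixed hyperparameters
#'
#' Builds the model state for a square-root-warped Gaussian process over
#' stimulation parameters: the warped responses z = sqrt(r), the normalized
#' training coordinates, and the Cholesky factorization of
#' K(S, S) + sigma_eps^2 I used by all posterior computations. The prior
#' mean in warped space is zero; responses are not centred.
#'
#' Use [fit_gp()] to choose the hyperparameters by maximum likelihood;
#' `make_gp()` is the low-level constructor (it also accepts zero trials,
#' in which case the posterior equals the prior).
#'
#' @param trials Data frame with columns `x`, `y`, `theta`, `response`
#'   (response >= 0), or `NULL` for a prior-only model.
#' @param kernel A [kernel_params()] object.
#' @param space A [search_space()].
#' @return An object of class `"warped_gp"`.
#' @export
make_gp <- function(trials, kernel, space) {
  stopifnot(inherits(kernel, "kernel_params"), inherits(space, "search_space"))
  if (is.null(trials) || nrow(trials) == 0L) {
    return(structure(list(trials = trials, kernel = kernel, space = space,
                          Xn = NULL, z = numeric(0), chol = NULL,
                          alpha = NULL, jitter = 0),
                     class = "warped_gp"))
  }
  stopifnot(all(c("x", "y", "theta", "response") %in% names(trials)))
  z <- warp_response(trials$response)
  Xn <- normalize_coords(trials, space)
  Ky <- rbf_kernel_matrix(Xn, Xn, kernel) + diag(kernel$noise_var, nrow(Xn))
  cj <- chol_jitter(Ky)
  alpha <- backsolve(cj$L, backsolve(cj$L, z, transpose = TRUE))
  structure(list(trials = trials, kernel = kernel, space = space,
                 Xn = Xn, z = z, chol = cj$L, alpha = alpha,
                 jitter = cj$jitter),
            class = "warped_gp")
}

#' @export
print.warped_gp <- function(x, ...) {
  cat(sprintf("Warped GP (sqrt warp): %d trials\n",
              if (is.null(x$trials)) 0L else nrow(x$trials)))
  print(x$kernel)
  invisible(x)
}

#' Log marginal likelihood of the warped responses
#'
#' Gaussian log marginal likelihood of z = sqrt(r) under the zero-mean GP
#' prior with RBF kernel and observation noise `kernel$noise_var`:
#' -1/2 z' (K + s2 I)^-1 z - 1/2 log|K + s2 I| - n/2 log(2 pi).
#'
#' @param kernel A [kernel_params()] object.
#' @param trials Data frame of trials (at least one row).
#' @param space A [search_space()] used for coordinate normalization.
#' @return The scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(kernel, trials, space) {
  if (is.null(trials) || nrow(trials) == 0L) stop("need at least one trial")
  m <- make_gp(trials, kernel, space)
  n <- length(m$z)
  -0.5 * sum(m$z * m$alpha) - sum(log(diag(m$chol))) - 0.5 * n * log(2 * pi)
}

# Negative LML and its gradient w.r.t. log(a), log(l), log(s2), sharing the
# precomputed squared-distance matrix D2. Used by the L-BFGS-B fit.
nll_with_grad <- function(logp, D2, z) {
  a <- exp(logp[1]); l <- exp(logp[2]); s2 <- exp(logp[3])
  n <- length(z)
  C <- exp(-D2 / (2 * l^2))
  Kf <- a * C
  Ky <- Kf + diag(s2, n)
  cj <- tryCatch(chol_jitter(Ky), error = function(e) NULL)
  if (is.null(cj)) return(list(value = 1e10, grad = c(0, 0, 0)))
  U <- cj$L
  alpha <- backsolve(U, backsolve(U, z, transpose = TRUE))
  nll <- 0.5 * sum(z * alpha) + sum(log(diag(U))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(U)
  A <- tcrossprod(alpha) - Kinv            # dL/dK = A/2
  g_loga <- 0.5 * sum(A * Kf)
  g_logl <- 0.5 * sum(A * (Kf * D2 / l^2))
  g_logs2 <- 0.5 * s2 * sum(diag(A))
  list(value = nll, grad = -c(g_loga, g_logl, g_logs2))
}

#' Options controlling maximum-likelihood GP fitting
#'
#' @param n_starts Number of restarts of the bounded L-BFGS optimizer; start
#'   points are drawn log-uniformly inside the bounds.
#' @param seed Integer seed making the restart draws (and hence the fit)
#'   deterministic.
#' @param bounds Named list of length-2 ranges for `amplitude`,
#'   `length_scale` (normalized units) and `noise_var`.
#' @param maxit Iteration cap per optimizer start.
#' @return A list of class `"gp_fit_options"`.
#' @export
gp_fit_options <- function(n_starts = 8, seed = 1,
                           bounds = list(amplitude = c(1e-4, 1e4),
                                         length_scale = c(0.01, 3),
                                         noise_var = c(1e-6, 1e2)),
                           maxit = 60) {
  structure(list(n_starts = n_starts, seed = seed, bounds = bounds,
                 maxit = maxit),
            class = "gp_fit_options")
}

#' Fit the warped GP by maximum marginal likelihood
#'
#' Hyperparameters (a, l, sigma_eps^2) are chosen by maximizing the log
#' marginal likelihood of the warped responses with a multi-start bounded
#' quasi-Newton optimizer (analytic gradients); the best of all starts is
#' kept. Deterministic given `opts$seed`.
#'
#' @param trials Data frame of trials (>= 1 row).
#' @param space A [search_space()].
#' @param opts A [gp_fit_options()] object.
#' @param init Optional [kernel_params()] used as an additional warm start
#'   (e.g. the previous step's fit in the closed loop).
#' @return A fitted `"warped_gp"` model (see [make_gp()]).
#' @export
fit_gp <- function(trials, space, opts = gp_fit_options(), init = NULL) {
  if (is.null(trials) || nrow(trials) == 0L) stop("need at least one trial")
  z <- warp_response(trials$response)
  Xn <- normalize_coords(trials, space)
  D2 <- sq_dist(Xn, Xn)
  b <- opts$bounds
  lower <- log(c(b$amplitude[1], b$length_scale[1], b$noise_var[1]))
  upper <- log(c(b$amplitude[2], b$length_scale[2], b$noise_var[2]))

  starts <- withr::with_seed(opts$seed, {
    matrix(stats::runif(3 * opts$n_starts, rep(lower, each = opts$n_starts),
                        rep(upper, each = opts$n_starts)),
           ncol = 3)
  })
  if (!is.null(init)) {
    w <- log(c(init$amplitude, init$length_scale, init$noise_var))
    starts <- rbind(starts, pmin(pmax(w, lower), upper))
  }

  # optim calls fn and gr separately at the same point; cache the last
  # evaluation so value and gradient are computed once
  last <- list(p = NULL, res = NULL)
  eval_at <- function(p) {
    if (is.null(last$p) || !identical(p, last$p))
      last <<- list(p = p, res = nll_with_grad(p, D2, z))
    last$res
  }
  fn <- function(p) eval_at(p)$value
  gr <- function(p) eval_at(p)$grad
  best <- NULL
  n_fail <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], fn, gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = opts$maxit)),
      error = function(e) NULL)
    if (is.null(res)) {
      n_fail <- n_fail + 1L
      res <- list(par = starts[i, ], value = fn(starts[i, ]))
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (n_fail == nrow(starts))
    warning("GP hyperparameter optimizer failed to converge from every ",
            "start; using the best evaluated candidate")
  p <- exp(best$par)
  make_gp(trials, kernel_params(p[1], p[2], p[3]), space)
}

#' Posterior of the warped GP at query points
#'
#' Computes the warped-space posterior mean and variance at each query point
#' using the cached Cholesky factorization, and the implied expected
#' response E\[r\] = mu_z^2 + var_z. The variance is clamped to
#' \[0, amplitude\]. For a model without trials the prior (mean 0, variance
#' a) is returned.
#'
#' @param model A `"warped_gp"` model.
#' @param points Data frame with columns `x`, `y`, `theta`.
#' @return A data frame: the query coordinates plus `mean_warped`,
#'   `var_warped`, `mean_response`.
#' @export
gp_posterior <- function(model, points) {
  stopifnot(inherits(model, "warped_gp"))
  Xq <- normalize_coords(points, model$space)
  a <- model$kernel$amplitude
  if (is.null(model$Xn)) {
    mu <- rep(0, nrow(Xq)); v <- rep(a, nrow(Xq))
  } else {
    Ks <- rbf_kernel_matrix(model$Xn, Xq, model$kernel)   # n x m
    mu <- drop(crossprod(Ks, model$alpha))
    V <- backsolve(model$chol, Ks, transpose = TRUE)
    v <- a - colSums(V^2)
    v[v < 0 & v > -1e-10] <- 0
    v <- pmin(pmax(v, 0), a)
  }
  cbind(points[, c("x", "y", "theta")],
        data.frame(mean_warped = mu, var_warped = v,
                   mean_response = unwarp_mean_var(mu, v)))
}

#' @export
predict.warped_gp <- function(object, newdata, ...) gp_posterior(object, newdata)

#' Plug-in predicted response map
#'
#' The point prediction of the warped GP in response units:
#' max(mu_z, 0)^2. The warped posterior mean is clipped at zero before
#' squaring because a negative predicted square-root amplitude means a
#' predicted response of zero; squaring an (extrapolation-induced)
#' negative undershoot would otherwise invent response mass in unsampled
#' regions. This is the map used for hotspot estimation and map
#' comparison; `mean_response` (mu_z^2 + var_z) is the full posterior
#' expectation instead.
#'
#' @param model A `"warped_gp"` model.
#' @param points Data frame with columns `x`, `y`, `theta`.
#' @return Numeric vector of predicted amplitudes.
#' @export
predicted_response <- function(model, points) {
  pmax(gp_posterior(model, points)$mean_warped, 0)^2
}

# Full posterior covariance over query points (warped space), no noise term.
posterior_cov <- function(model, points) {
  Xq <- normalize_coords(points, model$space)
  Kss <- rbf_kernel_matrix(Xq, Xq, model$kernel)
  if (is.null(model$Xn)) return(Kss)
  Ks <- rbf_kernel_matrix(model$Xn, Xq, model$kernel)
  V <- backsolve(model$chol, Ks, transpose = TRUE)
  Kss - crossprod(V)
}

#' Joint samples from the GP posterior over a point set
#'
#' Draws `n_draws` joint realizations of the latent warped function over the
#' query points from the multivariate Gaussian posterior. Reproducible for a
#' given `seed`.
#'
#' @param model A `"warped_gp"` model.
#' @param points Data frame with columns `x`, `y`, `theta`.
#' @param n_draws Number of joint draws.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A `n_draws` x `nrow(points)` matrix of sampled warped values.
#' @export
sample_posterior_functions <- function(model, points, n_draws, seed = NULL) {
  post <- gp_posterior(model, points)
  S <- posterior_cov(model, points)
  m <- nrow(points)
  if (max(diag(S)) < 1e-14) {               # degenerate: all mass at the mean
    return(matrix(post$mean_warped, nrow = n_draws, ncol = m, byrow = TRUE))
  }
  cj <- chol_jitter(S, ladder = c(1e-10, 1e-8, 1e-6))
  draw <- function() {
    Z <- matrix(stats::rnorm(n_draws * m), nrow = n_draws)
    sweep(Z %*% cj$L, 2, post$mean_warped, "+")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
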