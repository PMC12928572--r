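# Shared fixtures, built in code. Heavy objects are memoized so several
# test files can reuse them within one test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Noiseless Gaussian-bump response field with a known peak.
bump_response <- function(s, peak = c(5, -3, 90), A = 1,
                          ls = 8, lth = 35, rho = 0.7) {
  d2 <- (s$x - peak[1])^2 + (s$y - peak[2])^2
  dth <- pmin(abs(s$theta - peak[3]) %% 180, 180 - abs(s$theta - peak[3]) %% 180)
  A * exp(-d2 / (2 * ls^2)) *
    ((1 - rho) + rho * exp(-dth^2 / (2 * lth^2)))
}

# Small deterministic trial set over the default space.
bump_trials <- function(n = 25, seed = 11, noise_sd = 0, ...) {
  sp <- search_space()
  withr::with_seed(seed, {
    s <- tmshotspot:::sample_space(sp, n)
    r <- pmax(0, bump_response(s, ...) + stats::rnorm(n, 0, noise_sd))
    cbind(s, response = r)
  })
}

# A modest fitted model on bump data, reused by acquisition tests.
bump_model <- function() {
  memo("bump_model", function() {
    fit_gp(bump_trials(30, seed = 11, noise_sd = 0.02), search_space(),
           gp_fit_options(seed = 5))
  })
}

# The default 8-subject synthetic ensemble (seed 1), shared by the
# ratio-study and benchmark tests.
default_ensemble <- function() {
  memo("ensemble8", function() make_subject_ensemble(8, seed = 1))
}

# Literal dense evaluation of the posterior mean/variance equations,
# independent of the package's cached-Cholesky path.
dense_posterior <- function(trials, kernel, space, query) {
  Xn <- normalize_coords(trials, space)
  Qn <- normalize_coords(query, space)
  z <- sqrt(trials$response)
  K <- rbf_kernel_matrix(Xn, Xn, kernel) + diag(kernel$noise_var, nrow(Xn))
  Ks <- rbf_kernel_matrix(Qn, Xn, kernel)           # m x n
  Ki <- solve(K)
  mu <- drop(Ks %*% Ki %*% z)
  v <- kernel$amplitude - rowSums((Ks %*% Ki) * Ks)
  list(mean = mu, var = v)
}
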