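sp <- search_space()

test_that("log marginal likelihood matches direct dense evaluation", {
  # single trial, z = 0, unit amplitude, no noise: standard normal at 0
  t1 <- data.frame(x = 0, y = 0, theta = 90, response = 0)
  expect_equal(log_marginal_likelihood(kernel_params(1, 0.5, 0), t1, sp),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  # explicit-determinant oracle on a 3-point set
  tr <- bump_trials(3, seed = 2)
  k <- kernel_params(0.8, 0.4, 0.05)
  Xn <- normalize_coords(tr, sp)
  z <- sqrt(tr$response)
  Ky <- rbf_kernel_matrix(Xn, Xn, k) + diag(0.05, 3)
  direct <- -0.5 * drop(t(z) %*% solve(Ky) %*% z) -
    0.5 * log(det(Ky)) - 1.5 * log(2 * pi)
  expect_equal(log_marginal_likelihood(k, tr, sp), direct, tolerance = 1e-10)

  # duplicating a trial stays finite when noise regularizes the system
  tr2 <- rbind(tr, tr[1, ])
  ll <- log_marginal_likelihood(k, tr2, sp)
  expect_true(is.finite(ll))
})

test_that("posterior matches the literal dense equations", {
  tr <- bump_trials(5, seed = 3)
  k <- kernel_params(0.5, 0.45, 0.02)
  m <- make_gp(tr, k, sp)
  q <- bump_trials(7, seed = 4)[, c("x", "y", "theta")]
  post <- gp_posterior(m, q)
  oracle <- dense_posterior(tr, k, sp, q)
  expect_lt(max(abs(post$mean_warped - oracle$mean)), 1e-8)
  expect_lt(max(abs(post$var_warped - oracle$var)), 1e-8)
})

test_that("posterior degenerates correctly with no data and at noiseless
          training points", {
  k <- kernel_params(0.7, 0.5, 0.01)
  prior <- gp_posterior(make_gp(NULL, k, sp),
                        stimulation_params(c(0, 5), c(0, -2), c(45, 120)))
  expect_equal(prior$mean_warped, c(0, 0))
  expect_equal(prior$var_warped, c(0.7, 0.7))

  tr <- bump_trials(4, seed = 5)
  m0 <- make_gp(tr, kernel_params(0.7, 0.5, 0), sp)
  at_train <- gp_posterior(m0, tr)
  expect_equal(at_train$mean_warped, sqrt(tr$response), tolerance = 1e-5)
  expect_true(all(at_train$var_warped < 1e-5))
})

test_that("posterior variance is bounded by the prior amplitude and shrinks
          with data", {
  probe <- bump_trials(40, seed = 6)[, c("x", "y", "theta")]
  k <- kernel_params(0.6, 0.4, 0.05)
  for (seed in 1:5) {
    tr <- bump_trials(15, seed = seed, noise_sd = 0.05)
    prev <- rep(Inf, nrow(probe))
    for (n in c(1, 3, 6, 10, 15)) {
      v <- gp_posterior(make_gp(tr[1:n, ], k, sp), probe)$var_warped
      expect_true(all(v >= 0 & v <= k$amplitude + 1e-12))
      expect_lte(mean(v), mean(pmin(prev, k$amplitude)) + 1e-10)
      prev <- v
    }
    # adding a trial never raises variance at that trial's location
    v14 <- gp_posterior(make_gp(tr[1:14, ], k, sp), tr[15, ])$var_warped
    v15 <- gp_posterior(make_gp(tr, k, sp), tr[15, ])$var_warped
    expect_lte(v15, v14 + 1e-10)
  }
})

test_that("marginal-likelihood gradients agree with finite differences", {
  tr <- bump_trials(12, seed = 7, noise_sd = 0.05)
  Xn <- normalize_coords(tr, sp)
  D2 <- tmshotspot:::sq_dist(Xn, Xn)
  z <- sqrt(tr$response)
  p0 <- log(c(0.4, 0.5, 0.03))
  g <- tmshotspot:::nll_with_grad(p0, D2, z)$grad
  h <- 1e-6
  for (i in 1:3) {
    e <- replace(rep(0, 3), i, h)
    fd <- (tmshotspot:::nll_with_grad(p0 + e, D2, z)$value -
             tmshotspot:::nll_with_grad(p0 - e, D2, z)$value) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("maximum-likelihood fit recovers a known length scale", {
  # data generated from a GP with known hyperparameters
  k_true <- kernel_params(0.5, 0.35, 0.01)
  errs <- replicate(20, NA_real_)
  for (rep in 1:20) {
    tr <- withr::with_seed(100 + rep, {
      s <- tmshotspot:::sample_space(sp, 200)
      prior <- make_gp(NULL, k_true, sp)
      f <- drop(sample_posterior_functions(prior, s, 1))
      z <- f + rnorm(200, 0, sqrt(k_true$noise_var))
      cbind(s, response = z^2)
    })
    fit <- fit_gp(tr, sp, gp_fit_options(seed = rep))
    errs[rep] <- fit$kernel$length_scale / k_true$length_scale
  }
  med <- median(errs)
  expect_gt(med, 1 / 1.5)
  expect_lt(med, 1.5)
})

test_that("single-trial fit interpolates and distant trials stay local", {
  tr <- data.frame(x = 0, y = 0, theta = 90, response = 0.81)
  m <- make_gp(tr, kernel_params(0.5, 0.4, 1e-9), sp)
  expect_equal(gp_posterior(m, tr)$mean_warped, 0.9, tolerance = 1e-6)

  far <- data.frame(x = c(-25, 25), y = c(0, 0), theta = c(10, 170),
                    response = c(0.25, 1))
  mf <- make_gp(far, kernel_params(0.5, 0.05, 1e-9), sp)
  expect_equal(gp_posterior(mf, far)$mean_warped, c(0.5, 1),
               tolerance = 1e-6)
})

test_that("fit_gp is deterministic given its seed and errors on no data", {
  tr <- bump_trials(10, seed = 8, noise_sd = 0.05)
  f1 <- fit_gp(tr, sp, gp_fit_options(seed = 3))
  f2 <- fit_gp(tr, sp, gp_fit_options(seed = 3))
  expect_identical(f1$kernel, f2$kernel)
  expect_error(fit_gp(tr[0, ], sp), "at least one trial")
})

test_that("posterior sampling is seeded, degenerate at zero variance, and
          consistent with the posterior moments", {
  m <- bump_model()
  q <- bump_trials(4, seed = 9)[, c("x", "y", "theta")]
  d1 <- sample_posterior_functions(m, q, 5, seed = 21)
  d2 <- sample_posterior_functions(m, q, 5, seed = 21)
  expect_identical(d1, d2)

  # Monte-Carlo consistency: sample mean near posterior mean
  post <- gp_posterior(m, q)
  draws <- sample_posterior_functions(m, q, 1e5, seed = 22)
  se <- sqrt(post$var_warped / 1e5)
  expect_true(all(abs(colMeans(draws) - post$mean_warped) < 4 * se))

  # zero posterior variance everywhere: all draws equal the mean
  m0 <- make_gp(data.frame(x = 0, y = 0, theta = 90, response = 1),
                kernel_params(1e-15, 0.5, 0), sp)
  dd <- sample_posterior_functions(m0, q, 10, seed = 23)
  expect_equal(dd, matrix(gp_posterior(m0, q)$mean_warped, 10, 4,
                          byrow = TRUE))
})
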