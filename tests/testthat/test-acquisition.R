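sp <- search_space()

fake_post <- function(mu, var) data.frame(mean_warped = mu, var_warped = var)

test_that("UCB arithmetic and schedule behave as specified", {
  p <- fake_post(1, 4)
  # beta_n = 4 at step 0: mu + sqrt(4) * sigma = 1 + 2 * 2
  expect_equal(ucb_value(p, 0, list(beta0 = 4, tau = 10)), 5)
  # beta -> 0 reduces UCB to the posterior mean
  expect_equal(ucb_value(p, 1e6, list(beta0 = 4, tau = 10)), 1,
               tolerance = 1e-8)
  b <- sapply(0:20, function(n) ucb_value(fake_post(0, 1), n,
                                          list(beta0 = 2, tau = 10)))
  expect_true(all(diff(b) < 0))
})

test_that("EI closed form matches limits and its Monte-Carlo oracle", {
  expect_equal(ei_value(fake_post(0.2, 0), r_star = 0.5), 0)
  expect_equal(ei_value(fake_post(0.5, 1), r_star = 0.5), 1 / sqrt(2 * pi),
               tolerance = 1e-10)

  set.seed(31)
  z <- rnorm(1e6)
  for (i in 1:20) {
    mu <- runif(1, -1, 1); sg <- runif(1, 0.05, 1.5); rs <- runif(1, -1, 1)
    mc <- pmax(mu + sg * z - rs, 0)
    se <- sd(mc) / sqrt(length(z))
    # + 1e-12 floor: in the deep tail every draw is exactly zero (se = 0)
    # while the closed form is subnormal-positive
    expect_lt(abs(ei_value(fake_post(mu, sg^2), rs) - mean(mc)), 3 * se + 1e-12)
  }
})

test_that("Thompson sampling is seeded, picks dominant candidates, and
          matches brute-force joint-sampling frequencies", {
  m <- bump_model()
  cands <- stimulation_params(c(0, 5, -10), c(0, -3, 8), c(90, 90, 30))
  expect_identical(thompson_select(m, cands, seed = 4),
                   thompson_select(m, cands, seed = 4))
  expect_error(thompson_select(m, cands[0, ]), "nonempty")

  # a strongly dominant candidate is selected essentially always
  dom <- make_gp(data.frame(x = c(-20, 20), y = 0, theta = c(45, 135),
                            response = c(0.0001, 100)),
                 kernel_params(0.5, 0.05, 1e-6), sp)
  dd <- stimulation_params(c(-20, 20), c(0, 0), c(45, 135))
  picks <- vapply(1:50, function(s) thompson_select(dom, dd, seed = s),
                  integer(1))
  expect_true(mean(picks == 2) > 0.95)

  # exchangeable candidates: uniform selection frequencies
  prior <- make_gp(NULL, kernel_params(0.3, 0.02, 0), sp)
  ex <- stimulation_params(c(-20, 0, 20), c(0, 10, 0), c(20, 90, 160))
  counts <- tabulate(vapply(1:4000, function(s)
    thompson_select(prior, ex, seed = s), integer(1)), 3)
  expect_gt(chisq.test(counts)$p.value, 0.01)

  # non-exchangeable toy: frequencies match an independent dense
  # joint-sampling oracle
  toy <- make_gp(data.frame(x = c(0, 6), y = c(0, 0), theta = c(80, 100),
                            response = c(0.5, 0.9)),
                 kernel_params(0.4, 0.3, 0.05), sp)
  tc <- stimulation_params(c(0, 3, 6), c(0, 0, 0), c(80, 90, 100))
  counts <- tabulate(vapply(1:4000, function(s)
    thompson_select(toy, tc, seed = s), integer(1)), 3)
  post <- gp_posterior(toy, tc)
  S <- tmshotspot:::posterior_cov(toy, tc)
  oracle <- withr::with_seed(99, {
    dr <- MASS::mvrnorm(40000, post$mean_warped, S)
    tabulate(apply(dr, 1, which.max), 3) / 40000
  })
  expect_gt(chisq.test(counts, p = oracle)$p.value, 0.01)
})

test_that("knowledge gradient is nonnegative, vanishes for uninformative
          observations, and matches a Gauss-Hermite oracle", {
  skip_if_not_installed("pracma")
  m <- bump_model()
  cand <- stimulation_params(8, -5, 70)
  disc <- tmshotspot:::sample_space(sp, 30)
  spec <- acquisition_spec("kg", mc_budget = 4000, seed = 17)
  kg <- kg_value(m, cand, sp, spec, disc = disc)
  expect_gte(kg, -1e-3)

  # oracle: exact E[max(mu + b z)] by Gauss-Hermite quadrature over the
  # fantasy observation, with moments from the dense posterior equations
  or <- dense_posterior(m$trials, m$kernel, sp, rbind(disc, cand))
  nd <- nrow(disc)
  Sfull <- {
    Xn <- normalize_coords(m$trials, sp)
    Qn <- normalize_coords(rbind(disc, cand), sp)
    Kss <- rbf_kernel_matrix(Qn, Qn, m$kernel)
    Ks <- rbf_kernel_matrix(Qn, Xn, m$kernel)
    Ky <- rbf_kernel_matrix(Xn, Xn, m$kernel) +
      diag(m$kernel$noise_var, nrow(Xn))
    Kss - Ks %*% solve(Ky) %*% t(Ks)
  }
  b <- Sfull[seq_len(nd), nd + 1] / sqrt(Sfull[nd + 1, nd + 1] +
                                           m$kernel$noise_var)
  gh <- pracma::gaussHermite(60)
  mu_n <- or$mean[seq_len(nd)]
  kg_exact <- sum(gh$w * vapply(gh$x, function(t)
    max(mu_n + b * sqrt(2) * t), numeric(1))) / sqrt(pi) - max(mu_n)
  # MC standard error from independent re-estimates
  reps <- vapply(1:6, function(s)
    kg_value(m, cand, sp, acquisition_spec("kg", mc_budget = 4000, seed = s),
             disc = disc), numeric(1))
  expect_lt(abs(mean(reps) - kg_exact), 3 * sd(reps) / sqrt(length(reps)) + 1e-4)

  # an uninformative observation (huge noise) yields ~zero gain
  noisy <- make_gp(m$trials, kernel_params(m$kernel$amplitude,
                                           m$kernel$length_scale, 1e6), sp)
  expect_lt(abs(kg_value(noisy, cand, sp, spec, disc = disc)), 1e-3)
})

test_that("max-value entropy search is zero without uncertainty and matches
          a numeric-integration entropy oracle", {
  expect_equal(tmshotspot:::mve_values_impl(fake_post(1, 0), fstar = 2), 0)

  m <- bump_model()
  cand <- stimulation_params(8, -5, 70)
  disc <- tmshotspot:::sample_space(sp, 25)
  v <- mve_value(m, cand, sp, acquisition_spec("mve", seed = 13),
                 disc = disc)
  expect_gte(v, -1e-6)

  # oracle: same f* average, but with the truncated-Gaussian entropy
  # computed by numerical integration instead of the closed form
  post <- gp_posterior(m, cand)
  mu <- post$mean_warped; sg <- sqrt(post$var_warped)
  ent_reduction <- function(fs) {
    Z <- pnorm((fs - mu) / sg)
    h_tn <- -integrate(function(z) {
      p <- dnorm(z, mu, sg) / Z
      ifelse(p > 0, p * log(p), 0)
    }, mu - 8 * sg, fs)$value
    0.5 * log(2 * pi * exp(1) * sg^2) - h_tn
  }
  reps <- vapply(1:8, function(s) {
    fstar <- withr::with_seed(s, {
      dr <- sample_posterior_functions(m, disc, 32)
      apply(dr, 1, max)
    })
    mean(vapply(fstar, ent_reduction, numeric(1)))
  }, numeric(1))
  vals <- vapply(1:8, function(s)
    mve_value(m, cand, sp, acquisition_spec("mve", seed = s), disc = disc),
    numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(vals) - mean(reps)), 3 * se + 5e-3)
})

test_that("acquisition spec validates names and budgets", {
  expect_error(acquisition_spec("bogus"), "unknown")
  expect_error(acquisition_spec("kg", mc_budget = 50), "mc_budget")
  expect_error(acquisition_spec("ts", candidate_count = 10),
               "candidate_count")
  expect_identical(acquisition_spec("UCB")$name, "ucb")
})

test_that("proposals are reproducible, stay inside the disc, and greedy UCB
          finds the posterior-mean argmax", {
  m <- bump_model()
  r1 <- propose_next(NULL, acquisition_spec("random"), sp, 0, seed = 9)
  r2 <- propose_next(NULL, acquisition_spec("random"), sp, 0, seed = 9)
  expect_identical(r1, r2)
  expect_lte(r1$x^2 + r1$y^2, sp$radius^2)

  for (nm in c("ucb", "ei", "ts", "kg", "mve")) {
    s <- propose_next(m, acquisition_spec(nm, candidate_count = 60,
                                          mc_budget = 128), sp,
                      step_n = 3, seed = 10)
    expect_lte(s$x^2 + s$y^2, sp$radius^2 * (1 + 1e-8))
    expect_true(s$theta >= 0 && s$theta <= 180)
  }

  # beta = 0 UCB is greedy mean maximization: compare to a dense grid scan
  grid <- expand.grid(x = seq(-28, 28, length.out = 60),
                      y = seq(-28, 28, length.out = 60),
                      theta = seq(0, 180, length.out = 10))
  grid <- grid[grid$x^2 + grid$y^2 <= sp$radius^2, ]
  mu <- gp_posterior(m, grid)$mean_warped
  best_grid <- max(mu)
  prop <- propose_next(m, acquisition_spec("ucb", beta0 = 0), sp,
                       step_n = 0, seed = 12)
  mu_prop <- gp_posterior(m, prop)$mean_warped
  expect_gte(mu_prop, best_grid - 1e-3)
})
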