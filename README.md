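# tmshotspot

Closed-loop TMS motor hotspot hunting with warped Gaussian processes and
Bayesian optimization.

## What problem this solves

Most TMS experiments and therapies start by locating the *motor hotspot*:
the coil placement over the motor cortex that elicits the largest
reliable motor-evoked potential (MEP) in a target hand muscle. The search
space is three-dimensional — coil location (x, y) on the scalp plus coil
rotation angle θ — and every probe costs a stimulus, so exhaustive grids
are slow and the common shortcut of fixing θ = 45° ignores individual
orientation tuning.

`tmshotspot` is for methods researchers and TMS labs who want to

- run or prototype a **closed-loop search** that optimizes location and
  rotation *concurrently* in a continuous space,
- compare **acquisition functions** (UCB, EI, Thompson sampling,
  knowledge gradient, max-value entropy search, random baseline) under
  controlled, reproducible conditions, and
- quantify what a fixed rotation angle costs in peak response.

## The model in brief

MEP amplitude is modeled as r = f(x, y, θ) + ε with a Gaussian-process
surrogate fit to the square-root-warped response z = √r (so predictions
back-transform to nonnegative amplitudes), a squared-exponential kernel
k(s, s′) = a·exp(−‖s − s′‖²/2l²) on normalized coordinates, and
hyperparameters (a, l, σ²) refit by maximum marginal likelihood after
every stimulus. An acquisition function proposes the next stimulus; the
final hotspot estimate is the argmax of the fitted response map, and maps
are scored against a ground truth by NRMSE and by top-decile
center-of-gravity distances d_xy (mm) and d_θ (degrees).

Because no public cohort ships with the package, a generative simulator
stands in for subjects: each synthetic subject is a latent orientation-
tuned response field sampled at 300 configurations with realistic
(CV ≈ 0.5) multiplicative noise, on which a ground-truth warped GP is
fit; stimuli are answered with draws from that model's posterior
predictive.

## A worked example

```r
library(tmshotspot)

# a synthetic subject: latent hotspot at (5, 8) mm, preferred angle 60 deg
sub <- make_synthetic_subject(
  synthetic_subject_params(hotspot_xy = c(5, 8), hotspot_theta = 60),
  seed = 21)
sub
#> Ground-truth subject: 300 trials, hotspot (5.7, 8.9) mm at 51 deg

# closed-loop search: 10 k-means init points + 20 Thompson-sampling stimuli
res <- run_search(subject_oracle(sub),
                  search_config(budget = 30, init_k = 10,
                                acquisition = acquisition_spec("ts"),
                                seed = 1))
res
#> Hotspot search: 30 stimuli (10 init), acquisition 'ts'
#>   estimated hotspot: x = 5.7 mm, y = 7.7 mm, theta = 55 deg

# how close is the fitted map to the ground truth?
grid <- build_test_grid(search_space())
nrmse(sub$gt_model, res$model, grid)
#> [1] 0.3626162
hotspot_distances(sub$gt_model, res$model, grid)
#>       d_xy    d_theta
#> 0.65687220 0.02671945

# what does fixing the coil at 45 degrees cost this subject?
fixed_angle_ratio(sub)
#> [1] 1.009663
```

After 30 stimuli the fitted map's center of gravity sits 0.66 mm from
the ground truth's with essentially no angular error. This subject's
preferred angle (60°) is close to the 45° convention, so fixing the
rotation costs it little (ratio ≈ 1.01); the same subject with a
preferred angle of 135° instead has
`fixed_angle_ratio(...) = 3.159274` — a threefold loss from the fixed
coil. Individual runs vary: a seed whose 10 initialization points all
miss the response region can oversmooth and localize poorly, which is
why the benchmarks below report medians over many seeds.

The command-line front end (`inst/cli/tmshotspot.R`) exposes the same
pipeline as verbs: `simulate-subjects`, `run-search`, `benchmark`,
`summarize`, `ratio-study`, with YAML configs and CSV/JSON outputs.

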