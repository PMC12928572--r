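---
title: "Closed-loop motor hotspot hunting: models and methods"
author: "tmshotspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop motor hotspot hunting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmshotspot)
```

## The problem

Transcranial magnetic stimulation (TMS) protocols begin by finding the
*motor hotspot*: the coil placement on the scalp that elicits the largest
reliable motor-evoked potential (MEP) in a target hand muscle. The search
space is genuinely three-dimensional — a coil location $(x, y)$ on the
scalp patch over the motor cortex *and* a coil rotation angle
$\theta \in [0^\circ, 180^\circ]$ — and every probe costs a stimulus, so
exhaustive grids are impractical and the conventional shortcut of fixing
$\theta = 45^\circ$ discards individually varying orientation tuning.

`tmshotspot` implements a closed-loop search that treats hotspot hunting
as Bayesian optimization of an unknown response function
$r = f(x, y, \theta) + \varepsilon$: a Gaussian-process surrogate is
refit after every stimulus and an acquisition function proposes the next
coil configuration, freely and concurrently in all three parameters.

## The surrogate: a square-root-warped GP

MEP amplitudes are nonnegative and strongly heteroscedastic, so the GP is
fit to the warped response $z = \sqrt{r}$ (`warp_response()`). The prior
is zero-mean with a squared-exponential kernel

$$k(\mathbf{s}, \mathbf{s}') = a \exp\!\left(-\frac{\lVert \mathbf{s} -
\mathbf{s}'\rVert^2}{2 l^2}\right),$$

plus observation noise $\sigma_\varepsilon^2$ in warped units. Because one
isotropic length scale $l$ acts on millimetres and degrees at once, inputs
are first mapped to a normalized cube — $x/R$, $y/R$, $\theta/180$ for a
search disc of radius $R$ (`normalize_coords()`). An anisotropic
(per-dimension) treatment would be a natural extension; it is deliberately
not the default so that the surrogate matches the single-length-scale
model the rest of the pipeline assumes.

Predictions come in two flavours, and the distinction matters:

* `mean_response` ($\mu_z^2 + \sigma_z^2$) is the exact posterior
  expectation of $r = z^2$. It is what the generative simulator's moment
  checks use.
* `predicted_response()` ($\max(\mu_z, 0)^2$) is the plug-in point
  prediction of the response map. All map-level evaluation — NRMSE,
  centers of gravity, hotspot argmax, the fixed-angle ratio — uses this
  map, for two reasons. With the variance term included, every
  *unexplored* region of a 30-trial model carries an apparent response of
  about the prior amplitude $a$, which systematically rewards
  space-filling samplers and penalizes focused ones. And the warped mean
  is clipped at zero before squaring because a negative predicted
  $\sqrt{\text{amplitude}}$ means a predicted response of zero —
  squaring an extrapolation undershoot would otherwise invent response
  mass (occasionally a spurious rim hotspot) in unsampled regions.

Hyperparameters $(a, l, \sigma_\varepsilon^2)$ are refit after every
stimulus by maximizing the log marginal likelihood with analytic
gradients, L-BFGS-B in log space, and eight restarts drawn log-uniformly
from the bounds $a \in [10^{-4}, 10^4]$, $l \in [0.01, 3]$ (normalized),
$\sigma_\varepsilon^2 \in [10^{-6}, 10^2]$, plus a warm start at the
previous step's fit. Cholesky factorizations fall back through a jitter
ladder $0 \to 10^{-10} \to 10^{-8} \to 10^{-6}$ before reporting a
numerical failure. Refitting begins once the initialization block is
complete (a surrogate fitted to a half-delivered design would never be
consulted, so nothing is lost).

```{r gp-demo}
sp <- search_space()            # 28.5 mm disc, theta in [0, 180]
set.seed(1)
s <- stimulation_params(runif(20, -15, 15), runif(20, -15, 15),
                        runif(20, 0, 180))
s$response <- pmax(0, exp(-((s$x - 5)^2 + (s$y + 3)^2) / 100) +
                     rnorm(20, 0, 0.05))
fit <- fit_gp(s, sp, gp_fit_options(seed = 1))
fit
```

## Acquisition functions

All five acquisition surfaces are computed in warped space, consistent
with the surrogate; only the final hotspot report is unwarped.

* **UCB**: $\mu_z + \beta_n^{1/2}\sigma_z$ with
  $\beta_n = \beta_0 e^{-n/\tau}$. A literal $\beta_n = e^{-n}$ schedule
  is degenerate ($\beta \approx 0$ after three stimuli), so the decay
  constant defaults to $\tau = $ budget$/3$ with $\beta_0 = 4$: wide
  early exploration, near-greedy behaviour by the end of the budget.
  Both knobs are exposed in `acquisition_spec()`.
* **EI** against the incumbent $r^\star$, the best *observed* warped
  response; the closed form degrades gracefully to
  $\max(\mu - r^\star, 0)$ at zero variance.
* **TS**: one joint posterior draw over a quasi-uniform candidate set
  (200 points by default), argmax selected, ties broken by lowest index.
* **KG**: Monte-Carlo knowledge gradient with 128 fantasy draws by
  default and the inner maximization over a 200-point discretization
  plus the training locations; fantasy draws are shared across
  candidates (common random numbers) so candidate ranking is not
  dominated by sampling noise.
* **MVE** (max-value entropy search): max-value samples are maxima of 32
  joint posterior draws over the discretization; the conditional entropy
  term uses the truncated-Gaussian closed form
  $\gamma\varphi(\gamma)/2\Phi(\gamma) - \log\Phi(\gamma)$,
  $\gamma = (f^\ast - \mu)/\sigma$.

Proposal maximization (`propose_next()`): UCB and EI surfaces are cheap
and smooth, so they get 16-start bounded continuous maximization. KG and
MVE are scored on the candidate set and the best candidate is polished by
one short Nelder-Mead refinement. TS is the exception: its sampled
function exists only on the candidate set, so the argmax candidate is
returned directly rather than inventing a continuous interpolation of the
draw. Proposals are always projected back into the disc and angle range.

## The closed loop

`run_search()` delivers `init_k` initialization stimuli (default 10),
then iterates fit–propose–stimulate–append until the budget or an early
stopping rule (relative stagnation of all three hyperparameters over a
trailing window, `stopping_check()`). Initialization points are k-means
centroids of 4,000 uniform samples of the space, clustered in normalized
coordinates so the rotation angle contributes to the spread on the same
footing as location. With `init_k = 0` the loop opens with a single
uniformly random stimulus, since the surrogate needs at least one
observation before it can propose anything informed.

Everything is driven by one integer seed: initialization, restart draws,
candidate sets, and the stochastic responses drawn through the oracle all
come from the run's seeded RNG stream, so a `search_config()` reruns
bit-identically.

## The generative MEP simulator

No recorded cohort ships with the package, so `make_synthetic_subject()`
builds one subject at a time from an explicit latent field:

$$r_{\mathrm{true}}(\mathbf{s}) = A\,
\exp\!\left(-\frac{(x - x^\ast)^2 + (y - y^\ast)^2}{2\lambda_s^2}\right)
\left[(1 - \rho) + \rho\,
\exp\!\left(-\frac{\Delta\theta^2}{2\lambda_\theta^2}\right)\right],$$

with $\Delta\theta$ the axial (180°-periodic) distance to the preferred
angle. 300 quasi-uniform trials are drawn with multiplicative Gaussian
noise (`noise_cv`, clipped at zero), a ground-truth warped GP is fit to
all of them, and *that model* — not the latent field — becomes the
response oracle: stimuli are answered with draws
$z \sim \mathcal{N}(\mu_z(\mathbf{s}),
\sigma_z^2(\mathbf{s}) + \sigma_\varepsilon^2)$ returned as $r = z^2$.
Sampling in warped space guarantees nonnegativity without clipping, and
the squared Gaussian reproduces both the expected amplitude and the
trial-to-trial variability the ground-truth model learned from its
noisy trials.

Default ensemble (`make_subject_ensemble()`): spatial scale
$\lambda_s = 7$ mm and angular scale $\lambda_\theta = 30^\circ$ (typical
FDI map extents), orientation depth $\rho = 0.8$ (strong but not total
orientation dependence), noise CV 0.5 (MEP variability is large), peak
amplitudes uniform on $[0.5, 1.5]$ a.u., hotspots uniform in the inner
60% of the disc, preferred angles uniform on $[20^\circ, 160^\circ]$.

What the simulator does *not* emulate: heteroscedastic floor effects near
the resting motor threshold, spatially correlated noise from coil-drift,
multi-peaked representations, and cohorts whose preferred angles cluster
near the conventional 45°. The last point is visible in the fixed-angle
ratio study: with preferred angles spread uniformly, the median gain of
free rotation over fixed 45° on this ensemble is around 2, where a real
cohort — whose preferred angles are near 45° more often than chance —
sits lower. Passing benchmarks here demonstrate the machinery and its
qualitative orderings, not clinical effect sizes.

## Evaluation metrics

`build_test_grid()` crosses a 3 mm Cartesian lattice inside the disc with
angles $0, 20, \ldots, 180^\circ$; at the default 28.5 mm radius this
gives 2,930 test points. Fitted and ground-truth plug-in maps are then
compared by:

* **NRMSE** — relative error pointwise, with the denominator floored at
  5% of the grid maximum of the ground-truth map. The floor is this
  package's choice: a literal pointwise division explodes wherever the
  map is silent, and 5% keeps the metric finite while preserving its
  relative-error reading in responsive regions.
* **Center-of-gravity distances** — each map is reduced to the
  response-weighted centroid of its top decile of grid points; `d_xy` is
  the Euclidean distance between the two centroids (mm) and `d_theta`
  the axial difference of the two weighted circular mean angles
  (degrees, in $[0, 90]$; angles are doubled before averaging because
  $\theta$ and $\theta + 180^\circ$ describe the same coil axis).

The surrogate itself treats $\theta$ as non-periodic on $[0, 180]$ — the
kernel sees the normalized interval, matching the evaluation range — while
the metrics use the axial convention. Wrap-around smoothing in the kernel
is a possible refinement the package intentionally leaves out.

## Benchmark harness and problem sizes

`run_benchmark()` crosses subjects, acquisition conditions and seeds;
within one (subject, seed) pair the k-means initialization is generated
once and shared by every condition with the same `init_k`, so acquisition
functions are compared from identical starting data. Metrics are recorded
at checkpoints (every 5 stimuli by default) by reconstructing the model
that existed at that step from the trace.

The package's standard study sizes, chosen to keep a full desk-scale
replication in the minutes range on one CPU: the headline localization
study uses 8 subjects x 20 seeds, Thompson sampling, and 10 shared
k-means points followed by 30 proposals (40 stimuli per run) (`scripts/acceptance.R` reruns exactly this);
the initialization study uses 4 subjects x 10 seeds x
{EI, UCB, TS, random} x {0, 10} initialization points with a 20-stimulus
budget. The full-scale preset (8 x 100, budget 40) is available via the
CLI (`--preset paper`).

## Numerical choices and degenerate inputs

* Posterior variances are clamped to $[0, a]$ (tolerance $10^{-10}$).
* Joint posterior sampling uses the same jitter ladder as fitting; an
  all-zero-variance posterior short-circuits to the mean.
* Ties: Thompson and candidate argmaxes break ties at the lowest index;
  the hotspot grid is ordered centre-out so a perfectly flat map yields
  the disc centre at the lowest angle.
* `stopping_check()` returns `FALSE` when fewer refits than the window
  exist — insufficient evidence is never treated as stagnation.
* Duplicated noisy trials are well-defined (the noise term regularizes
  the Gram matrix) but *not* a no-op: duplicating observations halves
  the effective noise. Only in the noise-free limit is the posterior
  invariant to duplication.

## Known limitations

* Single isotropic length scale; no ARD, no angular periodicity.
* The initialization study reproduces the rescue of EI/UCB by k-means
  points and TS's robustness, but *not* the early underperformance of
  uninitialized EI/UCB relative to random sampling: on this simulator's
  smooth GP-derived oracles, even a single-random-start EI or UCB run
  localizes the responsive region within about ten stimuli. Messier real
  response fields (multi-modal, floor-censored) are plausibly what makes
  uninitialized exploiters flounder early on real data.
* The MES and KG approximations are standard but coarse (finite
  discretizations, truncated-Gaussian entropy); they reproduce ordering
  behaviour, not publication-grade acquisition values.
* The simulator's unimodal latent field cannot probe multi-hotspot
  topographies.
* No hardware, neuronavigation, or safety-interlock integration — inputs
  and outputs are trial logs and JSON/CSV traces only.
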