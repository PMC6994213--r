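---
title: "Curiosity-driven exploration of droplet formulations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curiosity-driven exploration of droplet formulations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curiodrop)
```

## The problem

Multicomponent oil-in-water droplets self-propel through Marangoni flows set
up by asymmetric oil dissolution. A mixture of four oils — octanoic acid,
diethyl phthalate (DEP), 1-octanol and 1-pentanol — placed as droplets on a
surfactant (TTAB) solution exhibits motion, division and fusion, and the
mapping from formulation to behavior is nonlinear, poorly understood, and
dominated by rare events. `curiodrop` implements the closed exploration loop
used to study such systems autonomously: an algorithm picks a formulation,
an experiment measures the droplets' behavior, the result is logged, and the
next formulation is picked in the light of everything logged so far.

Two strategies are implemented.

* **Random parameter search**: each experiment draws a formulation uniformly
  on the mixture simplex (flat Dirichlet), ignoring history.
* **Curiosity algorithm (CA), random goal exploration**: each experiment
  first draws a *temporary goal* uniformly over the normalized observation
  space — the (mean speed, mean droplet count) unit square — then inverts
  the goal through a forward model learned from the log, and runs the
  formulation predicted to realize it. The goal is used once and discarded.

The forward model is locally weighted linear regression (LWR): for a query
formulation $x_q$, stored formulations are weighted by
$w_i = \exp(-\lVert x_i - x_q \rVert^2 / 2h^2)$ and a ridge-regularized
weighted linear fit, independent per observation dimension, is evaluated at
the query. Goal inversion minimizes
$c(x) = \lVert g(\hat f(x)) - g^\ast \rVert^2$ — the squared goal-space
distance between the model prediction and the target — with CMA-ES over the
unit box, renormalizing every candidate onto the simplex before evaluation.

## What the synthetic environment emulates

Exploration runs need an environment; the package ships a synthetic
stand-in (`simulate_experiment()`, `simulate_trajectories()`) that
reproduces the *qualitative* phenomenology reported for the physical
system, at desk scale. It makes no claim of quantitative fidelity to the
real landscape, which is unknown beyond a handful of published
observations. Its defaults define the study conditions used by the tests
and the acceptance script, and were fixed once, by construction:

* **Rare high-activity regions.** Mean speed is a sum over a small number
  of localized modes — squared-exponential kernels on the simplex
  (default: 3 modes, length scale 0.10, amplitudes 6–10 mm/s) — so that
  fewer than 15% of uniformly sampled formulations exceed the 3 mm/s
  "active" threshold even at the hot setting (about 5–9% at the default
  landscape). Everywhere else the kernel floor gives exactly zero speed.
* **A sharp temperature regime shift.** All mode activity is gated by a
  logistic in temperature with midpoint 24.8 °C and steepness 1.5 /°C, so
  the contrast between 22.6 °C and 27.0 °C — the two temperatures at which
  the physical effect was characterized — is large: the gate passes 0.96 at
  27 °C and 0.04 at 22.6 °C. At the default amplitudes this makes active
  behavior essentially disappear at the cold setting; the real system
  retained some cold activity, so the synthetic contrast is deliberately
  starker than reality.
* **The observation model.** Droplet count is the initial four droplets
  modulated by a second, independent mode map (divisions in active regions,
  fusion elsewhere), and both observation dimensions receive Gaussian noise
  (SD 0.3 mm/s and 0.5 droplets) floored at zero. Noise is a pure function
  of (formulation, temperature, environment seed), which makes every run
  bit-reproducible from its seed.
* **Two-peak long-time dynamics.** For 15-minute experiments, per-droplet
  speed follows a sum of two log-normal-shaped bumps in time. Peak times
  decrease linearly with temperature (−8 and −25 s/°C) and amplitudes
  increase linearly, so peaks occur earlier and larger when hotter, and the
  five transition times between the six motion phases (initiation,
  fluctuation, irregular, deceleration, continuous, saturation) are close
  to linear in temperature by construction. Heading dynamics are
  phase-dependent — high-variance direction changes during irregular
  motion, persistent headings during continuous motion — and droplets
  reflect specularly off the 16-mm arena wall (a 32-mm dish).

What the environment does *not* emulate: chemistry (dissolution kinetics,
DEP hydrolysis, pH effects), droplet–droplet interactions, deformable
contours, or any mechanistic Marangoni model. Consequently, a passing
benchmark here shows that the exploration machinery behaves as intended on
a landscape with the right *structure* (rarity, nonlinearity, a temperature
switch); it does not show that the same coverage numbers would be obtained
on the physical system.

## Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| LWR bandwidth `bandwidth_h` | 0.1 | ratio space | a few percent of a ~1000-point log carries non-negligible weight near a query |
| ridge `ridge_lambda` | 1e-6 | — | conditioning of the 5×5 local system |
| `min_points` | 5 | points | a local linear fit in 4 inputs needs ≥ 5 points; below this the model falls back to the kernel-weighted mean |
| CMA-ES `sigma0` | 0.3 | box units | covers the simplex from the uniform start |
| CMA-ES budget | 400 evals (240 in explorer loops) | — | inversion quality vs. run time |
| `n_bootstrap` | 10 | experiments | minimal support before the first model-based pick |
| bounds | speed, count ∈ [0, 10] | mm/s, — | observed behavior ranges; out-of-bounds observations clip rather than error |
| activity threshold | 3 | mm/s | the published definition of an "active" experiment (strict `>`) |
| coverage grid `G` | 20 | cells/dim | resolves the observation cloud without rewarding noise |
| tracking link radius | 12 mm/s ÷ fps | mm/frame | comfortably above the ~10 mm/s fastest droplets |
| profile window | 2 | s | the published sliding-window width |
| campaign sampling `dt` | 0.05 | s | the 20 fps recording rate; coarser sampling biases peak times via reflection chord loss |

## Numerical choices

* **Coverage normalization.** "Percent of the observable space" is
  ill-defined without the true reachable set, so coverage is reported
  relative to the pooled occupied-cell union of all runs under comparison.
  The per-prefix curve is non-decreasing by construction and the count
  agrees exactly with brute-force cell enumeration.
* **Goal inversion tie-breaks and audits.** The lattice oracle enumerates
  compositions in lexicographic order and keeps the first minimum; the
  CMA-ES result is audited against a fixed 4-level-per-axis box grid, so
  its achieved cost never exceeds the best audit point. With a fixed seed
  the optimizer replays identically, and a larger evaluation budget can
  only improve the best-found cost.
* **Transition detection.** Characteristic points are located on the
  smoothed mean-speed profile and its centered-difference acceleration:
  the 10%-of-maximum acceleration rise (P1→P2), the first acceleration
  maximum (P2→P3), the first speed peak (P3→P4), the inter-peak trough,
  i.e. the acceleration re-crossing to positive (P4→P5), and the second
  speed peak (P5→P6). Peaks and troughs are refined by a local quadratic
  fit over a ±max(8 s, 5% of t) window: wide enough to average sample
  noise on the broad second peak, narrow enough not to inherit the bump's
  skew. Absent features yield `NA`, never fabricated times; a transition
  seen in fewer than two temperature bins is dropped from the diagram.
* **Per-bin averaging before detection.** Raw per-experiment speed
  profiles are averaged within each 1 °C bin and transitions are detected
  once per bin (matching how per-interval curves are constructed), rather
  than detecting per experiment and averaging times.
* **Degenerate inputs.** All-zero formulations, empty datasets, monotone
  speed profiles, single-peak envelopes, empty videos and out-of-range
  temperatures raise typed errors or return explicit absences, as
  exercised by the test suite.

## Problem sizes used by tests and the acceptance script

The benchmark runs 5 matched seed pairs × 2 algorithms × 2 temperatures at
a budget of 300 experiments (the published campaigns used 1000; 300 keeps a
desk-scale run under a couple of minutes while leaving the directional
contrasts far from marginal). The phase campaign simulates 60 fifteen-minute
experiments at 20 fps over 20–30 °C in 1 °C bins, mirroring the 59-usable-
experiment design. The temperature-sensor check trains on 200 and tests on
100 observations of a fixed mode-center recipe over 20–30 °C; on synthetic
data the k-nearest-neighbor regressor achieves a mean signed error within
±0.3 °C with an error SD near 1 °C. The published 0.05 ± 0.66 °C figure was
measured on the physical system and is not asserted here.

## Known limitations

* The benchmark's cold condition is nearly flat at the default gate, so
  both algorithms see few active formulations there; only the hot-side
  contrasts and the hot-vs-cold contrast are meaningful.
* LWR falls back to kernel-weighted means wherever the effective support is
  below `min_points`; early in a run, model-based picks are therefore close
  to weighted-nearest-neighbor guesses.
* Greedy nearest-neighbor linking can mislabel `fused` vs `ended` when a
  droplet vanishes far from any surviving neighbor, and the split child's
  identity is necessarily new — lineage is not reconstructed.
* The phase-diagram boundary lines are global least-squares fits; they are
  only valid inside the fitted temperature range, and `classify_phase`
  refuses temperatures outside it.
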