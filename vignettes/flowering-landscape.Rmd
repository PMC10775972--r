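---
title: "A stochastic landscape model of miR156/miR172-controlled flowering time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic landscape model of miR156/miR172-controlled flowering time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`flowerscape` implements a six-variable model of the gene network that
controls the juvenile-to-flowering transition in *Arabidopsis thaliana*. The
state vector collects the expression levels of the two microRNAs and four
gene families that form the core of the pathway:

| variable | species | role |
|---|---|---|
| X1 | miR156/157 | juvenile identity; represses SPLs |
| X2 | SPL family | activates miR172 and feeds back on miR156 |
| X3 | miR172 | represses the AP2 family |
| X4 | AP2 family | floral repressors; self- and cross-repressing |
| X5 | FT | floral pathway integrator |
| X6 | AP1 family | floral meristem identity output |

Each production term is a Hill function: activations have the form
`a x^n / (S^n + x^n)` and repressions the form
`bm (1 - b + b S^n / (S^n + x^n))`, where `b` in [0, 1] is the repression
depth (`b = 0` switches the repression off, which is the knockout semantics
for depth parameters). Every species decays at the common rate `k`.
Atmospheric CO2 enters only the miR156 equation, as a repressor with
effective concentration `c * co2` — the lumped action of the photosynthetic
sugar signal that shuts down miR156 transcription. The constant SVP input
enters only the miR172 equation. The deterministic drift is assembled in
`flowering_drift()`; `flowering_jacobian()` provides the analytic
linearization used for root finding and stability classification.

Intrinsic molecular noise and environmental fluctuation are modeled as
additive Gaussian white noise with intensity `2 D`, integrated by the
Euler-Maruyama scheme (`simulate_trajectory()`), with reflection at zero so
concentrations stay non-negative. Reflection was chosen over truncation
because it preserves probability mass near the boundary instead of piling
an atom at zero; at the calibrated noise level the boundary is rarely
touched by any species except the near-zero AP1 output in the juvenile
state.

The analysis pipeline then follows the standard landscape program for
stochastic gene circuits:

1. **Fixed points** (`find_fixed_points()`): multi-start damped Newton on
   the drift with deduplication and eigenvalue classification. The
   calibrated network is bistable: a juvenile attractor (AP2 high, AP1 off)
   and a flowering attractor (AP2 low, AP1 on), separated by a saddle.
2. **Landscape** (`estimate_landscape()`): the steady-state probability
   `Pss` is estimated by histogramming long stochastic trajectories on the
   (X4, X6) projection — the AP2/AP1 plane in which the two developmental
   states separate — and the potential is `U = -ln(Pss)`. Basins and the
   saddle are located on the grid (`locate_basins_and_saddle()`), the
   saddle as the minimax bin of the lowest-maximum path joining the two
   minima. Barrier heights are `Uc - Ub` (forward, juvenile to flowering)
   and `Uc - Ua` (backward).
3. **Flowering time** (`first_passage_ensemble()`): the mean first passage
   time (MFPT) from the juvenile attractor to a neighborhood of the
   flowering attractor, in days, with censoring at a finite horizon.
4. **Experiments** (`co2_scan()`, `parameter_scan()`,
   `knockout_experiment()`, `sensitivity_analysis()`): the derived scans
   over CO2, regulation strengths and feedback removals.

## Calibration of the default parameters

No quantitative parameter table is available for this network, so the
package derives its default `flowering_params()` from a unity-style
starting point (all strengths, the Hill threshold `S` and the degradation
rate `k` at 1; Hill coefficient `n = 4`) perturbed until four
experimentally anchored behaviors hold simultaneously:

1. the network is bistable at ambient CO2 (430 ppm);
2. the MFPT at 430 ppm falls in the observed 70–80-day flowering window;
3. at 810 ppm CO2 flowering is about 10% earlier than at 430 ppm;
4. sweeping the miR156 -| SPL repression depth `b21` downward from 1 in
   steps of 0.01, bistability is lost below 0.8.

The structural departures from unity, and what each one buys, are:

* `bm43 > S k > bm44`: the juvenile branch of AP2 sits at `bm43 / k`, above
  the Hill threshold, and the flowering branch at `bm44 / k`, below it —
  this separation across the switch is what makes the miR172–AP2 module
  bistable at all.
* `bm34 > 1` gives miR172 enough dynamic range to shut the `bm43` branch
  off in the flowering state.
* `bm21 > 1` gives the SPL pool the dynamic range that makes the `b21`
  depth an effective bifurcation parameter; its exact value pins the
  bistability-loss threshold into the (0.79, 0.80] grid cell.
* `a14 > 1` routes most of the juvenile state's miR156 production through
  the AP2 -> miR156 feedback, so removing the SPL branch (`a12 = 0`)
  shallows the juvenile basin without destroying it.
* `a12 < 1` sets the share of the SPL -> miR156 feedback so that its
  removal advances flowering by roughly 20 days in the 400–800 ppm range.
* a partial CO2 repression depth (`b < 1`) leaves a CO2-independent floor
  of miR156 production, which keeps the network's CO2 response in the
  observed range without overdriving the miR156 arm.
* `c` places the CO2 half-effect near 140 ppm: the flowering-time response
  is steep between 200 and 300 ppm and nearly saturated above 400 ppm,
  while retaining the ~10% advance from 430 to 810 ppm.
* `D` sets the noise-driven escape scale: it is the only parameter that
  converts the fixed barrier topography into the 70–80-day flowering
  window.

`scripts/calibrate.R` re-derives the shipped values: it pins `bm21` by
bisection against the deterministic `b21` sweep, then pins `D` by bisection
against the 430-ppm MFPT, and verifies the remaining anchors. The
structural knockout checks (below) are preserved by construction and
re-verified.

A consequence of the network wiring worth documenting: every upstream
influence on the bistable miR172–AP2 core — the CO2 signal, the
SPL -> miR156 feedback `a12`, the AP2 -> miR156 feedback `a14` and the
miR156 -| SPL depth `b21` — funnels through the single SPL -> miR172
activation. The calibration anchors that keep the CO2 channel and the
`a12` knockout effect alive (behaviors 3 and the ~20-day advance)
therefore also keep the `a14` and `b21` small-perturbation sensitivities
substantial; with this wiring and a shared Hill coefficient they cannot be
made arbitrarily small relative to the in-module depths `b43`/`b34`. At the
shipped calibration the four channels `b34`, `b43`, `a14` and `b21` end up
of comparable magnitude — the in-module depths are the strongest delaying
(`b43`) and among the strongest accelerating (`b34`) influences, but the
two miR156-side channels remain the same order, a direct footprint of the
anchors that keep them alive.

## Noise, absorption and numerical choices

* **Integrator**: Euler-Maruyama with `dt = 0.01` days. The drift
  relaxation times are O(1/k) = O(1 day) and MFPTs are tens of days, so
  the discretization bias is far below Monte-Carlo error; tests verify
  first-order convergence in `dt` and the `2 D dt` variance contract of
  the noise increments.
* **Absorption criterion**: a trajectory has "flowered" when its full 6-D
  Euclidean distance to the flowering fixed point drops below a quarter of
  the distance between the two attractors. A fraction of the
  inter-attractor separation is scale-free: it moves with the attractors
  as parameters change, which matters in scans where the basins drift.
* **Censoring**: the default horizon is 1000 days, more than ten times the
  baseline MFPT. Censored trajectories are counted and reported, never
  dropped; the reverse transition (flowering back to juvenile) is expected
  to censor heavily — that asymmetry, mirrored by the higher backward
  barrier `Uc - Ua`, is the model's statement that flowering is
  effectively irreversible.
* **Seeds**: every ensemble member i runs under `child_seed(seed, i)`, a
  counter-based derivation, so ensembles are reproducible, parallelizable,
  and — crucial for the scans — pairable: comparing two scenarios under
  the same seed bank reuses identical noise streams per trajectory
  (common random numbers), which is what makes 5% sensitivity
  perturbations resolvable at desk-scale ensemble sizes.
* **Landscape estimator**: trajectories are seeded half at each attractor
  and pooled after burn-in. In a slowly mixing bistable system this
  approximates the stationary weights at desk-scale run lengths; the
  residual bias shifts `U` levels slightly but cancels in barrier
  *differences* across scenarios run with the same plan. Empty bins get
  `U = +Inf` and are excluded from saddle paths. Counts are lightly
  box-smoothed (one-bin half-width) and basins are identified by
  topographic persistence (default 0.75 in U units) combined with a basin
  mass floor (0.5% of the probability), restricted to connected components
  carrying at least 0.2% of the mass — all three guards target
  the same failure mode, sparse-histogram speckle masquerading as basins.
* **Saddle definition**: the minimax bin over 4-connected paths between
  the two minima, found by a union-find sweep in order of increasing U;
  this is the discrete realization of the lowest mountain pass on the
  projected landscape.
* **Fokker-Planck cross-check**: `fokker_planck_steady_state()` solves the
  discrete stationary equation with zero-flux boundaries and
  Scharfetter-Gummel (exponentially fitted) fluxes on 1-D/2-D reduced
  models only. It is a validation tool — the Ornstein-Uhlenbeck line has a
  Gaussian solution with variance `D/k`, and the 2-D double-well toy has
  the Boltzmann form `exp(-V/D)` — not a route to the 6-D landscape, whose
  direct solution is out of desk reach.

## What the toy fixture does and does not show

`make_toy_double_well()` builds a 2-D gradient system with a quartic
double-well potential whose minima, saddle, barrier and stationary
distribution are known in closed form. The landscape and first-passage
machinery are validated against it: symmetric wells must give equal
barriers and equal forward/backward passage times, the histogram `U` must
match `V/D` up to a constant, and the MFPT must sit near the Kramers
estimate. Passing these tests certifies the *machinery* — histogramming,
persistence, minimax saddle, censored MFPT accounting — on a system where
truth is analytic. It does not certify the flowering model itself, which
has no closed form; there the anchors are the calibration behaviors and
the structural facts (basin topology under knockouts, monotone scans).

Simulated data in this package emulate the stochastic dynamics of a
six-gene regulatory module under a stated noise model. They do not emulate
measurement noise, cell-to-cell heterogeneity in parameters, or the
developmental staging of real plants; agreement with the package's tests
is therefore evidence about the model and its implementation, not direct
evidence about field biology.

## Problem sizes

Test-grade runs use first-passage ensembles of 120–200 trajectories at
`dt = 0.01` days and landscape estimates pooling 12–20 trajectories of
300–400 days on 50–60 bins per axis; the reproduction script uses 1000
trajectories per ensemble. These sizes put Monte-Carlo standard errors on
the MFPT near 4–5 days (about the width the calibration anchors tolerate)
and resolve basin positions to a bin or two. Figure-grade runs would
simply scale `n_traj` and the sampling plan up; every function takes its
plan as an argument.

## Known limitations

* The glucose/T6P/HXK1 signaling chain is subsumed into the single
  `c * co2` coupling; GI regulation of miR172 is not modeled.
* `Pss` from seeded-basin sampling is biased when the two basins exchange
  mass much more slowly than the run length; barrier *differences* across
  scenarios are the robust quantity, absolute `U` levels are not.
* The projected 2-D saddle is a property of the (X4, X6) marginal, not of
  the full 6-D dynamics; it matches the deterministic saddle's projection
  to within a bin at the calibrated noise, but the identification is
  heuristic.
* A single scalar `D` ignores species-specific noise scales; the
  parameter container accepts only one diffusion coefficient by design.
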