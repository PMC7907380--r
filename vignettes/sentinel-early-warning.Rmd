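---
title: "Detecting and localizing human intruders from sentinel-animal movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and localizing human intruders from sentinel-animal movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Savanna herbivores that are not themselves poaching targets react to humans
on foot much as they react to predators: they flee away from the threat,
speed up, straighten their paths, raise their body acceleration, and bunch
into more aligned groups. If enough animals in a reserve carry GPS +
tri-axial accelerometer collars, those reactions are a distributed sensor
for human intrusion. `sentinelews` implements the full analysis chain for
such an early-warning system — from raw, irregular collar data to a
per-animal response probability, a reserve-level intrusion verdict, and a
spatial probability surface for where the intruder is — together with a
synthetic world that makes every stage testable without any field download.

The package is organized as an analysis: numbered drivers under `analysis/`
run the stages in order and write their tables under `results/`, while all
computation lives in the package so the test suite and the acceptance
script exercise exactly the same code.

## The synthetic world

`simulate_study()` generates the study conditions end to end:

* **Landscape.** Spatially autocorrelated tree-cover and elevation fields
  (Fourier-smoothed Gaussian noise, 10 m cells, 3 km × 3 km), with habitat
  suitability per species and time-of-day bin derived deterministically
  from tree cover and slope. Grass-preferring grazers peak at low tree
  cover; all species avoid steep slopes; midday shifts preference slightly
  towards shade.
* **Herds.** A correlated random walk at 1-s resolution with three-zone
  social interactions (repulsion < 8 m, alignment < 60 m, cohesion towards
  the herd centroid), a persistent move/rest process (mean bout roughly
  5 min), and lognormal moving speeds per species scaled by local
  suitability (speed scale $= 0.4 + 0.6\,s$). Animals reflect at the
  reserve boundary. Each species splits into two herds by default: the
  field system this emulates had ~95 active collars spread over many
  smaller herds, and sentinel coverage of the area — not collar count —
  is what determines whether an intruder can be noticed at all.
* **Intrusions.** Correlated walks on foot (1.2 m/s) or by vehicle (5 m/s)
  lasting about two hours, positions every 5 s, stratified over
  morning/midday/afternoon; matched control segments use the same clock
  window one or two days away.
* **Responses.** An animal inside the detection radius (default 300 m — the
  perception distance is not an observable of the original study, so it is
  exposed as a plain configuration knob with no claimed default beyond
  plausibility) switches to flight: heading rotated away from the intruder,
  speed multiplied (default ×3), turning noise reduced, alignment raised,
  ODBA raised. Flight durations are lognormal with the observed
  species-specific means and SDs (zebra 47±28 min, wildebeest 39±33, eland
  46±18, impala 43±14). A regroup phase with boosted cohesion follows.
  Each response carries a drawn intensity (low/medium/high) scaling the
  effect strength — intensity describes how pronounced the response looks,
  and cannot be derived from trigger distance because animals always
  trigger near the perimeter. Fleeing animals press against the fence
  rather than reflecting, which is what fenced reserves actually produce
  (bunching along the fence line) and keeps flight headings pointed away
  from the threat.
* **Null world.** `response_enabled = FALSE` keeps the entire trigger and
  label bookkeeping but neutralizes every behavioral effect. This is the
  calibration control: any downstream "signal" found in that world is
  leakage or bias, so the detector must fall to chance on it.
* **Sensors.** ODBA is summarized per contiguous 15-s window
  (mean/max/variance, with measurement noise). GPS fixes follow the
  adaptive firmware schedule: 15-min intervals when the windowed mean ODBA
  is below the activity threshold, 2- or 10-min (a per-collar setting)
  when active, re-evaluated at every window boundary; a 5-m geofence
  suppresses fixes measured within 5 m of the previous one; Gaussian noise
  (SD 15 m) and rare spike outliers (1% of fixes, 500–1500 m, uniform
  direction — constructed to satisfy all three spike criteria so the
  corrector is genuinely exercised).

The activity threshold (0.10) was calibrated so undisturbed herds trigger
the fast schedule roughly half the time, which is the stated design point
of the firmware emulation.

What the generator does *not* emulate: real terrain barriers (rivers,
fences inside the area), weather-driven behavior, predator cues,
inter-species herding, tag failure and data gaps, and the full richness of
wild behavioral repertoires (no freeze/threat-inspection states). Passing
tests therefore demonstrate that the chain is correct and calibrated on a
world obeying its assumptions, not that field performance matches the
original deployment.

## Trajectory reconstruction

Raw sensor tracks are modelled to regular 1-min trajectories in five steps:

1. **Gross errors** — fixes outside the inflated bounding box (default
   margin 500 m) or implying speed above 30 m/s are dropped.
2. **Spikes** — a fix is a spike when both legs exceed 500 m, the
   neighbours are within 100 m of each other, and the turning angle
   exceeds 150° (the "approached 180°" rule made operational). The
   spikiness score $(\min(d_{in}, d_{out})/\text{gap}) / (1 - \text{turn}/\pi)$
   maps through a saturating exponential to a shift fraction in
   $[0.5, 1)$ of the distance to the neighbours' midpoint — spikier
   patterns shift closer to the midpoint.
3. **Kalman smoothing** — a continuous-time local linear trend (position +
   velocity) per coordinate, the simplest dynamic linear model consistent
   with irregular sampling; process/observation variances by maximum
   likelihood on the filter likelihood (Nelder-Mead over the log
   variances, shared between x and y), then a two-sided RTS smoother. The
   recursion is in compiled code (`src/kalman.cpp`) because per-track
   likelihood optimization is the pipeline's inner loop.
4. **ODBA-informed densification** — inside each fix gap, displacement is
   allocated over 10-s slots proportionally to ODBA in excess of the
   stationarity threshold (0.08); slots below it repeat the previous
   position; gaps without ODBA coverage fall back to plain linear
   interpolation, flagged.
5. **X-spline resampling** — an X-spline through the densified points,
   evaluated on the exact 60-s grid. The observed/interpolated weighting is
   encoded in the per-point shape parameter (weight 1 maps to shape −0.5,
   near-interpolating; weight 0.3 maps to ~0.4, approximating), which is
   the natural way to express point confidence in this spline family.
   Per-step ODBA statistics are averaged onto the steps.

Under the default sensor conditions the minute-level reconstruction error
has a median of roughly 15–22 m depending on the herds' activity mix — on
the order of the fix noise itself (raw radial fix error has median
$\sigma\sqrt{2\ln 2} \approx 17.7$ m at $\sigma = 15$ m). The floor is
set by the fix noise and by long inactive gaps, which contain almost no
positional information beyond the geofenced endpoints; the
reconstruction's gains concentrate where they matter — spike outliers
(hundreds of metres) are removed, with transect RMSE dropping roughly
twenty-fold, and fix noise is smoothed at observation times.

Intrusion routes are dense and accurate, so their "reconstruction" is a
plain 1-min decimation.

## Features

Four classes of base features per animal-minute: individual geometry
(speed, turning angle, 5-min directional persistence, 10-min net-gross
ratio, log-log MSD fit over lags 1–5 min, variance of log first-passage
times through 50/100/250 m circles, censored at 45 min), accelerometer
(per-step ODBA mean/max/variance and windowed aggregates), collective
movement (nearest-neighbour distance, density within 150 m, heading
alignment as the mean resultant length of neighbour headings, speed
synchrony, centroid distance — computed within species, i.e. herd
topology), and space use (suitability and tree cover at position,
elevation change, Tobler-implied walking speed
$6 e^{-3.5|s + 0.05|}$ km/h for the step's slope, the realized/Tobler
speed ratio as an energetic-cost proxy, and the suitability gradient along
the heading). No feature references absolute coordinates or absolute time;
a translation test in space and time asserts this.

Right-skewed features are log(1+x)-transformed; all features are
winsorized at the 0.001/0.999 quantiles of the reference pool; moving
windows (5-min centred mean and SD, 10- and 20-min lagging means, and the
centred-minus-lagging differences) capture recent history; five z-variant
families standardize against reference sets built from undisturbed data
only — per species (all features), and per 30-m area cell, time-of-day ×
5-week period, area × time-of-day × period, and individual × time-of-day ×
period (a designated context-sensitive subset). Degenerate or unseen
groups fall back to species statistics. Dividing by the standard deviation
is the default (unit-variance outcome); a literal divide-by-variance mode
exists behind a flag. An ordinal variant (10 quantile bins) closes the
registry. The registry reports its own column count (≈ 235 under defaults)
rather than chasing any external tally; windows are computed on the raw
features before standardization — the two orders agree up to a per-group
affine map wherever the context group is constant within a window, and
computing windows first keeps the window variants fold-independent.

## Behavior classification

Training rows come only from intrusion-present segments: undisturbed rows
must lie more than 1 km from the intruder and 90% of them are removed
(seeded) for balance; response rows keep only medium and high intensities.
Features are scored by four importance measures against proximity labels
(within 1 km of a concurrent intrusion versus an equal-sized seeded control
sample): univariate Mahalanobis distance $|\mu_1-\mu_0|/\sigma_{pooled}$
(univariate because the scores rank individual features), marginality
$(\mu_1-\mu_0)/\sigma_0$, specialization $\sigma_1/\sigma_0$ (ranked by
$|\log|$, since deviation from 1 in either direction is informative), and
random-forest mean decrease in accuracy (forest settings recorded in the
spec object). The union of the four top-125 lists feeds a two-stage PCA —
per feature class to 95% retained variance, then a second PCA across the
pooled scores — and the first 8 components feed an RBF-kernel
C-classification SVM (gamma $10^{-3.2}$, cost $10^{-2.2}$, equal class
weights, species-specific models with a pooled fallback; flight-regroup:
gamma $10^{-2.0}$, cost $10^{-1.5}$, 12 components). The SVM probabilities
pass through a centred moving-window maximum (±15 min).

Everything reference-dependent — winsorization quantiles, all five
standardization families, ordinal bins, importance, the PC stack, the
clustering and the SVMs — is refitted inside each leave-one-intrusion-out
fold; the held-out intrusion and its matched control are predicted out of
fold. Average precision of the least occurring class is reported pooled
over folds and per fold (the original report does not say which; both are
exposed), plus per species, intrusion mode and time of day.

## Detection

Per 15-min block of each segment: mean/SD/max/90th percentile of the
smoothed probabilities; Moran's I with inverse-distance weights over the
per-animal mean probabilities at the animal positions (the smallest
standard statistic matching "local spatial autocorrelation"; all-equal
values give 0 by convention); the nearest-neighbour index of predicted-
undisturbed animals (observed over expected NN distance under complete
spatial randomness within the convex hull); and the mean log
cluster-association odds from the per-species 25-cluster k-means of the
reduced feature space (Laplace-smoothed, fitted per detection fold).
Each block feature aggregates over the segment with exactly eight
statistics: mean, SD, min, max, and mean/SD/min/max of the first
differences between consecutive blocks.

The cluster-odds features deserve a caution that the original scale hides:
plug-in odds estimated on a training fold encode the training segments'
own labels, so their in-fold t-values are wildly optimistic when segments
are few. Training segments therefore receive cross-fitted
(leave-own-segment-out) odds; held-out segments use the full-training odds
table.

Features are ordered by the iterative residualized t-test procedure (add
the largest-|t| feature, regress the remaining features on the added
original feature, standardize the residuals, repeat; ties break by name),
and a logistic regression on the top ordered features (optionally with
all two-way interactions) is evaluated by 25× stratified twofold
cross-validation. Two protocol choices matter at small segment counts and
are both exposed. First, by default the ordering is re-run inside every
training fold; determining it once on all segments (the
sequence-determination variant, available via `refit_ordering = FALSE`)
leaks feature selection into the evaluation — on a response-free null
world its cross-validated accuracy sits near 0.7 rather than 0.5, while
the per-fold default is centred on 0.5 under label permutation. Second,
the default model size of 7 features is appropriate for a study of 100+
segments; at the 20-segment calibration scale the tests use 2 features
(about one covariate per five events, the usual logistic rule of thumb).
Complete separation — common at synthetic effect sizes — is flagged;
prediction remains usable, and a ridge refit is available.

The pipeline's own calibration, recomputed by the test suite: on the
planted-response world the behavior classifier reaches out-of-fold AP far
above prevalence and detection accuracy above both the null world and the
95th percentile of its label-permutation distribution; on the null world
(identical dynamics, effects disabled) AP falls to prevalence and
detection accuracy into the permutation band around 0.5.

## Localization

For candidate location $i$ and sentinel $j$ with movement direction
$\mu_j$ and response probability $p_j$, the odds ratio is

$$O_{i,j} = \frac{p_j\, f_{wn}(\theta_{ij}; \mu_j, \rho_1(t_s))\,
f_{ln}(\gamma_{ij}; \mu_1(t_s), \sigma_1(t_s)) + (1-p_j)\,
f_{wn}(\theta_{ij}; \mu_j, \rho_0)\, f_{ln}(\gamma_{ij}; \mu_0, \sigma_0)}
{f_{wn}(\theta_{ij}; \mu_j, \rho_0)\, f_{ln}(\gamma_{ij}; \mu_0, \sigma_0)}$$

with $\theta_{ij}$ the direction and $\gamma_{ij}$ the distance from cell
to animal, $f_{wn}$ the wrapped normal density (series truncated at ±10
wraps) and $f_{ln}$ the lognormal. The printed source formula lacks an
operator between its two numerator products and uses $\sigma_0$ where a
directional parameter is expected; this package reads the numerator as the
sum of the response- and undisturbed-weighted joint densities (the only
reading that makes $O$ a well-formed two-state mixture likelihood ratio)
and uses $\rho_0$ in the undisturbed directional term. Under this reading
an undisturbed animal ($p_j = 0$) is exactly uninformative ($O = 1$). An
alternative "additive" numerator ($O = 1 + p_j \cdot LR$, which yields
$O = 2$ when $p_j = 1$ and the response geometry equals the null) is a
configuration switch.

$\mu_1$, $\log\sigma_1$ and $\log\rho_1$ are 3rd-order polynomials in
$t_s$, the minutes since the predicted response onset (first minute of the
current above-boundary run of the smoothed probability at the max-F1
boundary), truncated at 45 min; they are fitted from predicted responders
against the known intruder positions (conditional-mean regression for
$\mu_1$; per-5-min-bin residual log-SD and circular SD — via the mean
resultant length estimator $\hat\sigma = \sqrt{-2\log R}$ — with thin bins
pooled and weighted polynomial fits through the bin values). The null
parameters come from control-segment animals paired with uniform random
locations in the bounding box, absorbing the study-area geometry.

$P_i = \alpha \sum_j O_{i,j}$ on a 50-m grid (resolution our choice; not
stated in the source), normalized so the surface integrates to 1 over the
bounding box. One surface per minute of each intrusion (cadence also our
choice); per intrusion the 10 surfaces whose top-5% probability mass
occupies the smallest area are kept and the mean peak-to-truth distance
reported, plus the fractions of intrusions within 100/300/500 m.

## Numerical choices and edge cases

* Zero-length steps give undefined headings/turning angles; they are
  emitted missing and imputed (z = 0, i.e. at the group mean) during
  standardization; remaining missing values are imputed at training column
  means before PCA.
* Constant feature columns collapse to one ordinal bin with a warning;
  zero-variance features are skipped by the t-test ordering with a
  warning; $\sigma_0 = 0$ features are excluded from importance.
* k-means uses 5 restarts under a derived seed; cluster prediction of new
  rows is by nearest centroid.
* Derived seeds: one master seed fans out per stage through a hash, so any
  stage can be rerun in isolation with identical randomness and every
  randomized quantity in the pipeline is reproducible from the single
  seed.
* Problem sizes used by the test suite: transects of 300 fixes with 90
  injected spikes; unit worlds of 12–16 animals over 40–60 min; the
  calibration worlds of 40 animals, 10 intrusions + 10 matched controls at
  2 h; localization recovery from 4000 simulated responder-minutes (about
  200 flights) and snapshot grids at 50–100 m. These are the package's
  stated evaluation scales.

## Known limitations

* The behavior-classifier hyperparameters default to the published
  selected values rather than a fresh grid search; a search grid is
  exposed but not run by default.
* The intensity labels scale the planted effect strength linearly; real
  response intensity is a property of the observer annotation, not the
  animal.
* The detector's cluster-odds features use the behavior-fold cluster
  models; within detector cross-validation only the odds table is
  refitted per fold (centroids are geometry, odds are the supervised
  part).
* Localization assumes the response onset clock is meaningful; when the
  classifier misses a response entirely, the corresponding sentinel
  contributes only null terms.
* End-to-end localization on the synthetic study is scale-limited: because
  planted flights are long and fast, the fitted response-distance scale
  broadens quickly with t_s (exp(mu1) from ~0.3 to ~1.7 km) and the best
  per-intrusion surfaces (peak errors of tens to hundreds of metres)
  are only weakly identified by the top-5%-mass condensation criterion;
  the mean selected error sits near 1 km on the 3-km domain. The
  known-geometry recovery tests, not the end-to-end synthetic errors, are
  what validate the surface machinery.
* The "spatial contagion" augmentation (using neighbours' predicted
  probabilities as features) is deliberately not implemented — it was
  explored and abandoned in the original analysis.
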