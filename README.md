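# sentinelews

Detecting and localizing human intruders in a wildlife reserve from the
movement responses of **sentinel animals** — abundant, non-targeted
herbivores wearing GPS + tri-axial accelerometer collars. When a person
moves through a reserve on foot or by vehicle, nearby herds flee away from
the threat, speed up, straighten their paths, raise their body
acceleration (ODBA) and bunch into more aligned groups. This package
implements the full analysis chain that turns those reactions into an
early-warning system, plus a synthetic savanna world that makes every
stage testable end to end:

1. **Synthetic world** — landscape rasters, multi-species herds
   (three-zone correlated random walk), intruder routes, planted
   flight/regroup responses with species-specific durations (zebra
   47 min, wildebeest 39, eland 46, impala 43), and sensor-realistic
   degradation (adaptive 2/10/15-min GPS schedule, 5-m geofence,
   positional noise, spike outliers, 15-s ODBA windows).
2. **Trajectory reconstruction** — gross-error filtering, spike
   correction, a continuous-time Kalman smoother (local linear trend,
   maximum-likelihood variances, Rcpp), ODBA-informed interpolation and
   X-spline resampling onto a regular 1-min grid.
3. **Feature engineering** — individual geometry, accelerometer,
   collective-movement and space-use features (including Tobler-cost and
   habitat-suitability terms), moving windows, and standardization against
   undisturbed reference sets per species, area, time of day × 5-week
   period, and individual.
4. **Behavior classification** — per-species RBF-kernel SVMs (gamma
   10^-3.2, cost 10^-2.2, 8 principal components) over an
   importance-selected (Mahalanobis / marginality / specialization /
   random-forest MDA, top-125 union), twice-PCA-reduced feature space;
   centred ±15-min running-maximum smoothing; leave-one-intrusion-out
   cross-validation with fold-local references (no leakage).
5. **Intrusion detection** — 15-min block summaries of the predicted
   response probabilities (level, Moran's I spatial autocorrelation,
   nearest-neighbour clustering of predicted-undisturbed animals,
   cluster-association odds), eight per-segment statistics, residualized
   t-test feature ordering, and a 7-feature logistic model under 25×
   stratified twofold cross-validation.
6. **Localization** — for each candidate cell, a wrapped-normal ×
   lognormal odds ratio per sentinel,

   O_ij = [ p_j f_wn(θ_ij; μ_j, ρ1(t_s)) f_ln(γ_ij; μ1(t_s), σ1(t_s)) +
   (1−p_j) f_wn(θ_ij; μ_j, ρ0) f_ln(γ_ij; μ0, σ0) ] /
   [ f_wn(θ_ij; μ_j, ρ0) f_ln(γ_ij; μ0, σ0) ],

   with the response geometry a 3rd-order polynomial in t_s (minutes since
   response onset, truncated at 45) and the null geometry fitted against
   random locations; P_i = α Σ_j O_ij on a 50-m grid, normalized to
   integrate to 1 over the study bounding box; surfaces ranked by how
   small an area holds their top-5% probability mass.

The repository is organized as an analysis: `analysis/01…06_*.R` are thin
narrative drivers that run the stages in order and write tables under
`results/`; all computation lives in `R/` so the tests and the acceptance
script call the same code.

## Worked example

A small end-to-end run (12 animals, 4 one-hour intrusions + matched
controls; about ten seconds on one core):

```r
library(sentinelews)
cfg <- ews_config(seed = 77, n_per_species = c(zebra = 6, wildebeest = 6))
run <- run_pipeline(cfg, n_intrusions = 4,
                    spec = behavior_spec(rf_rows = 400, rf_ntree = 40,
                                         n_clusters = 5),
                    n_features = 2, detector_repeats = 4,
                    localize_every_min = 20, duration_s = 3600)
run
#> <ews_run seed 77: behavior AP 0.767 (prev 0.132), detection acc 0.812,
#>  localization <500m 0%>
```

Reading those numbers: out-of-fold average precision of the response class
is 0.767 against a 0.132 prevalence baseline — the SVM finds the planted
flights; twofold-CV detection accuracy is 0.812 against a 0.5 coin-flip
baseline; and no intrusion is localized within 500 m at this tiny scale
(localization needs many concurrently responding sentinels; see the
methods vignette). The `analysis/` scripts run the full 40-animal,
10-intrusion configuration; their headline numbers land at behavior AP
0.900 (prevalence 0.128), detection accuracy 0.706 versus 0.564 on a
response-free null world, and localization that is scale-limited (best
surfaces within tens to hundreds of metres, but weakly identified by the
condensation criterion).

The full analysis sequence:

```sh
Rscript analysis/01_simulate_study.R     # world + segments
Rscript analysis/02_reconstruct_tracks.R # spike recall, reconstruction error
Rscript analysis/03_engineer_features.R  # feature registry + sanity checks
Rscript analysis/04_classify_behavior.R  # LOIO cross-validated SVM
Rscript analysis/05_detect_intrusions.R  # detector CV + null-world control
Rscript analysis/06_localize_intruders.R # geometry fit + error curve
```

Each script prints what it found and leaves its tables in `results/`.
Stage outputs are cached under `scratch/` so later scripts reuse earlier
stages.

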