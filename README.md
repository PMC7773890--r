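# ctxbind

Tools for studying **context binding in visual working memory**: how the
brain keeps track of *which* remembered item goes *where*, and what happens
behaviorally and neurally when that binding fails (a "swap error").

The package implements, as reusable and tested R functions, the complete
analysis path of a delayed-estimation fMRI experiment:

- **Mixture modeling of recall error.** Continuous-report errors on the
  orientation circle are decomposed into target responses (von Mises with
  concentration κ on the doubled-angle circle), non-target "swap" responses
  (probability pN), and uniform guesses (pU), fitted by maximum likelihood
  (EM with multi-start). For the two-factor model pU + pT = 1; pN is
  estimable only on multi-item trials. Subjects are grouped into low and
  high swap-error groups by extreme thresholds (pN < 0.05 vs > 0.12) or by
  a median split.
- **Univariate GLM and ROI selection.** Boxcar regressors for the 4-s
  sample, 8-s delay, and 4-s response epochs, convolved with a
  double-gamma HRF at TR = 2 s; per-voxel contrast t-maps; top-k (by
  default 400-voxel) functional ROIs; trial-averaged signal-change time
  courses baselined at the first TR of each 12-TR trial.
- **Inverted encoding models (IEM).** Channel bases of half-rectified
  cosines raised to the 7th power (9 or 6 orientation channels; 6 location
  channels on the 360° circle); mean-pattern baseline removal per run;
  weight estimation `W = B1 C1ᵀ (C1 C1ᵀ)⁻¹`; inversion
  `Ĉ2 = (ŴᵀŴ)⁻¹ Ŵᵀ B2`; location-specific models; per-trial circular
  recentering on the tested feature; and aggregation over 1°-shifted bases
  into smooth 180-point channel tuning functions (CTFs).
- **CTF quantification.** Each CTF is fitted with the exponentiated cosine
  `f(x) = α exp(κ[cos(μ − x) − 1]) + β` (μ fixed at 0) by ordinary least
  squares over a κ grid of 1..30 in 0.1 steps; α is the reconstruction
  amplitude and may be negative.
- **Bootstrap inference.** Subject-resampling bootstrap of CTF amplitudes
  (one-tailed p = proportion of resampled amplitudes ≤ 0, 2500 iterations
  by default), group-difference bootstraps, recall-specificity scores
  (probed minus randomly selected non-probed reconstruction amplitude),
  Benjamini–Hochberg FDR, repeated-measures (ANCOVA) correlation, and
  Spearman/Pearson correlations with a Shapiro–Wilk gate.
- **Synthetic-data generator.** Balanced trial schedules (e.g. 108 3O and
  360 1O trials, every orientation probed at every location equally
  often, ±1–5° jitter), mixture-generated behavioral responses with
  ground-truth component labels, and channel-tuned voxel time series with
  epoch-specific gains and Gaussian noise — so the entire pipeline is
  testable without scanner data.

## Worked example

```r
library(ctxbind)

# one synthetic subject: 108 3O trials, behavioral responses, mixture fit
sched <- make_schedule(6, 6, 3, 3, "3O", seed = 1)
prof  <- group_profile(pT = 0.8, pN = 0.15, pU = 0.05, kappa_mix = 10)
resp  <- simulate_behavior(sched, prof, seed = 3)
fit_mixture(resp, n_factors = 3, n_starts = 5, seed = 4)
#> 3-factor von Mises mixture fit (108 trials)
#>   pT = 0.811  pN = 0.174  pU = 0.016  kappa = 10.65 rad^-1
#>   log-likelihood -91.221  (converged, 5 starts)
```

The fitted proportions recover the generating regime (pT 0.81 vs 0.80,
pN 0.17 vs 0.15) and κ ≈ 10.7 vs the true 10 — at 108 trials the swap rate
carries a few percent of sampling error, which the package's
parameter-recovery tests quantify at n = 500.

A full synthetic replication — simulate two subject groups, fit mixtures,
median-split, select ROIs, reconstruct orientation and location CTFs at
the recall epoch, and run the four preplanned hypothesis tests with
bootstrap + FDR:

```r
cfg <- replica_config(n_low = 14, n_high = 13, seed = 1)
report <- run_replica(cfg, out_dir = "replica_report")
report$hypotheses        # statistic, p, FDR-adjusted p per hypothesis
```

or from a shell:

```sh
Rscript inst/scripts/run-replica.R --config config.yaml --out replica_report
```

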