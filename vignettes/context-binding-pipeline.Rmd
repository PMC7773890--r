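---
title: "Mixture models, inverted encoding, and bootstrap inference for context binding in visual working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture models, inverted encoding, and bootstrap inference for context binding in visual working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxbind)
```

## The scientific problem

In a delayed-estimation task the subject sees one or three oriented bars,
each at a distinct screen location, retains them over a delay, and then
reproduces the orientation of the item probed at one location on a
continuous wheel. Successful recall of a multi-item array requires
*context binding*: the association between each item's identity
(orientation) and its trial-unique context (location). When binding fails,
the subject reports a *non-probed* item's orientation — a swap error.

`ctxbind` implements the full analysis chain used to study this behavior
and its neural correlates: a mixture model that measures swap errors in
behavior, an inverted encoding model (IEM) that reconstructs orientation
and location information from voxel activity, an exponentiated-cosine fit
that quantifies each reconstruction, and a subject-resampling bootstrap
that tests amplitudes, group differences, and "recall specificity". A
synthetic-data generator stands in for scanner data, so every stage is
testable end to end.

## The behavioral mixture model

The signed recall error $e \in (-90^\circ, +90^\circ]$ on the
180°-periodic orientation circle is modeled as

$$p(e) = p_T \, \phi_\kappa(e) \;+\; p_N \, \frac{1}{m}\sum_{j=1}^{m}
\phi_\kappa(e - \delta_j) \;+\; p_U \, \frac{1}{2\pi},$$

where $\phi_\kappa$ is a von Mises density evaluated on the doubled
angle ($2e$, in radians), $\delta_j$ are the non-target offsets, and
$p_T + p_N + p_U = 1$. Conventions that matter:

- **Doubled-angle circle.** Orientation is 180°-periodic; all circular
  math doubles the angle onto the full circle first. The concentration
  κ (rad⁻¹) is reported on the doubled circle, which matches the
  magnitudes conventionally reported for orientation data (κ ≈ 10 is
  a precise observer; κ ≈ 2–4 a typical multi-item regime).
- **Two- vs three-factor.** Single-item trials cannot contain swaps, so
  the two-factor model fixes $p_N = 0$ and the estimates satisfy
  $p_U + p_T = 1$ exactly — a structural identity the acceptance script
  recomputes.
- **Swap component weights.** The swap density averages the non-targets
  with equal weight (uniform over the two non-probed items). Whether the
  original fits used pooled or per-item responsibilities is not
  documented anywhere we could check; pooling is the simplest
  well-defined choice and is stated here once.

Fitting is EM over component responsibilities with the concentration
updated by inverting the weighted mean resultant length (the standard
A1-inverse approximation, written in-package because no circular-statistics
dependency is available in the stack we target). Numerical choices:
κ is clipped to [0.05, 200] (the cap absorbs degenerate all-zero-error
inputs), convergence is declared at 1e-6 change in log-likelihood with a
500-iteration cap, and `n_starts = 10` random initializations guard
against local optima. The per-iteration log-likelihood trace of the
winning start is stored so monotonicity is testable.

Group classification offers the screening rule (low < 0.05, high > 0.12,
otherwise unclassified) and the median split (values at or equal to the
median go to the low group — a tie rule the data source never states;
degenerate splits are flagged).

## The inverted encoding model

Each voxel's response is modeled as a weighted sum of $k$ feature
channels whose idealized tuning curve is a half-wave-rectified cosine
raised to the 7th power, centered every $\mathrm{period}/k$ degrees.
The phrase "rectified and squared sinusoid raised to the seventh power"
in the methods lineage is internally ambiguous (squared-then-seventh would
give exponent 14); we take the total exponent on the rectified cosine to
be 7, matching the widely used implementations, and expose `exponent` so
14 can be explored.

The pipeline at one within-trial TR:

1. **z-scoring per run** (idempotent; applied automatically), then
   **baseline removal**: each run's voxels × trials matrix is projected
   onto the orthogonal complement of its mean pattern,
   $B \leftarrow B - m(m^\top B)/(m^\top m)$. The printed equation in
   parts of this literature omits the $m^\top m$ normalizer; without it
   the transform is not a projection and amplifies (and sign-flips) the
   mean-pattern component whenever $\lVert m\rVert^2 > 2$, which destroys
   decoding. The projection form is the one consistent with the
   description "orthogonalized against the mean pattern" and with the
   cited origin of the step, so it is what this package computes.
2. **Training** on the single-item condition:
   $\hat W = B_1 C_1^\top (C_1 C_1^\top)^{-1}$, the per-voxel
   least-squares solution. One model is trained per sample location for
   orientation decoding; a single model on all training trials for
   location decoding (a location-specific location decoder would see only
   one feature value).
3. **Inversion** on test data:
   $\hat C_2 = (\hat W^\top \hat W)^{-1} \hat W^\top B_2$. Exported
   `train_iem()`/`invert_iem()` refuse designs with condition number
   above 1e8; inside the shifting loop a symmetric eigenvalue-truncated
   pseudoinverse is used instead, because some basis alignments are
   legitimately near-degenerate (see below) and dropping the null
   direction is preferable to aborting or amplifying it.
4. **Recentering and smoothing.** Each test trial's estimated channel
   vector is circularly shifted so the tested feature sits at 0°, and the
   analysis is repeated with the channel centers rigidly shifted one CTF
   bin (1° for orientation, 2° for location) at a time — 180 shifts by
   default — yielding a smooth 180-point channel tuning function. Every
   estimate lands in an integer bin because stimulus jitter is integer
   degrees; bins average all estimates they receive.

Two modeling decisions deserve emphasis:

- **Jittered features.** Training and recentering use the *presented*
  (jittered) orientations. Besides realism, this matters numerically:
  with un-jittered features equal in number to the channels, the channel
  design $C_1 C_1^\top$ is exactly singular whenever the shifted basis
  sits halfway between the discrete feature values. The ±1–5° jitter of
  the emulated designs breaks that symmetry.
- **Model assignment for multi-item test trials.** The location-specific
  orientation model used for a 3O test trial is the one matching the
  *tested item's location* (probed, or the randomly selected non-probed
  item for specificity analyses). The alternative reading — assignment by
  orientation — is not well defined, since orientations are not tied to
  models.
- **Split repetition.** When training and test conditions coincide, the
  per-location pool is split 90%/10% (81/9 for 90 trials); how often that
  split is repeated is unspecified in the designs we emulate, so the
  package averages 10 seeded random splits by default (`n_splits`).
  Baseline removal is applied per run before splitting.

## Quantification and inference

CTFs are fitted with $f(x) = \alpha e^{\kappa[\cos(\mu - x) - 1]} + \beta$,
$\mu \equiv 0$, by a grid search over κ ∈ {1.0, 1.1, …, 30.0} (291
values, both endpoints) with α and β from ordinary least squares at each
grid point; the minimum-SSE triple wins and SSE ties break toward the
smallest κ (flat inputs therefore report κ = 1, α = 0). The CTF's offset
axis is mapped uniformly onto the full circle before fitting, so
orientation (±90°) and location (±180°) CTFs are both fitted over one
full period. α is deliberately unconstrained: the one-tailed bootstrap
counts amplitudes ≤ 0, so negative fits are meaningful.

The bootstrap resamples subjects with replacement (2500 iterations by
default, 500 in the test suite), averages their CTFs, refits, and reports
the one-tailed p as the proportion of amplitudes (or group differences,
low minus high) at or below zero — ties count toward the tail, as the
"≤ 0" rule implies. Subject CTFs are sorted into a canonical order before
resampling so results are invariant to input order at a fixed seed.
Recall specificity is the amplitude of the probed item's reconstruction
minus that of one randomly selected non-probed item (selection seeded,
never the probed item). The repeated-measures correlation removes
between-subject differences by centering within subject and tests the
common slope with $N(k-1)-1$ degrees of freedom; FDR control is
Benjamini–Hochberg via `stats::p.adjust`.

## What the generator emulates — and what it does not

`make_schedule()` reproduces the balanced designs (each orientation
probed at each location equally often; 108 three-item and 360 one-item
trials at the full scale; non-probed items drawn without replacement;
integer jitter uniform on ±{1..5}°; 4/8/4/8-s epochs, 24-s trials, 12
volumes at TR = 2 s, 18-trial runs). `simulate_behavior()` draws each
response from the mixture generative model and records its true
component, so recovery tests can score against ground truth.
`simulate_bold()` gives each voxel nonnegative uniform channel weights
for orientation and location, drives them with the trial's features —
sample epoch at full gain, delay epoch location-only times
`delay_location_gain`, response epoch probed/non-probed items times
`probed_gain`/`nonprobed_gain` — convolves with a canonical double-gamma
HRF (peak 6 s, undershoot 16 s) sampled at the TR, and adds white
Gaussian noise.

The default group profiles mirror the fitted behavioral means of the
median-split groups (low: pT 0.896, pN 0.012, pU 0.092; high: pT 0.700,
pN 0.169, pU 0.131) with κ = 10 during simulation of recall noise, and
encode the hypothesized neural difference as recall-epoch gains: a
strong, well-differentiated probed representation in the low group
(1.0 vs 0.1) versus a weak, poorly differentiated one in the high group
(0.5 vs 0.4), with delay-period location signal likewise stronger in the
low group (1.0 vs 0.4).

Deliberate simplifications, hence limits on what passing tests show about
real data: white noise only (no scanner noise spectrum, drift, or
physiological artifacts — though polynomial detrending is provided);
linear superposition of item signals with no surround suppression or
attention effects; no eye movements, masks, or stimulus rendering;
heterogeneous (orientation/color/luminance) trials exist only as design
labels; and per-run z-scoring removes overall gain differences between
subjects, which attenuates pure-gain group effects on *delay-epoch*
amplitudes — group effects expressed as differentiation (probed vs
non-probed) survive z-scoring, and that is what the end-to-end test
targets.

## Problem sizes used in testing

The package defaults are the full study conditions (400 voxels, 400-voxel
ROIs, 108 + 360 trials, 2500 bootstrap iterations, 180 basis shifts,
14 + 13 subjects). The test suite exercises the identical code at desk
scale, chosen once: 36 three-item and 72 one-item trials per synthetic
subject, 50–100 voxels, 30 basis shifts (the smallest multiple of the
channel spacing that still covers all 180 CTF points, each point then
receiving one estimate per location model), 500 bootstrap iterations, 100
mixture-recovery datasets of 500 trials, 50 null-calibration datasets of
14 subjects (the low-swap group size), and 100 twelve-versus-twelve
group-effect datasets. The null for calibration is voxels with zero
channel weights — pure noise; note that zeroing only the epoch *gains*
is not a null, because the always-on sample epoch leaks a small positive
amplitude into the recall-epoch TR through the HRF tail.

## Known limitations

Swap-error variants beyond the equal-weight non-target mixture are out of
scope, as are searchlight mapping, cross-TR generalization, prospective
power calculation, and anatomical-template ROI handling. The
`unclassified` band of the screening rule (pN between 0.05 and 0.12)
reflects an extreme-groups design; analyses on continuous pN should use
the correlation tools instead. NIfTI export unravels voxels onto a dummy
grid — it carries no spatial information.
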