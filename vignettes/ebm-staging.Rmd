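---
title: "Event-based staging with ebmstager: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based staging with ebmstager}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebmstager)
```

## The problem

A cross-sectional cohort — controls through dementia — observes each
subject once, at an unknown point of an underlying progression. The
event-based model treats progression as a fixed but unknown *ordering*
of biomarker events and each subject as an observation at an unknown
discrete stage along that ordering. `ebmstager` implements the linear
z-score variant: each metric's z-score rises piecewise-linearly through
several per-metric threshold events, rather than switching once between
a "normal" and an "abnormal" distribution, which lets a handful of
metrics define a fine-grained staging.

## Model and assumptions

For metrics $i = 1..I$, subjects $j = 1..J$ and stages $k = 1..N{+}1$:

$$P(Z \mid S) = \prod_{j=1}^{J}\sum_{k=1}^{N+1} p(t_j = k)\,
  \prod_{i=1}^{I}\mathcal N\!\left(z_{ij};\, \mu_i(k),\, 1\right),
  \qquad p(t_j = k) = \tfrac{1}{N+1}.$$

Assumptions worth keeping in view:

* **Signed z-scores.** Metrics are standardized by the control mean and
  SD; metrics that *decrease* with severity are sign-inverted
  ($z = (\bar x^C - x)/\sigma^C$), so "larger z = more severe" holds
  uniformly (`zscoreMetrics`).
* **Unit-variance Gaussian noise** around the stage z-score, independent
  across metrics given the stage. The synthetic cohort generator
  (`simulateCohort`) draws from exactly this model, sharing the
  stage-mean code (`stageZscores`) with the estimator so the generator
  and the model cannot drift apart.
* **Uniform stage prior**, matched by the generator's uniform true-stage
  draw. Real cohorts are not uniform over stages; the posterior is
  correspondingly diagnostic, not a prevalence estimate.
* **Event times on an integer grid.** The events of the fitted sequence
  sit at times $1..N$ with anchors at $0$ and $N{+}1$; stages sit at the
  temporal midpoints $k - \tfrac12$. The model only specifies midpoints
  between *consecutive event times*; equal spacing is the convention of
  the linear z-score EBM lineage, and only the ordering — never the
  spacing — is interpreted.
* **Full Gaussian normalizing constant** in the likelihood. It cancels
  within any fixed metric count, so grid selection is unaffected, but
  absolute log-likelihoods become comparable and reportable.

## Event thresholds: anchors and the quantile grid search

Anchors $z_{\text{initial}}, z_{\text{final}}$ are the means of the
bottom and top 10% tails of each metric's z distribution
(`anchorEvents`), computed over the full cohort — anchors must span
disease severity, which controls alone cannot. The intermediate event
thresholds are *not* fixed a priori: `quantileEventGrid` forms every
combination of `nEvents = 3` thresholds from the
$\{0.2,\dots,0.8\}$-quantiles (35 triples per metric; $35^I$ grids),
and `optimizeEventSettings` fits each grid and keeps the likelihood
winner. Sample quantiles use the type-7 (linear interpolation)
convention. Candidate grids with tied or non-monotone thresholds are
dropped with a message rather than perturbed, keeping the likelihood
search well-posed; ties in the winning likelihood are broken by
candidate order and reported.

## Sequence inference

Within a metric, events must occur in ascending z order, so a valid
sequence is fully determined by the order of *metric labels* — the
sample space is the multiset permutations, $N!/\prod_i n_i!$ of them
(`countValidSequences`). The Metropolis chain (`mcmcSequences`)
proposes swapping two uniformly chosen positions of the label vector:
every proposal is again a valid interleaving (swapping two labels of
the same metric is the identity move), the proposal is symmetric, and
with a uniform sequence prior the acceptance ratio is the likelihood
ratio — detailed balance on the valid set with no rejection bookkeeping
for invalid states. The chain records every sample (no burn-in or
thinning; the chain starts near the optimum by construction), and is
initialized by a greedy ascent from 10 random sequences, 1000
improvement-only swap proposals each by default. Positional variance
diagrams (`positionalVariance`) are sample frequencies of each event at
each position; rows and columns sum to one because each sample is a
permutation.

Likelihoods are computed in log space throughout with a per-subject
log-sum-exp; the posterior (`stagePosterior`) is normalized the same
way and cannot underflow to NaN.

## Trajectories and stage statistics

Stage values of any metric are posterior-weighted means (Eq. weighted
mean) with standard error
$SE(k) = \sigma_i \sqrt{\sum_j p_j(k)^2} / \sum_j p_j(k)$, which
reduces to $\sigma_i/\sqrt J$ under uniform weights and to $\sigma_i$
when one subject carries a stage; $\sigma_i$ is the cohort SD of the
metric (the cohort, not the controls, is the population whose spread
the trajectory summarizes). Stage composition by a categorical label
(e.g. CDR) applies the same formula to category indicators, so
fractions sum to one per stage.

Stage pairs are compared by a **conditional bootstrap**: subject values
are resampled with replacement while the posterior weights stay fixed.
Resampling severs the pairing between values and weights, so the
replicate differences $\delta x^\star$ form a *null* distribution of no
stage effect centered at zero; the two-sided p-value is twice the
smaller tail of that distribution beyond the observed difference, with
a $+1/(B+1)$ continuity floor. (A naive "does the replicate
distribution cross zero" rule would be incoherent under this resampling
scheme — the replicates are not centered at the observed difference.)
The test suite verifies type-I error within $[0.03, 0.07]$ at
$\alpha = 0.05$ over 1000 null simulations and $p < 0.001$ power for a
2-SD planted shift. The multiple-comparison family is all stage pairs
of one metric, adjusted by Benjamini–Hochberg (`bhFdr`, a validated
wrapper over `stats::p.adjust`).

## Synchrony metrics

* **AEC-c** (`aecMatrix`): band-pass both regional signals (zero-phase
  forward–backward 4th-order Butterworth — the zero-phase property
  preserves envelope timing), orthogonalize the target on the seed by
  time-domain least squares (exactly zero residual correlation with the
  seed, hence removal of any instantaneously mixed copy), take Hilbert
  amplitude envelopes of the full record (no envelope down-sampling or
  low-pass), Pearson-correlate, and average the two asymmetric
  directions into a symmetric matrix. A zero-variance residual envelope
  (exact scalar leakage) yields a flagged 0 entry with a warning, never
  NaN. Regional strengths are row means of the off-diagonal
  (`regionalConnectivity`); 94 regions contribute
  $94 \times 93/2 = 4371$ unique pairs.
* **Relative band power** (`welchPSD`, `relativeBandPower`):
  Hann-windowed Welch periodogram with 50% overlap and 2048-sample
  segments, giving a frequency step of exactly
  $f_s/2048$ (0.293 Hz at 600 Hz); band power divided by total power
  over 0.5–55 Hz (the conventional broadband pre-processing range,
  configurable). One-sided density scaling makes the PSD integrate to
  the signal variance.
* Scalar metrics (`scalarSynchronyMetrics`) average regional values
  over named ROIs.

## The signal generator

`simulateTimeSeries` builds per-region sources as band-limited
**constant-modulus carriers** (filtered Gaussian noise, twice
modulus-normalized and re-filtered) multiplied by **log-normal slow
modulators** (sub-1-Hz low-passed Gaussians, log-SD 0.7 by default).
The carrier construction keeps >99% of source power within ±1 Hz of the
band edges while making the Hilbert envelope track the modulator
directly — a plain noise carrier would add Rayleigh-distributed
envelope fluctuations that cap the achievable envelope correlation well
below the requested value. Envelope coupling is imposed on the latent
Gaussian modulators with the correlation solved analytically from the
log-normal moment formula
$\rho_u = \log\!\big(1 + \rho_e(e^{\sigma^2}-1)\big)/\sigma^2$. Because
carriers are independent across regions, coupled sources stay
uncorrelated at zero lag and their coupling *survives*
orthogonalization, while leakage injected by the instantaneous mixing
matrix does not — the contract the AEC-c tests exercise. Remaining
envelope-estimation attenuation means a requested coupling of 0.8
measures as ≈0.7 at 60 s; the test band for that scenario is
$[0.6, 0.9]$, from Monte-Carlo spread.

What the generator does **not** emulate: sensor-level physics (head
models, beamforming), 1/f background spectra, artifacts, nonstationary
band structure. Passing tests demonstrate correctness of the metrics
and staging machinery, not robustness to those real-data features.

## The cohort generator

`simulateCohort` draws uniform true stages, adds unit-scale (or
configurable) Gaussian noise to the planted stage z-scores, maps to the
raw scale with per-metric affine maps and trend directions, adds linear
covariate effects (age ~ uniform(49, 88) years, matching a typical
aging-cohort range; TIV ~ normal(1450, 120) ml; scan-date offsets ~
normal(0, 1) yr), and assigns CDR labels by thresholding the true stage
with a 10% adjacent-category flip rate emulating imperfect
stage–rating alignment. Controls are the CDR-0 subjects. Covariate
adjustment (`adjustCovariates`) fits the linear model on controls only
— a normative fit, so disease effects are not absorbed into covariate
slopes — and removes the effect with the design centered at control
covariate means, preserving the control-group mean exactly.

## Numerical conventions and degenerate inputs

* Quantiles: type 7 everywhere.
* Tail means include ties ("at or below/above" the quantile).
* Grid candidates with non-monotone thresholds: dropped, counted,
  messaged.
* Posterior underflow: impossible by construction (log-sum-exp).
* Zero-variance inputs fail loudly: degenerate orthogonalization seed,
  zero control SD, zero total power, constant anchors all raise typed
  errors; the one silent-but-warned case is the degenerate envelope
  entry in the AEC matrix, set to 0 because a single pathological pair
  should not poison a 94-region matrix.
* All stochastic functions take explicit integer seeds and are
  bit-reproducible given them; the pipeline derives per-step child
  seeds from one configuration seed.

## Problem sizes used in validation

The shipped validation runs at desk scale, chosen to exercise every
code path with exhaustively enumerable oracles: sequence-space oracles
on (3,3) and (2,2) event problems (20 and 6 valid sequences), 50,000
MCMC samples where sequence statistics are compared to enumeration,
planted-sequence recovery on 20 cohorts of J = 300 at noise SD 1
(mean Kendall tau ≥ 0.8; tau = 1 at zero noise), 1000 null simulations
for bootstrap calibration, and 10–100 Monte-Carlo seeds for the
synchrony contracts. The full-scale settings of a real analysis
(1225–42875 grids × 50,000 samples; B = 50,000) are exposed via
`defaultPipelineConfig(paperScale = TRUE)` and the `--paper-scale`
pipeline flag.

## Known limitations

* Linear covariate adjustment only; strongly nonlinear age effects
  would need a spline/GAM normative model.
* The conditional bootstrap holds the staging fixed; uncertainty in the
  posterior itself is not propagated into stage comparisons.
* Equal event spacing means stage indices are ordinal, not a clock.
* No subject-level event-time estimation, longitudinal modeling, or
  subtype mixtures (single sequence assumed).
* AEC-c orthogonalization is whole-record and time-domain; per-window
  variants exist in the literature and would differ on nonstationary
  data.
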