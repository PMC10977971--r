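# ebmstager

Event-based model (EBM) staging of disease progression from
cross-sectional biomarkers, with neural-synchrony metrics from regional
electrophysiological time courses.

## Who this is for

Cross-sectional cohorts — e.g. a memory-clinic sample spanning
cognitively unimpaired controls, MCI and dementia — carry information
about the *order* in which biomarkers become abnormal, even without
longitudinal follow-up. `ebmstager` implements the linear z-score
event-based model to recover that ordering, assign each subject a
probabilistic disease stage, and trace how any metric (gray-matter
volume, cognitive scores, MEG/EEG synchrony) evolves across the
estimated stages. It also computes the two resting-state synchrony
metrics the staging is typically fed with: leakage-corrected
amplitude-envelope correlation (AEC-c, long-range synchrony) and
relative spectral band power (local synchrony).

## The model

Each metric *i* is converted to a signed z-score against the control
group so that larger z always means more severe (metrics that decrease
with progression are sign-inverted: z = (x̄ᶜ − x)/σᶜ). An *event* is a
metric crossing a z threshold. With N events in total across metrics,
a sequence S of events defines N + 1 stages, and the data likelihood is

P(Z | S) = ∏ⱼ ∑ₖ p(tⱼ = k) · ∏ᵢ 𝒩(zᵢⱼ ; μᵢ(k), 1)

with a uniform stage prior p(tⱼ = k) = (N+1)⁻¹. The stage z-scores
μᵢ(k) interpolate each metric linearly between its own consecutive
events (anchored at the bottom/top-10% tail means), evaluated at the
temporal midpoints between event times. Inference proceeds in three
layers:

1. **Event thresholds** — an exhaustive search over all combinations of
   quantile-derived event z-scores (choose(7,3) = 35 candidate triples
   per metric; 1225 grids for two metrics, 42875 for three), keeping
   the grid with the highest likelihood.
2. **Sequence** — Metropolis MCMC over order-constrained event
   sequences (valid interleavings only; N!/∏nᵢ! of them), initialized
   by a 10-restart greedy ascent; the maximum-likelihood sequence of
   50,000 samples is kept and the sample record yields positional
   variance diagrams.
3. **Staging and trajectories** — posterior stage memberships pⱼ(k)
   normalize the stage likelihoods; any metric's stage value is the
   posterior-weighted mean x̄(k) = ∑ⱼ pⱼ(k)xⱼ / ∑ⱼ pⱼ(k) with
   SE(k) = σ·√(∑pⱼ(k)²)/∑pⱼ(k). Stage pairs are compared by a
   conditional bootstrap (resampling values, weights fixed) with
   Benjamini–Hochberg FDR control.

Synthetic-data generators (`simulateCohort`, `simulateTimeSeries`)
produce cohorts following exactly this generative model and
band-limited oscillatory signals with controlled envelope coupling and
instantaneous leakage, so every stage of the pipeline is testable with
known ground truth.

## Worked example

Plant a two-metric alternating event sequence, simulate 148 subjects,
and recover it end to end:

```r
library(ebmstager)

grid <- eventGrid(rbind(volume_loss       = c(-2, -1, 0, 1, 2),
                        cognitive_decline = c(-2, -1, 0, 1, 2)))
planted <- eventSequence(c(1, 2, 1, 2, 1, 2),
                         metricNames = rownames(gridZ(grid)))
cohort <- simulateCohort(148, grid, planted, noiseSd = 1, seed = 7)
cohort <- adjustCovariates(cohort, covariates = "age")
z      <- zscoreMetrics(cohort, setNames(rep("increasing", 2),
                                         rownames(cohort)))
grids  <- quantileEventGrid(z, levels = c(0.25, 0.4, 0.6, 0.75))
fit    <- optimizeEventSettings(zValues(z), grids, nStarts = 5,
                                ascentIter = 300, nSamples = 5000,
                                seed = 1)
fit
#> EbmFit: best of 16 grid(s), log-likelihood -497.8586, 5000 MCMC samples
#> EventSequence: volume_loss.1 -> cognitive_decline.1 -> volume_loss.2
#>   -> cognitive_decline.2 -> volume_loss.3 -> cognitive_decline.3
```

The 16-grid search recovers the planted alternating order exactly. The
staging posterior then gives probability-weighted trajectories:

```r
post <- stagePosterior(zValues(z), bestModel(fit))
weightedStageMean(SummarizedExperiment::assay(cohort)[2, ], post)
#>         stage   mean    se weight
#> stage_1     1 -2.060 0.247 19.802
#> stage_2     2 -0.964 0.164 23.861
#> stage_3     3 -0.333 0.157 23.154
#> stage_4     4 -0.040 0.149 21.778
#> stage_5     5  0.384 0.155 20.955
#> stage_6     6  0.708 0.183 20.900
#> stage_7     7  1.424 0.242 17.549
```

Six events yield seven stages; the cognitive metric climbs
monotonically from −2.1 to +1.4 raw units across them, with the
per-stage standard errors from the weighted-mean formula. `positionalVariance(fit)`
summarizes sequence uncertainty, and
`compareAllStagePairs(values, post, B = 50000, seed = 2)` tests stage
differences with q-values.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/ebm-pipeline.R all --out runs/demo --seed 7
```

writing `cohort.csv`, `zscores.csv`, `fit.json`, `posterior.csv`,
`trajectories.csv`, `comparisons.csv` and a `manifest.json` recording
parameters and seeds (reruns are bit-identical).

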