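---
title: "Correcting batch effects and run-order drift in LC-MS peak tables"
author: "msdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting batch effects and run-order drift in LC-MS peak tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdrift)
```

## The problem

Non-targeted LC-MS metabolomics experiments acquire hundreds of injections
over days or weeks. The instrument's response is not stable over that time:
the column gradually fouls, sources are cleaned, calibrations are redone.
Acquisitions are therefore grouped into *batches*, and two kinds of
technical variation contaminate the resulting peak-intensity matrix:
jumps between batches, and *drift* within a batch — a systematic,
often nonlinear change of recorded intensity with acquisition order that
can include sudden level shifts mid-batch. When the biological differences
of interest are small, this technical variation can dominate them.

The classical remedy is to intersperse identical pooled QC injections and
divide each sample's intensities by a trend fitted through the QCs.
This package implements that family, and its alternative — *background
correction*, where the trend is estimated from **all** observations
(experimental samples and QCs together). Background correction matters
because QCs can fail to represent the samples: a pooled QC made from
different material can sit at a very different intensity level per
metabolite, respond differently to drift, and — being sparse (one QC per
~6 samples) — cannot see changes happening between interspersions. In that
regime a QC-fitted trend misleads, and dividing by it can *create*
artefacts rather than remove them.

## The correction model

Everything is a ratio correction. For peak $p$, batch $b$ and observation
$i$ (counted in acquisition order),

$$X'_{p,b,i} = X_{p,b,i}\,\frac{R_p}{C_{p,b,i}}$$

where $C_{p,b,i}$ — the *trend* — is the fitted expected intensity of peak
$p$ at acquisition rank $i$, and $R_p$ is a per-feature rescaling constant
that restores corrected values (which sit near 1 after the division) to an
interpretable intensity level. A strategy is fully described by a
`TrendSpec`:

* **method** — how the trend is fitted:
  * `constant`: the mean or median of the fit subset (the per-batch QC
    average is the classical batch correction);
  * `linear`: ordinary least squares on acquisition rank;
  * `moving_median`: the median of the fit values within a rank window
    $[i-w,\,i+w]$, truncated at the batch edges. The median rather than a
    moving mean, because single high or low values (including genuine
    ones) should not drag the trend;
  * `polynomial`: degree-$n$ least squares, on ranks rescaled to
    $[-1, 1]$ for conditioning;
  * `spline`: penalized cubic smoothing spline minimizing
    $\sum_i (x_i - f(i))^2 + \lambda \int f''^2$, with $\lambda$ chosen by
    generalized cross-validation when `lambda = "auto"` (the default, via
    `stats::smooth.spline`);
  * `loess`: local linear regression at every rank over the
    $q = \lceil \alpha m \rceil$ nearest fit points, tricube-weighted,
    with no robustness iterations.
* **scope** — `qc_only` (classical QC correction) or `background`
  (all observations, QCs included).
* **application** — `batchwise` (fit and apply per batch; handles
  between-batch jumps) or `global` (the whole run as one unit).

The default pipeline, `trendSpec("spline")` with rescale mode
`all_batches`, is the batch-wise background smoothing spline — the
configuration that minimizes replicate RSD on the package's synthetic
benchmark (see `scripts/acceptance.R`).

### Ranks, not run indices

Within each fit unit the acquisition positions are recomputed as
consecutive integers $1..m$. Raw run indices would leave gaps wherever
observations were removed (outliers, other batches), and gaps distort
window- and neighbourhood-based smoothers. Rank $i$ therefore counts
*acquired observations in the unit*, which is also what a per-batch
regression on acquisition order means.

### Rescaling

`rescaleMode` controls $R_p$: the average of the fit-scope subset of the
first batch (`first_batch`, the convention that anchors everything to
batch 1), of the whole run (`all_batches`, the default), or `none`
($R_p = 1$), which leaves data on a fold-of-trend scale where a QC
corrected by its own batch mean is exactly 1. Mean-RSD evaluation is
invariant to per-feature rescaling, so the choice matters for
interpretability, not for the benchmark ordering.

### Division guards

A badly fitting trend can cross zero — a per-batch linear regression of
sparse, noisy QCs is the canonical offender. Dividing by values near zero
produces huge artificial outliers; this is a real failure mode worth
reproducing, not papering over, so the default guard (`faithful`) divides
by whatever was fitted and only *flags* cells whose factor is below
$10^{-6}$ of the unit's median positive factor. Cells with a non-positive
or non-finite factor have no meaningful ratio correction at all; they are
set to 0 and flagged, which also keeps corrected matrices valid
non-negative peak tables. The opt-in `clamp` guard instead replaces tiny
and non-positive factors by the unit's median positive factor; `faithful`
and `clamp` differ only at flagged cells. A feature whose entire fit
subset is zero in some unit is left uncorrected there (factors 1) with a
warning.

Zeros encode "not detected" and are never corrected into positive values.

## Filtering

Features near the limit of detection cannot support a trend. Before
correction, `filterFeatures()` removes features whose median QC intensity
is zero (for QC-fitted trends: half or more of the QCs saw nothing) or
whose median over all observations is zero (the background counterpart).
With an even count and exactly half zeros the midpoint median is positive,
so such borderline features are retained and listed in the report.
`workingSet()` combines this with manual removal of named outlier
observations — manual by design: outlier removal here is an inspection
decision, and an automatic rule would hide it.

## Judging a correction

Two complementary measures, both continuous:

**Mean replicate RSD** (`replicateRsd()`). For each feature and each set
of biological replicates (same experimental condition and timepoint,
randomized across batches), $\mathrm{RSD} = \sigma / \bar{\bar{x}}$, with
$\sigma$ the sample standard deviation of the set and $\bar{\bar{x}}$ the
feature's grand mean; the mean over all included (feature, set) pairs is
the score. Only sets with at least three members count; pairs are excluded
when any set value is zero in the original data, when all corrected values
are zero, or when the grand mean is zero. Replicates share their biology,
so whatever spread a correction removes was technical — but a floor of
genuine biological variation always remains. The grand mean is taken over
all experimental observations; `grandMean = "sets"` restricts it to
members of eligible replicate sets (the definition is ambiguous in the
field; both are exposed, the default is the pooled one). The sample
($m-1$) standard deviation is used, appropriate for sets of three.

**PCA-MANOVA** (`pcaManova()`). Features are centred and scaled to unit
variance, the first two principal-component scores are computed once over
all experimental observations, and a MANOVA (Wilks' $\Lambda$ with Rao's
F approximation — exact for two groups or two response columns, reducing
to the classical one-way ANOVA F for a single column) asks how much of
that dominant variance a labelling explains:
$F = \text{between-group} / \text{within-group}$ variance. Because batch
and experimental-group labellings are tested on the *same* score
coordinates, their F statistics are directly comparable: before a good
correction the batch F dominates; after it, the group F should. QCs carry
no group and are always excluded; component signs are fixed (largest
loading positive) so scores are reproducible. PCA on a two-group subset
would answer a different question (is there any separating direction
within the pair), not which variation dominates — hence the shared-axes
design.

**Parameter choice** (`gridOptimize()`). The window $w$, degree $n$ and
neighbourhood $\alpha$ are chosen to minimize mean replicate RSD over a
grid ($w \in 1..15$, $n \in 1..8$, $\alpha \in 0.05..1$ by default);
$\lambda$ is not gridded — GCV inside the spline handles it. Ties within
$10^{-12}$ break toward the smoother model (smaller $w$ or $n$, larger
$\alpha$). Note the protocol optimizes on the same data it evaluates —
deliberately so, to mirror common practice; treat the optimized RSD as an
in-sample quantity. The search is fully deterministic.

## The drift simulator

No public dataset accompanies this problem in a form with known ground
truth, so `simulateDataset()` generates one. All effects are
multiplicative (log-normal) — the correction is a ratio, so this makes a
perfect correction attainable and testable. Observed intensity is

$$\text{baseline}_p \times \text{group effect} \times
  \text{biological noise} \times \text{batch offset}_{b,p} \times
  \text{drift}(i)^{a} \times \text{measurement noise}$$

censored to 0 below a limit of detection; the exponent $a$ is 1 for
samples and `qc_drift_attenuation` for QCs, and QC rows swap the group
effect for a per-feature QC level (`qc_bias`), emulating a pooled QC made
from different material.

Defaults emulate a realistic plant-extract study and were fixed from the
study design being modelled, not fitted to any test: 7 batches of 24
experimental injections with a QC after every 6; replicate sets of three
randomized across batches; baselines log-normal
(`log-mean log(5000)`, `log-sd 1.2`, so a realistic spread of feature
intensities sits near a LOD of 500); batch offsets with a component
shared across features (log-sd 0.4) — batch effects are coherent, which
is what makes batches separate in a scores plot — plus a per-feature
component (log-sd 0.2); one drift curve per batch shared by all features
(kinds: flat, linear ramp, smoothed random walk, or a sudden level shift
at a random position; amplitude 0.6 of baseline); QC level divergence
log-sd 0.5; biological noise log-sd 0.1 and measurement noise log-sd
0.15 (a 10–15% CV). Group effects touch 25% of features; with the default
four groups they follow the factorial design of a two-stress experiment —
control, stress A, stress B, dual stress = A + B, the secondary stress at
0.4 of the primary log-sd of 0.25 — so the stress-A vs dual comparison is
intrinsically subtle and group differences stay small relative to batch
variation, the regime in which correction method choice matters at all.
`qcDivergentConfig()` is the stress-test preset: attenuation 0.2 and
alternating changepoint/smooth drift, the regime where QC-fitted trends
mislead.

Everything derives from one master seed in a fixed draw order, so a
config is exactly reproducible. The stored `SyntheticTruth` (clean
matrix, applied drift, batch offsets, group effects, QC bias) supports
recovery tests: with noise off, multiplicative offsets and linear drift,
the batch-wise background linear correction restores the clean matrix up
to one constant per feature (a ratio correction is only ever defined up
to rescaling) and drives replicate RSD to numerical zero.

What the simulator does **not** emulate: retention-time drift and peak
shape changes (assumed handled upstream by alignment/peak picking),
missing-at-random holes, correlated metabolite blocks, per-feature drift
sensitivity (the drift curve is shared within a batch), and
heavy-tailed outliers. Passing the synthetic benchmark therefore shows
the machinery behaves correctly in the intended regime, not that any
particular method will win on a given real dataset.

## Numerical choices and edge cases

* Moving-median windows truncate at unit edges (use what is available);
  at ranks without a fit point the trend is linearly interpolated between
  fit-rank values and extended flat beyond them. $w = 0$ reproduces the
  fit values — a useful identity.
* Regression and smoother trends extrapolate to ranks outside the fit
  subset's span by their own model (a QC-fitted line is evaluated at every
  sample rank, including before the first QC); factors are finite at every
  rank by contract.
* LOESS is local-linear with tricube weights on distance scaled by the
  neighbourhood radius; degenerate neighbourhoods (all weight on one
  point) are widened infinitesimally, and a rank-deficient local fit falls
  back to the weighted mean.
* A smoothing-spline penalty beyond the solver's range returns the exact
  infinite-smoothing limit, the least-squares line.
* Empty intensity cells on input are read as 0 (absence), with a count
  reported; negative or unparseable cells are errors naming the cell.
* Advisory feature bounds (m/z 80–1000, RT 1–30 min) warn, never reject.
* Conditioning injections (`role = "conditioning"`) are carried but
  excluded from every fit, rescale, filter and evaluation.

## Problem sizes

The test suite exercises the full pipeline at the simulated study's
natural size (7 x 24 samples x 300 features; 20 seeds for the ordering and
PCA-MANOVA checks, chosen to make >= 90%-style frequency statements
meaningful), and unit-level checks at 1–3 batches and 4–50 features,
where oracles by exhaustive enumeration are cheap.

## Limitations

* The hybrid scheme weighting QCs more strongly than background
  observations is not implemented.
* No robust (iteratively reweighted) LOESS, kernel regression or wavelet
  detrending.
* PCA is classical; a single gross outlier can dominate the scores
  (remove it via `workingSet()` — robust PCA is out of scope).
* The RSD optimization protocol is in-sample by design (no nested
  cross-validation).
* QC-acceptance thresholds (e.g. "keep features with QC RSD < 30%") are
  deliberately not applied; `qcRsd()` reports the quantity for inspection
  only.
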