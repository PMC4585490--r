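---
title: "Regression-based analysis of evoked MEG responses: methods and design"
author: "errcmeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression-based analysis of evoked MEG responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(errcmeg)
```

## The problem

Classical evoked-response analysis averages trials within experimenter-defined
categories and subtracts conditions. When the quantities of interest are
continuous item properties — visual complexity ratings, semantic feature
counts, word length, phonological neighborhood size, word frequency — binary
categorization discards information and forces awkward median splits.
`errcmeg` implements the regression alternative: at every sensor and every
latency, the single-trial amplitude is regressed on item-level predictors,
yielding an *event-related regression coefficient* (ERRC) time course per
predictor. ERRCs are weighted averages of trials and can be carried through
the same source-estimation machinery as ordinary evoked averages, which is
what the rest of the pipeline does: minimum-norm source estimation with dSPM
noise normalization, and bias-corrected region-of-interest (ROI) group
statistics. A synthetic-data generator with known ground truth closes the
loop, so every stage can be validated end to end without access to recordings.

## Composite predictors

Item measures arrive on incommensurable scales (ratings, counts, log
frequencies). `deriveComposite()` z-scores each measure (sample SD, n − 1
denominator), computes a PCA on the correlation structure, and uses the first
principal component's scores — re-standardized to mean 0, SD 1 — as the
composite predictor. Correlation PCA (rather than covariance PCA) makes the
composite invariant to affine rescaling of any input measure, which is the
property one actually wants when mixing a 5-point rating with a feature
count. PCA is sign-ambiguous, so the PC1 sign is oriented to load positively
on a named orientation measure (default: the first measure listed); with two
z-scored measures the loadings are always (±1/√2, ±1/√2).

Items with a missing value in any contributing measure are excluded from that
composite and recorded in `excludedItems` — no imputation is attempted,
because silently projecting partial z-scores would distort the composite's
variance.

`assembleDesign()` maps item-level composites onto trials. The design matrix
includes an intercept column by default: epochs are baseline-corrected but
the predictors are not re-centered per subject's realized trial set, so the
intercept absorbs the mean evoked response and the remaining coefficients are
interpretable as slopes in sensor units per predictor SD. The intercept
coefficient itself is the evoked grand mean and is reused for ROI
definition (below).

## ERRC estimation

Solving y = Xb by least squares for each (channel, latency) cell gives
b = Gy with G = (XᵀX)⁻¹Xᵀ. `linearEstimator()` computes G once per design
through an SVD pseudoinverse; singular values below 1e-10 of the largest are
treated as rank deficiency and reported as an error naming the collinear
columns. Surfacing collinearity loudly was preferred to silently returning
minimum-norm coefficients, because a rank-deficient psycholinguistic design
almost always indicates a data-preparation mistake rather than a modelling
intent.

Each row of G is a vector of per-trial weights: an intercept-only design
weights every trial 1/n (the evoked average), and a dummy-coded binary design
weights the categories 1/n and −1/m (`factorialWeights()`), reducing the ERRC
to the familiar condition-mean difference. The test suite verifies the ERRC
against independent per-point QR fits at 1e-10.

Sensor summaries divide each channel's series by its own baseline SD
(`snrTimecourse()`), rendering magnetometers (T) and gradiometers (T/m)
unitless and combinable, then take the RMS across channels
(`rmsAcrossChannels()`). The SNR definition — signed amplitude over baseline
SD — is chosen so that the baseline RMS is 1 by construction and the curve is
invariant to rescaling any channel. Each coefficient's SNR uses that
coefficient's own baseline segment. `findPeaks()` reports local maxima with
prominence at least 0.25 of the series maximum within a 0–300 ms window, the
pre-articulatory range within which overt-naming epochs can be analyzed
before speech artifacts dominate.

## Minimum-norm inverse and dSPM

The forward model is a fixed-orientation lead field L (one signed scalar per
source). `noiseCovariance()` pools outer products of per-trial demeaned
baseline segments and adds diagonal loading (default 0.1 of the mean
diagonal) for small-sample stability. `whitener()` computes W = Λ^(−1/2)Uᵀ
from the eigendecomposition, truncating eigenvalues below 1e-8 of the
largest, so that WCWᵀ = I on the retained subspace.

`makeInverse()` assembles M = RL̃ᵀ(L̃RL̃ᵀ + λ²I)⁻¹W with L̃ = WL, a source
prior R = σ²I scaled by the convention trace(L̃RL̃ᵀ) = n (the number of
whitened channels), and λ² = 1/SNR² with SNR = 3 by default. The SNR-based
regularization is the standard minimum-norm convention; SNR = 3 corresponds
to roughly 10% residual variance (λ²/(1 + λ²) = 1/10; the alternative
reading 1/SNR² = 1/9 ≈ 11% differs immaterially). The prior-scaling
convention had to be fixed somewhere for reproducibility; it is recorded in
the operator (`sigma2` slot).

dSPM divides each source's estimate by its noise SD under whitened unit
noise — the row norms of the kernel before the final W is folded in —
yielding unitless values with unit SD under pure noise. The test suite
verifies this calibration by simulation (per-source SDs within [0.9, 1.1]
over 10⁴ samples) together with the λ² → 0 recovery of an invertible
whitened system.

## ROI statistics

ROIs are defined from the grand-mean (intercept) dSPM map averaged across
subjects — a condition orthogonal to the predictors, so ROI placement cannot
bias predictor tests (verified by a label-permutation test). Within a
candidate region mask, the seed is the vertex with the largest time-maximum
|dSPM| (ties to the lowest id), and the ROI is the seed plus its k − 1
nearest neighbors within the mask (default k = 20 on the toy source space).

ROI intensity is the mean *absolute* dSPM over the ROI: fixed-orientation
estimates are signed and would cancel across a folded patch. The magnitude
makes the intensity positively biased even in pure noise, which is removed by
subtracting the mean over a −50..+50 ms interval straddling stimulus onset
(`windowedBiasCorrected()`); placing the bias estimate adjacent to the
analysis window makes the correction robust to slow changes in noise level,
at the cost of absorbing any true activity inside ±50 ms. Group inference is
a two-tailed one-sample t-test of the per-subject bias-corrected windowed
intensities against zero, Bonferroni-corrected over the loci tested with
each predictor (0.05 over 6 loci gives a per-test threshold of 0.008 at
three decimals).

### A calibration subtlety

Baseline correction subtracts each trial's baseline mean, which *reduces*
variance inside the baseline interval by about 1/n_b (n_b = baseline
samples) and *increases* it outside by the same order. If the bias interval
overlaps the baseline interval while the analysis window does not, the
bias-corrected null intensity acquires a small positive mean and the nominal
test size is exceeded: with a 21-sample baseline we measured a per-cell
rejection rate near 0.06 at nominal 0.05. The distortion shrinks linearly
with the baseline length (it is below half a percent for a 100-ms baseline
at 1000 Hz). The simulation experiments that check test calibration
therefore use a 200-ms pre-stimulus baseline interval ending at −100 ms —
disjoint from the −50..+50 ms bias interval — which restores the nominal
size; this mirrors estimating noise statistics from a pre-stimulus segment
that precedes the analysis windows entirely.

## Behavioral module

`filterResponses()` applies the standard exclusion sequence for naming
latencies — wrong name, hesitation/stutter, out-of-range (<300 ms or >2 s),
then per-subject ±2.5 SD outliers with mean/SD computed over that subject's
responses surviving the earlier rules. Conditioning the outlier statistics
on the post-range-filtered set was a deliberate choice: computing the SD
before range filtering would let a single 10-second response mask genuine
outliers. `latencyRegression()` is the joint OLS of item-mean latency on the
composite predictors with the overall F-test (146 items and 4 predictors
give F on (4, 141) df); stepwise selection is deliberately not implemented.

## The synthetic generator

`makeItemSet()` draws standardized predictors with a target correlation
structure via the Cholesky factor; the default targets are weak
inter-predictor correlations (|r| ≤ 0.23) with one moderate negative
visual–action correlation (−0.39), the structure typical of picture-naming
norm sets. `toyGeometry()` lays sources on a 1-D posterior-to-anterior
cortical strip partitioned into six regions (Occ, pITG, pMTG, pSTG, IFG,
vPMC) with two interleaved sensor arrays above it; `makeLeadfield()` builds
Gaussian-profile gains with per-type scales a hundredfold apart (1e-13 T vs
1e-11 T/m per unit source), alternating gradiometer polarity.

`simulateSubject()` draws trial items without replacement up to the item
count (each picture named once, as in the experiment proper) and then with
replacement; source activity is a sum of Gaussian bumps whose amplitudes
scale linearly with the item's predictor values (β source units per
predictor SD), projected through the lead field, plus independent Gaussian
sensor noise per channel kind. The default study emulates 17 subjects with
121 trials each, a visual-complexity effect at 100 ms in the occipital
region and semantic/word-form effects at 150 ms in pITG/pMTG (bump SD
20 ms, β = 1, between-subject β jitter SD 0.2), with noise SDs
(2e-13 T, 2e-11 T/m) chosen once so that the group ERRC SNR-RMS curves show
clearly prominent peaks at moderate single-trial SNR. Noise is white by
default for analytic tractability; real MEG noise is temporally colored and
spatially structured, so passing recovery tests here demonstrates
correctness of the estimators, not field-realistic operating
characteristics. Per-subject seeds are drawn from the master-seeded RNG, so
one master seed reproduces an entire study.

## Problem sizes used in the validation experiments

The simulation experiments in the test suite and the acceptance script use:
20 master seeds × 17 subjects × 121 trials on a 120-source / 64-channel
geometry at 250 Hz for latency and locus recovery (recovery is demanded in
at least 90% of seeds, latencies within ±10 ms); 500 null studies × 17
subjects × 60 trials on a 24-source / 16-channel geometry at 200 Hz for
test-size calibration; and analytic identities (whitening, unregularized
recovery, dSPM scaling, ERRC–OLS equivalence) at small fixture sizes. These
sizes were chosen to give stable Monte-Carlo estimates while keeping a full
validation run in the minutes range on one core. For the locus checks, each
coefficient is tested in a ±15 ms window centred on its own group SNR-RMS
peak — the same peak-driven window placement that motivates a 130–160 ms
window when the dominant peaks sit near 150 ms.

## Known limitations

* No anatomical forward modelling: the lead field is an input or a toy
  construction; BEM/FreeSurfer processing, coregistration and morphing are
  out of scope, and group analysis assumes a shared source space.
* No SSS/tSSS, movement compensation, bad-channel interpolation or
  ICA-based artifact removal; rejection is peak-to-peak thresholding only.
* The noise model is Gaussian and, by default, white in time; oscillatory
  background and physiological artifacts are not simulated.
* Sensor-space statistics are not implemented beyond SNR summaries;
  inference lives in source space at Bonferroni-corrected ROI level, without
  cluster-based or permutation alternatives.
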