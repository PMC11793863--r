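---
title: "Predicting antidepressant treatment response from fNIRS and miRNA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting antidepressant treatment response from fNIRS and miRNA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirstreat)
```

## The problem

About half of patients with major depressive disorder do not respond
adequately to their first antidepressant. An objective pre-treatment marker
of antidepressant treatment response (ATR) would let clinicians triage
patients into non-responders (NR, HAM-D reduction below 25% after six
months), partial responders (PR, 25-50%, both boundaries inclusive) and
responders (R, above 50%) before committing to a treatment course.

`nirstreat` implements a complete three-level ATR prediction pipeline from
two inexpensive pre-treatment measurements:

* a 52-channel functional near-infrared spectroscopy (fNIRS) recording of
  the prefrontal cortex during a 60 s verbal fluency task (VFT), and
* a three-miRNA expression panel (hsa-miR-550b-2-5p, hsa-miR-125a-5p,
  hsa-miR-374b-3p).

The methodological core is a *reference-group PCA* routine: principal
components are fitted on the non-responders' feature matrix and the leading
subspace holding 99% of the explained variance -- which is dominated by
inter-subject nuisance variability rather than treatment-response
information -- is discarded before classification.

## Signal model and preprocessing

Raw dual-wavelength intensities (695/830 nm, 10 Hz) are converted to
optical density, `dOD(t, lambda) = -log10(I / I0)`, with `I0` the mean
intensity over the whole recording. The chain then applies, in fixed order:

1. **Motion detection** (`detect_motion`): sliding-window peak-to-peak
   excursions beyond `std_thresh` robust standard deviations (1.4826 MAD;
   the robust scale keeps the artifacts themselves from inflating the
   reference) or an absolute OD threshold, dilated by `t_mask`. Defaults
   (`t_motion` 0.5 s, `t_mask` 1 s, `std_thresh` 20, `amp_thresh` 5) are
   conventional starting points and fully configurable.
2. **Spline correction** (`correct_motion_spline`): within each flagged
   segment a smoothing spline (p in (0, 1], near-interpolating at the 0.99
   default) is subtracted and the segment re-levelled to the preceding
   clean segment's mean (the following one at the recording start).
   Unflagged samples outside segments are untouched.
3. **Wavelet correction** (`correct_motion_wavelet`): a periodized
   Daubechies-4 transform; detail coefficients outside the per-level
   interquartile fence (Q1 - 1.5 IQR, Q3 + 1.5 IQR) are zeroed. Only levels
   at artifact timescales (<= 4 s by default) are fenced, so slow
   hemodynamics pass through bit-exact; a C1 Hermite bridge closes the
   periodization boundary so clean smooth signals reconstruct to machine
   precision.
4. **Linear detrend** and a **zero-phase Butterworth band-pass**
   (5th-order high-pass at 0.01 Hz, 3rd-order low-pass at 0.1 Hz, each
   applied forward-backward). Zero-phase filtering preserves task timing.
   Two numerical notes: the channel mean is removed before filtering (the
   recursion at a 0.002 normalized cutoff is ill-conditioned, and an exact
   DC null is wanted), and because of that conditioning, linearity of the
   filter holds to about 1e-3 relative accuracy rather than machine
   precision.
5. **MBLL conversion** (`od_to_hemoglobin`): each wavelength's dOD is
   divided by the age- and wavelength-dependent differential pathlength
   factor `DPF = alpha + beta * age^gamma + delta * lambda^3 +
   epsilon * lambda^2 + zeta * lambda`, the 2x2 extinction system is
   solved, and the result divided by the 3 cm source-detector distance,
   giving molar dHbO/dHbR. The cubic DPF coefficient defaults to
   `-5.723e-7`; the `-5.723e-3` variant found in some transcriptions gives
   DPF around minus three million and is rejected unless explicitly forced.
   Extinction coefficients ship as editable configuration; the absolute
   concentration scale follows them.
6. **Two-point baseline correction**: the line through (center of the 10 s
   pre-task window `b1`, its mean) and (center of the 55 s post-task window
   `b2`, its mean) is subtracted, nulling both window means exactly.
7. **Channel QC** (`channel_qc`): spectral SNR = Welch band power below
   0.1 Hz over band power above 4.5 Hz, computed on the motion-corrected OD
   *before* the band-pass (afterwards the reference band is empty); the
   amplitude criterion is the min-max range of dHbO against 1.5e-3 M.
   The default discards channels with SNR below 10 *or* range above the
   amplitude limit. A literal mode that discards high-SNR channels instead
   is retained behind a flag for comparability, but as a default it would
   discard exactly the best channels. Whether SNR should be computed
   before or after band-passing is genuinely ambiguous; both orderings are
   supported and the pre-band-pass default is documented here.

A note on amplitudes: the 0.01 Hz high-pass attenuates the sustained
component of a 60 s block response heavily -- the recovered peak of a clean
synthetic response is roughly a fifth of the planted amplitude. This is a
property of the prescribed filter, not a defect; the round-trip tests
therefore compare the pipeline against an independently filtered version of
the planted response rather than against its raw amplitude, and absolute
activation values should always be interpreted relative to the filter
response.

## Features

**Time domain (13 per subject).** The QC-surviving in-use channels are
averaged into a single prefrontal dHbO trace first, keeping the total
feature count at 13; the features are statistics of the task-period trace:
mean, SD, variance, coefficient of variation, min-max range, peak
amplitude, time to peak, power-weighted centroid time, trapezoidal AUC,
onset slope (first 10 s of task), recovery slope (first 10 s post-task),
skewness and excess kurtosis. Amplitude-bearing features are reported in
micromolar, times in seconds. Zero-variance traces define CV, skewness and
kurtosis as 0. The set is pluggable, so an alternative feature list can be
substituted via the extraction function without touching the rest of the
pipeline.

**Functional connectivity (7 per subject).** The task segment (baselined
against 1 s flanking windows) of all 32 in-use channels enters a Pearson
correlation matrix; QC-discarded channels are first reconstructed as the
mean of their kept neighbors (neighbors share an optode and run
perpendicular to the channel -- the cross of four channels around it in the
probe grid -- and reconstructed channels never donate to one another).
Negative correlations and the diagonal are zeroed. The matrix is binarized
by **orthogonal minimal spanning trees**: successive edge-disjoint MSTs on
distance 1/weight are aggregated while tracking global cost efficiency
(weighted global efficiency of the union minus the fraction of total
positive weight spent), and the union with maximal GCE is kept. On the
binary graph, seven metrics are computed: degree assortativity (0 when
degenerate, e.g. regular graphs), mean local clustering, characteristic
path length, global efficiency, mean local efficiency (efficiency of each
neighborhood subgraph), greedy modularity, and small-worldness sigma
against 10 degree-preserving rewired references (seeded; defined as 0 for
triangle-free graphs).

The montage deserves a design note. The probe is the standard 3 x 11
alternating source-detector grid (33 optodes, 52 channels); the 20 channels
touching the two lateral optode columns on each side sit over T3/T4 and are
excluded, leaving 32 prefrontal in-use channels. The packaged file numbers
the in-use channels C1..C32 row-wise over the central sub-grid and the
lateral channels C33..C52. Under a naive "shares an optode" rule every
interior channel would also neighbor the collinear channel sharing its
middle optode; the packaged rule additionally requires perpendicular
source-detector axes, which reproduces the intended cross-shaped
neighborhood (C14 has exactly C7, C8, C20, C21) and gives corner channels
two neighbors. Users may supply their own montage YAML.

## Inter-subject variability reduction

Let `X` (subjects x features) be the fNIRS feature matrix. The basis is
fitted on the NR rows only: features are z-scored with NR statistics,
principal components ordered by explained variance, and the smallest `k`
with cumulative explained variance at or above `theta = 0.99` discarded.
The retained matrix `V` (components k+1..n) spans the directions in which
non-responders are most similar to one another; projecting all groups
through the identical `V` (`P = X V` after the same z-scoring) removes the
dominant nuisance axes -- per-subject gain, global physiological state --
while preserving directions in which the other groups deviate from the NR
cluster. Component signs are fixed (largest-magnitude loading positive) so
bases reproduce across linear-algebra backends; covariance PCA with divisor
m-1 is used, which on z-scored data coincides with correlation PCA.

Two ambiguities were resolved as follows. Z-scoring uses NR-only statistics
(consistent with fitting `V` on NR only; pooled statistics would leak group
composition into the transform). And by default the basis is fitted on all
NR subjects *before* cross-validation -- replicating the original modelling
workflow, with a warning, since reference subjects appear in test folds; a
`leakage = "fold_safe"` mode refits the basis inside every training fold
for an honest generalization estimate.

The ablation modes (`include`-leading versus `exclude`-leading, theta 0.95
or 0.99) exist to demonstrate the mechanism: projections onto the *leading*
subspace should classify worst, and discarding more of it should help.

## Classification and evaluation

Projected fNIRS features are concatenated with the three miRNA values
(passed through unmanipulated; an RBF kernel is scale-sensitive, so an
optional standardization flag exists but is off by default for fidelity to
the modelling workflow the pipeline replicates). An RBF-SVM
(one-vs-one for three classes, features unscaled) is trained under
stratified 5-fold cross-validation with a seeded random search over 1000
candidates, box constraint and kernel scale log-uniform on [1e-3, 1e3]; the
winning candidate minimizes mean CV error plus one standard error (an
upper-confidence-bound rule; ties go to the earliest candidate), echoing a
"best point" Bayesian-optimization selection under a fixed budget -- the
contract here is the budget, the seed and the selection rule, not a
specific optimizer. Stratification is used because with 13 subjects in the
smallest class unstratified folds can lose a class entirely.

Evaluation pools out-of-fold predictions into one confusion matrix. For
class i, TP/FN/FP/TN are the one-vs-rest counts; accuracy is the trace over
n, and sensitivity, precision and specificity are macro-averaged
(unweighted means over classes). Undefined precisions (a class never
predicted) are set to 0 with a warning so macro averages stay defined.
Binary mode merges PR into R before training; balanced mode down-samples
every class to the smallest class size (13 at the default cohort
composition) with a seeded draw.

`feature_diagnostics` reproduces the screening toolkit: per-feature one-way
ANOVA, k-means silhouette (squared Euclidean) for k in 2..4, and the count
of feature pairs with |r| > 0.7.

## The synthetic cohort generator

No clinical recordings ship with the package; `simulate_cohort` generates
cohorts (default 52 subjects: 24 NR, 15 PR, 13 R; ages uniform on 21-49)
with the statistical structure the method presumes, so that every stage and
the headline mechanism are testable end to end.

Per subject, ground-truth dHbO per channel is

* a double-gamma HRF convolved with the 60 s task boxcar, whose *shape*
  carries group information (peak latency 5.5/7.0/8.5 s and undershoot
  0.35/0.20/0.08 for NR/PR/R; small within-group jitters of 0.25 s and
  0.03),
* times a group amplitude (0.30/0.33/0.36 uM) and a **dominant log-normal
  subject gain** (sdlog 0.6) -- the first planted nuisance,
* plus band-limited (0.02-0.09 Hz) latent fluctuations shared across
  channels: a global source and four block-level sources whose total
  variance share (0.65) is scaled by a **log-normal subject synchrony
  factor** (sdlog 0.5, the second nuisance) while the *balance* between
  global and block coupling carries the group effect (0.98/0.80/0.60 for
  NR/PR/R, jitter 0.02): non-responders behave as one globally
  synchronized network, responders reorganize toward subnetworks at similar
  total synchrony,
* plus physiological noise -- linear drift, a 0.1 Hz Mayer wave with its own
  log-normal subject gain, 0.25 Hz respiratory and 1.1 Hz cardiac tones,
  and a 0.01 uM white noise floor chosen so channel SNR spans the tens to
  hundreds and the QC stage drops an occasional channel rather than whole
  neighborhoods,
* plus seeded motion spikes (0.4 per minute, 3 uM, 0.2-1 s).

dHbR is the typical anticorrelated -1/3 mirror of dHbO plus noise (the
downstream analysis uses dHbO only, so this choice exercises the MBLL
plumbing rather than the science). The forward MBLL maps concentrations to
OD and intensities (`I = I0 * 10^-dOD`, per-channel log-normal `I0`).
miRNA values are log-normal with group-shifted means, reported on the log
scale (relative expression, the customary qPCR normalization; shifts
0.5-1.0 log units against a 0.5 within-group SD, giving miRNA-alone
accuracies in the high 60s). HAM-D pairs are drawn inside each group's
reduction band so re-annotation reproduces the planted label exactly.

The nuisance factors (gain, synchrony, Mayer gain) are deliberately much
larger than the group effects, which is the premise of the reference-PCA
method: they load a low-rank, high-variance subspace of the feature matrix
that the 99% rule removes, while the group effects (coupling balance, HRF
shape) live in directions of near-zero NR variance that survive into the
retained subspace. At these defaults, across seeds 1-5 with the
100-candidate search budget, multimodal accuracy with the projection
exceeds raw fusion by 12-29 percentage points, and the ablation medians
order exclude-99 >= exclude-95 >= both include modes -- the mechanism the
acceptance suite asserts.

What the generator does *not* emulate: scalp/superficial-layer
contamination and short-separation channels, realistic optode-coupling
drift, subject head motion correlated across channels, non-Gaussian miRNA
measurement error, or any correlation between miRNA and fNIRS nuisance.
Passing tests therefore demonstrate the pipeline's correctness and the
mechanism's operation under the assumed statistical structure, not clinical
performance on real data.

## Numerical choices and degenerate inputs

* OD conversion rejects nonpositive intensities by channel and sample.
* Motion-spline segments shorter than four samples fall back to constant
  replacement; `p` outside (0, 1] is an error.
* The OMST loop breaks ties by construction order (edges are built in
  channel order); disconnected positive graphs are an error advising
  subject exclusion, and reconstruction failure (a discarded channel with
  no kept neighbor) by default fails the subject, mirroring the exclusion
  of incomplete measurements.
* `fit_projection` refuses zero-variance reference features and the
  degenerate `k = n` case (nothing retained); `theta = 0` retains all
  components.
* Classification requires at least `folds` subjects per class; evaluation
  defines undefined ratios as 0 with warnings rather than dropping
  classes.
* All stochastic steps (folds, candidate draws, down-sampling, rewired
  reference graphs, the simulator) derive from explicit seeds and restore
  the caller's RNG state.

## Problem sizes used in the test-suite

Unit tests run on one- to six-channel fixtures and graphs of up to six
nodes (where exhaustive enumeration is feasible); pipeline-level tests use
a reduced 20-subject cohort with a 10-15 candidate search; the acceptance
suite runs the full 52-subject cohorts across five seeds with a
100-candidate search, the budget at which the mechanism results above were
measured. These sizes are the package's chosen trade-off between coverage
and turnaround; all of them are parameters, not limits.

## Known limitations

* The exact identities of the 32 in-use channels, the 13 time-domain
  features and the 7 network metrics are package defaults anchored to the
  documented counts and named exemplars (centroid, coefficient of
  variation, assortativity); all three sets are configuration points.
* The replication-mode projection leaks reference subjects across CV folds
  by construction; use `fold_safe` for honest estimates.
* Absolute hemoglobin scale depends on the extinction-coefficient
  configuration and on the heavy band-pass attenuation of block designs.
* SNIRF/HDF5 containers are not read natively; recordings travel as the
  documented CSV + JSON sidecar dialect.
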