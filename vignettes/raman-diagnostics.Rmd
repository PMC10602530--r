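---
title: "Single-cell Raman diagnostics for fatigue disease cohorts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell Raman diagnostics for fatigue disease cohorts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrsdx)
```

## The problem

Myalgic encephalomyelitis / chronic fatigue syndrome (ME/CFS) lacks an
objective diagnostic test; diagnosis rests on questionnaires and exclusion.
Single-cell Raman microspectroscopy of peripheral blood mononuclear cells
(PBMCs) offers a label-free molecular fingerprint of individual immune cells:
a single-cell Raman spectrum (SCRS) is the average of several point spectra
acquired within one cell, and its band intensities act as relative
concentration proxies for intracellular metabolites. `scrsdx` implements the
full analysis chain needed to evaluate such a diagnostic: simulation of
realistic cohorts, chemometric preprocessing, band quantification with group
statistics, discriminant visualization and feature selection, a stacked
ensemble classifier from cell to subject level, and ordinal symptom-burden
statistics.

Because the real cohort data are an external deposit, the package ships a
first-class synthetic cohort generator whose defaults mirror the study
design: 98 subjects — 16 healthy controls (HC), 61 ME/CFS patients split by
severity (25 mild, 15 moderate, 21 severe, graded by the SF-36 Physical
Function score with 25 as the mild/moderate boundary), and 21 multiple
sclerosis (MS) patients as disease controls — with about 30 cells per subject
and 5–10 acquisitions per cell on a canonical axis of 1019 channels spanning
319–3401 cm⁻¹ (step ≈ 3.027 cm⁻¹).

## The synthetic cohort model

Each acquisition of cell $j$ from a subject in group $g$ is

$$ y(\nu) \;=\; s \sum_k A_k \, f_{k}(g)\, c_j \, b_{jk}\,
   \mathcal{L}(\nu;\,\nu_k,\gamma) \;+\; B(\nu) \;+\; \varepsilon(\nu), $$

where $\mathcal{L}$ is a Lorentzian line with FWHM $2\gamma = 10$ cm⁻¹ (a
typical cellular Raman linewidth), $A_k$ are library peak heights,
$f_k(g)$ are the group effect factors (1 for every generic band and for the
HC column), $c_j \sim \mathrm{LN}(0, 0.15)$ is a latent per-cell
concentration shared by all of the cell's acquisitions (this is what makes
SCRS averaging meaningful), $b_{jk} \sim \mathrm{LN}(0, 0.10)$ is per-cell
band-level biological variability, $s \sim \mathrm{LN}(0, 0.10)$ is a
per-spectrum scale (focus/laser fluctuation), $B$ is a random positive
5th-order polynomial autofluorescence baseline with amplitude uniform in 0–5
times the mean peak height, and $\varepsilon \sim N(0, 0.05^2)$ a.u. is
additive noise. Cosmic-ray spikes hit each spectrum with probability 0.05 at
a single random channel, with amplitude 30–120 times the noise scale. The
peak library couples the eight biomarker bands (glucose 405, glycogen 485,
cholesterol/CE 617, tryptophan 758, tyrosine 860, phenylalanine 1003,
glycerol 1114, unsaturated fatty acids 3010 cm⁻¹) with ~20 generic cellular
bands shared identically across groups, so a classifier must find the
informative channels rather than any channel.

The default effect directions encode the reported disease phenotypes:
tryptophan, tyrosine and glycerol up in all disease groups; phenylalanine
down in moderate/severe ME but up in mild ME and MS; unsaturated fatty acids
up in mild ME/MS, down in moderate/severe ME; cholesterol down everywhere and
most strongly in MS; glycogen down in mild/severe ME and MS; glucose down in
all disease groups with MS lowest. (The source literature is internally
inconsistent on the tyrosine direction — its results section reports an
increase, its discussion a decrease; the generator follows the results.)

Clinical scores use *median-anchored stratified assignment*: within each
group the middle order statistic(s) are pinned at the configured median
(Fatigue Severity Scale 59 for every ME subgroup, 54 for MS, 17 for HC) and
the two halves are filled through a piecewise-linear inverse CDF over the
configured range, then permuted across subjects. Medians are therefore exact
at any group size — including the even-sized HC group, where i.i.d. draws or
plain rank-quantile assignment would round away from the target. Because
every ME subgroup (25/15/21 subjects, all odd) has its middle value pinned at
59, the pooled 61 ME subjects have median 59 exactly. The 63-variable ordinal
symptom table (0 absent – 3 severe) draws entries from Binomial(3, p) with
group propensities rising with ME severity and an MS propensity declining
along a per-variable "ME specificity" gradient; missingness is MCAR at rate
0.05. MCAR was chosen because the study reports missing cells but no
mechanism.

```{r cohort}
coh <- generate_cohort(cohort_config(seed = 1))
coh
median(coh$subjects$fss[coh$subjects$group %in% c("MildME", "ModME", "SevME")])
```

## Preprocessing

The chain is resample → despike → polyline baseline → SNR quality control →
per-cell averaging → vector normalization.

**Despiking.** A channel is flagged when its residual from a 5-channel
running median exceeds 8 times a local scale, and replaced by the
running-median value. The local scale is the MAD of the *intensities* in a
25-channel window. This choice is deliberate: a scale based on residuals is
near zero beside a narrow peak in clean data, so genuine peak tops (FWHM 10
cm⁻¹ is only ~3 channels at the canonical step) would be clipped, whereas the
intensity MAD is large near real spectral structure and noise-sized in flat
regions. A strict inequality makes constant spectra a fixed point while a
lone spike on a constant background is still removed exactly. One limitation
is irreducible: replacement cannot restore the specific noise value the spike
destroyed, so a despiked channel differs from its uncontaminated counterpart
by O(noise SD); tests assert suppression to that scale (and a >20-fold
reduction versus uncorrected spikes), not exact recovery.

**Polyline baseline.** The axis is split into 12 equal spans; the minimum
point of each span is an anchor, and the first and last channels are always
anchored so the piecewise-linear baseline covers the whole axis (this also
makes the correction exact for affine trends, which the test suite pins).
Corrected intensities are clipped at zero.

**Quality control.** SNR = (maximum baseline-corrected intensity in
1420–1470 cm⁻¹, the CH₂ deformation band) / (SD in 1800–2600 cm⁻¹, the
biologically silent region); spectra under SNR 3 are discarded. The source
names the QC step but no threshold; 3 is a conventional detection limit.

**Averaging and normalization.** Acquisitions of a cell are averaged into the
SCRS, which is then vector-normalized to unit L2 norm over the entire
spectral region (fingerprint-only normalization is selectable). Normalizing
after averaging was chosen (and is pinned by tests) because the downstream
analysis operates on SCRS; per-acquisition normalization before averaging is
available via `normalize_per = "acquisition"` since the source is ambiguous
about the order.

## Quantification and group statistics

Band values are trapezoid integrals of the SCRS minus a local chord joining
the window's endpoint intensities — a window-local background subtraction
that makes the statistic robust to residual baseline; a constant spectrum
integrates to zero. Default windows are ±8 cm⁻¹ around the single
characteristic wavenumbers above; the alternate multi-band "methods" profile
(tryptophan 758/880/1013/1550 + 1022–1036; phenylalanine 1003 + 1032;
tyrosine 642/830/850) is kept in the registry because the two published band
lists disagree. Group comparisons use Welch's two-sample t-test against HC
with Welch–Satterthwaite degrees of freedom and the star convention ns /
\*\* (p<0.01) / \*\*\* (p<0.001) / \*\*\*\* (p<0.0001). Cell-to-cell
fluctuation of a group is summarized as
$100 \cdot \sum_\nu \mathrm{SD}(\nu) / \sum_\nu |\mathrm{mean}(\nu)|$
(sample SD), which is invariant under uniform rescaling.

## Discriminant analysis

`fit_lda()` solves the between/within generalized eigenproblem with the
within-class covariance shrunk toward a scaled identity by a Ledoit–Wolf
intensity estimated from the within-class deviations — necessary because the
1019 channels far exceed the cells per class. Directions are
unit-normalized with the sign fixed so the largest-magnitude coefficient is
positive; explained-variance ratios are eigenvalue fractions over the
retained axes (at most one fewer than classes). Subject-level fits average
each subject's cells first. `top_features()` ranks channels by
|coefficient| on a chosen axis (ties break toward the lower wavenumber);
this channel-space use of LDA for feature selection is distinct from the
classifier's LDA, which runs on PCA scores. `confounder_scan()` reports
Pearson correlations of covariates (one-hot expanded where categorical)
against LD coordinates, flagging |r| > 0.75.

## The two-layer ensemble classifier

`fit_ensemble()` implements the full training protocol: a stratified 80/20
train/test split; centering, unit-variance scaling and PCA to at most 100
components fitted on the train partition only; eight base learners — LDA,
extreme gradient boosting, linear- and radial-kernel SVM, a single-hidden-
layer perceptron, random forest, mixture discriminant analysis, and a
gradient boosting machine — evaluated by stratified 10-fold cross-validation
with 5 repeats; and a GBM meta-learner stacked on the out-of-fold class
probabilities (8 × C columns). Out-of-fold probabilities rather than hard
labels are used as meta-features because they carry strictly more
information. Only the perceptron's hidden size is tuned (grid {8, 32, 64},
chosen by mean CV accuracy); the other learners use fixed documented
settings in `ensemble_control()`.

Two components are implemented in the package rather than imported. The GBM
is stagewise multinomial-deviance boosting with depth-3 rpart trees and
Friedman's one-step Newton terminal-node updates (learning rate 0.1, 100
rounds); it is cross-checked in tests against xgboost as an independent
boosting implementation. MDA models each class as a Gaussian mixture
(default 3 subclasses) with a covariance shared across all subclasses,
fitted by EM (k-means initialization, 100-iteration cap, 1e-6 relative
log-likelihood tolerance); with one subclass it reproduces `MASS::lda`
posteriors, which the tests assert.

Split grouping defaults to the *subject*: all cells of one subject stay in
one partition, preventing within-subject leakage from inflating test
accuracy. A per-cell split (`grouping = "cell"`) is available since the
source protocol does not state its grouping. Cell probabilities aggregate to
subject diagnoses by a GBM over per-subject predicted-label fractions
(trained on the train subjects) when at least 20 train subjects exist,
otherwise by mean cell probability; ties break toward the fixed class order
HC < MildME < ModME < SevME < MS and are flagged. Collapsing the three ME
subgroups by summing their probabilities gives exactly marginalized
three-class output. Evaluation reports a row-percent confusion matrix,
one-vs-rest sensitivity/specificity, and overall accuracy with its exact
Clopper–Pearson 95% interval.

## Clinical symptom statistics

Symptom screening compares severe ME against MS: per variable, the relative
mean ordinal intensity is computed per group (missing entries excluded
pairwise) and the fold ratio uses a pseudo-count of 0.05 to guard zero
denominators; variables with fold ≥ 1.5 are included. Fisher's exact test is
computed by full hypergeometric enumeration on the presence/absence 2×2
table (presence = ordinal ≥ 1, i.e. "mild" or worse — the source does not
state how 4-level data entered a 2×2 test) and adjusted by Benjamini–
Hochberg; tests verify the enumeration against `fisher.test` across all
small-margin tables and the adjustment against the hand step-up formula.

## Numerical choices and problem sizes

All randomness flows from a single integer seed through a deterministic
sub-stream scheme (`spawn_seed`), so cohorts are byte-reproducible and a
spike-free twin cohort shares every other draw with its spiked counterpart.
The test suite exercises the pipeline at reduced scale chosen to keep the
full run in minutes on one CPU: cohorts of 3–10 subjects per group with
2–10 cells each for pipeline properties, 100 cells per group for
effect-direction recovery, 5-fold × 1–2-repeat CV with reduced tree counts
for ensemble behaviour (defaults remain 10 × 5 and 100 trees), and ten seeds
for the stacking-dominance property on a constructed five-class task whose
linear, XOR-mixture and annulus structures are deliberately complementary
across learner families.

## What passing tests do and do not show

The generator emulates group-specific band effects, fluorescence baselines,
shot-like noise, per-spectrum scale and cosmic spikes — but not instrument
physics (CCD response, grating dispersion, wavenumber miscalibration),
immune-cell-subtype mixtures, batch or storage-duration effects, or
subject-level random effects beyond cell sampling. Passing tests therefore
demonstrate that the implementation is correct and that the method recovers
known structure under these assumptions; they do not certify the headline
diagnostic accuracies of the real cohort, which depend on the deposited
measurement data and are outside the package's reproducible surface. The
real-data figures quoted in the literature (e.g. 91% three-class accuracy)
require downloading that deposit and are intentionally not asserted anywhere
in this package.

## Known limitations

- Despiked channels carry O(noise SD) replacement error (see above); spikes
  landing inside strong peaks whose local MAD is large may evade detection,
  though their effect is bounded by the same local scale.
- The polyline baseline anchors at terminal channels, which can inflate the
  baseline when a real band sits exactly at an axis end; negatives are
  clipped.
- MDA's shared covariance is estimated with an unbiased pooled divisor and a
  tiny ridge; for heavily rank-deficient inputs the model relies on the
  PCA transform upstream.
- The repeated-split scheduler cycles seeds; it does not guarantee that
  every cell enters a test set at least once for arbitrary split counts.
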