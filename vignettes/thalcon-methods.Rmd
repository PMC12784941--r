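---
title: "Quantifying lateralized thalamic pathology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lateralized thalamic pathology: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`thalcon` quantifies lateralized secondary thalamic pathology after an
experimental focal brain injury from four observation channels — resting-state
fMRI connectivity, TSPO-PET tracer uptake, diffusion-tensor scalar metrics,
and Nissl/myelin histology — and asks one question of them jointly: do the
ipsilateral-minus-contralateral differences (the Δ lateralization indices)
of the structural, functional and cellular metrics track the lateralized
subacute neuroinflammation measured by PET? This vignette explains each
stage's model and assumptions, the parameters that matter, what the
synthetic cohort emulates (and does not), and the design decisions taken
where the methodology was genuinely open.

## Study design encoded in the package

The design the defaults encode: two groups (36 injured, 11 sham-operated
rats), four imaging timepoints — baseline (BL), two weeks (W2), two months
(M2) and six months (M6) post-injury — and six regions of interest: the
ipsilateral and contralateral ventral posterior nucleus (`VPNi`, `VPNc`)
and lateral nuclei (`LNi`, `LNc`) of the thalamus, and the bilateral
retrosplenial (`RS`) and cingulate (`CG`) cortices. PET is acquired at W2
in a subgroup (25 injured + 9 sham), of which 7 + 1 scans fail injection
QC; terminal histology is available for 14 + 6 of the PET-successful
animals. fMRI scans are 1500 volumes at TR = 1 s.

## Functional connectivity

**Framewise displacement.** Per-volume head motion is summarized
Power-style: the sum of absolute backward differences of the three
translations plus the rotation differences converted to arc length on a
sphere of radius `rotation_radius_mm`. The default radius is 5 mm — a
rat-brain scale rather than the 50 mm human convention — and is exposed as
a parameter because any radius merely reweights rotations against
translations. The first volume is assigned zero. This rigid-parameter
formula is a deliberate, oracle-checkable choice; image-based FD variants
exist but depend on the registration stack rather than on the motion
parameters the pipeline actually consumes.

**Least-motion segment.** Connectivity is computed on the contiguous
300-volume (5 min) window minimizing mean FD, with the first 300 volumes
excluded to avoid lingering anesthesia effects. "Least motion" is
operationalized as minimum *mean* FD because mean FD is the same summary
used for motion QC; ties break to the earliest admissible start, and a
small numerical tolerance makes the tie-break robust to floating-point
noise in the running sums. Volumes are indexed 1-based in the R
convention, so the earliest admissible window is volumes 301–600.

**Scan-level QC.** Scans in which ICA-based motion correction removed more
than 20 of 30 components are discarded outright; the threshold is strict,
so exactly 20 removed components is retained. Mean and maximum FD are
reported both over the whole scan and within the selected window, since
either convention is defensible for QC reporting.

**Motion regression and correlation.** Within the selected window each ROI
series is regressed on an intercept plus the six motion parameters by
ordinary least squares; collinear columns (e.g. zero motion) are dropped
with a warning so the regression degrades gracefully to demeaning.
Regression is performed *within* the window only — the window is selected
first, then nuisance regression is applied to the data actually analyzed.
Pearson correlations of the residuals give the ROI-pair connectivity;
Fisher z = atanh(r) is used for all inference, with |r| clipped at
1 − 10⁻⁷ so duplicated series produce a large finite z rather than
infinity. ROIs invalidated by the lesion rule, and zero-variance series,
propagate as missing — never as zero.

## Lesion-artifact voxel exclusion

Focal lesions, microbleeds and CSF expansion distort the mean fMRI signal.
The exclusion rule works on mean volumes per timepoint: each mean image is
normalized for global intensity by dividing by its in-brain-mask mean (the
simplest normalization that makes the threshold's unit — "baseline-mean
intensity" — well defined), and a voxel is excluded when the *absolute*
normalized difference from baseline strictly exceeds 2.5 × the grand-mean
baseline intensity averaged across all animals. The absolute difference is
used because both hypointense (microbleed) and hyperintense (CSF)
deviations are artifacts for connectivity purposes; both the factor and
the signed/absolute choice are configurable since the methodology admits
either reading. An ROI losing strictly more than 30% of its voxels is
omitted; in retained ROIs the excluded voxels are dropped from the ROI
mean series, matching the rule's purpose of keeping lesion tissue out of
the regional signal. Volumes are assumed co-registered upstream; no
resampling is performed.

## PET uptake

Dynamic frames are summed over 15–60 min post-injection with
duration weighting: each frame contributes its value times the length of
its overlap with the interval, so edge frames contribute proportionally.
ROI comparisons are invariant to this choice because the subsequent
normalization cancels constants. The summed map is normalized to the total
rostro-thoracic activity: U(v) = 100 · a(v) / Σ(a · voxel volume) over the
body mask, in %/ml, which makes the whole-mask integral of U exactly 100
and removes injected-dose differences. The body mask is an input — in the
original workflow it is operator-defined from the field of view. A faulty
tail-vein injection is detected from the whole-mask time-activity curve: a
relative drop exceeding 5% between consecutive frames within the first
5 min (a paravenous bolus spike-and-drop) flags the scan; the criterion is
configurable because no quantitative rule is established.

## Diffusion-tensor metrics

The tensor is fit per voxel by log-linear least squares,
log S = log S₀ − b gᵀDg, which is exactly invertible on noise-free data
and entirely adequate at ROI-summary scale; weighted and nonlinear fits
reduce noise-induced bias but do not change ROI contrasts materially.
Signals clipped at zero (possible under noise) are floored at machine
epsilon and counted. From the sorted eigenvalues λ₁ ≥ λ₂ ≥ λ₃:
MD = (λ₁+λ₂+λ₃)/3, AD = λ₁, RD = (λ₂+λ₃)/2, and
FA = √(3/2)·√Σ(λᵢ−MD)² / √Σλᵢ², defined as 0 for an all-zero tensor;
negative eigenvalues are clipped to zero for the scalar computation and
flagged. The acquisition protocol is b = 2800 s/mm² in 42 uniformly spaced
directions plus 4 b = 0 images; the synthetic protocol places directions
on a deterministic Fibonacci sphere. Bundle-specific tractography and
along-tract segment ROIs are outside this package's scope — ROI masks are
accepted directly, and scalar maps and masks must share a grid.

## Histological quantification

Classification thresholds are the mean ± 2 sample SD (n − 1) of nuclear
areas in manually selected training populations of neuronal and glial
cells. Class intervals are closed at both ends, matching how the reference
ranges (52–215 µm² neuronal, 8–34 µm² glial) are stated; nuclei in neither
interval stay unclassified and are excluded from both counts, and the
(with these thresholds impossible) overlap case is resolved by
standardized distance for robustness. Cell density is CD = CC / ROI area,
reported per mm² with µm² inputs converted. Myelin optical density is
corrected as OD = (I_ROI − I_BG)/I_WM with background and white-matter
references from the same section; the formula is applied to whatever
intensity scale is supplied (transmittance vs absorbance is not fixed by
the method), and negative OD is allowed but flagged. All metrics are
averaged over the three analysed sections, with missing sections dropped
under a warning.

## Lateralization statistics

Every metric is reduced per animal to Δ = ipsilateral − contralateral
(connectivity Δs on Fisher-z values, e.g. ΔFC_CG(LN) = z(CG,LNi) −
z(CG,LNc)); swapping hemisphere labels negates every Δ, and missing values
propagate without imputation. Group comparisons use Student's equal-variance
two-sample t (Welch available), within-group comparisons a paired t on
differences; multiplicity is handled by Benjamini–Hochberg q-values with
one family per analysis table, the natural reading of per-matrix
presentation (the exact family partition is configurable since it is not
uniquely determined). Spearman correlations are Pearson correlations of
mid-ranks, with a two-sided p from the t approximation; an exact
enumeration permutation p is available for n ≤ 8 (enumeration beyond that
is computationally pointless when the t approximation is already accurate).
The central result object is the nucleus × metric × timepoint grid of
Spearman correlations between ΔU (subacute uptake) and every other Δ,
pooling injured and sham animals, with cells under 4 complete pairs
reported missing. Both the correlation test and the regression line are
reported, since scatter overlays are conventionally annotated with either.

## The synthetic cohort: what it emulates

The generator is first-class code with stored ground truth, not a test
fixture. Its model:

* **ROI time series** are Gaussian AR(1) processes (unit marginal
  variance, default φ = 0.3 at TR = 1 s) mixed through the symmetric
  square root of a target correlation matrix, the simplest stationary
  model whose population Pearson correlation is exactly the target.
* **Motion** is Gaussian jitter (default SD 0.01 mm; rotations at 10% of
  the translation scale) plus rare persistent translation steps
  (default rate 0.005/volume, 0.15 mm), whose true locations are stored as
  ground truth.
* **Lesions** are focal boxes of +3.5 normalized-intensity units in a
  cortical region disjoint from the analysis ROIs (the ROIs were chosen
  outside the primary injury), over multiplicative scanner-scale
  differences that exercise the global normalization.
* **PET** is simulated directly as summed-frame activity-concentration
  maps under a rise-and-plateau time-activity curve (1-min early frames,
  5-min late frames, 0–70 min); kinetics are out of scope. Faulty
  injections get a spike-and-drop early curve.
* **DTI** per-voxel tensors carry configured eigenvalues (baseline
  (1.0, 0.6, 0.5)·10⁻³ mm²/s, a plausible thalamic profile) in random
  orientations; Rician noise is available and used in the noise-bias
  tests, but the cohort default is noise-free signals with subject-level
  variance carried by per-subject eigenvalue factors — the quantity
  entering the correlation analysis is the ROI mean, whose sampling noise
  the subject-level parameters model directly.
* **Nuclei** are per-class Gaussians truncated at zero (neuronal
  133.5 ± 40.75 µm², glial 21 ± 6.5 µm², chosen so the derived ±2 SD
  intervals reproduce the published 52–215 and 8–34 µm² ranges); counts
  are Poisson around the configured densities.

A single positive latent severity per injured animal (Gamma, mean 1,
SD 0.5; zero for sham) jointly drives ipsilateral uptake elevation,
diffusivity increase, glial density increase, neuronal loss, myelin OD
reduction — and the M2 connectivity deficit on the CG–VPN, CG–LN and
RS–LN edges. The W2 connectivity deficit is a *group-level* bilateral
corticothalamic and thalamo-thalamic hypoconnectivity plus heterogeneous,
severity-independent lateral variation with zero mean, and the M6 deficit
is likewise uncoupled. Two consequences worth stating plainly. First,
effect sizes are free parameters of the generator: the source methodology
reports significances, not effect sizes, so the defaults are chosen once
as what a scientist would call a strong, clearly-lateralized injury
phenotype. Second, any *mean* lateral shift confined to the injured group
induces a pooled rank correlation with ΔU simply through group
separation; the uncoupled timepoints therefore carry heterogeneity rather
than a net shift. This is exactly the configuration under which "coupling
only at M2" is a well-posed recoverable pattern, and it is the main sense
in which passing tests speak to the pipeline's correctness rather than to
real biology: real data have unknown couplings, non-Gaussian noise,
registration error, physiological confounds and spatially structured
artifacts that the generator does not model.

Isotropic severity scaling of the eigenvalues leaves FA invariant, so FA
is deliberately an uncoupled metric; independent per-component eigenvalue
jitter (SD 3%) gives FA honest between-subject variability.

## Numerical choices and degenerate inputs

Clipping |r| at 1 − 10⁻⁷ before atanh; eigenvalue-floor repair (Higham-style
one-step projection, floor 10⁻⁴) for correlation targets pushed outside
the PSD cone by effect perturbations; strict inequalities at every stated
threshold boundary (2.5× exclusion, 30% omission, 20-component discard);
window tie-break to the earliest start with a 10⁻⁹ relative tolerance;
zero pooled variance in t-tests is an error except the all-equal case
(t = 0, p = 1); constant vectors make Spearman undefined (missing, with a
warning); empty ROIs, empty masks, non-positive normalization constants
and grid mismatches are errors that name the offending object.

## Problem sizes used in the checks

The automated checks run at desk scale, chosen to exercise every code
path with comfortable statistical margins: 1000 random FD traces against
the exhaustive window oracle; 50 synthetic scans per population
correlation for connectivity recovery (mean z within three standard
errors); 10,000 synthetic nuclei for classifier exactness; 10,000 null
replicates for t-test calibration; 1000 replicate delta tables for the
correlation null rate; and 20 full end-to-end cohort replicates scored
for recovery of the generating significance pattern, where a replicate
counts as recovered when at least 90% of the 34 grid cells agree with the
generating coupling.

## Known limitations

The generator's simplifications are listed above; beyond those, the
package deliberately excludes everything upstream of its inputs — image
reconstruction, registration, ICA decomposition itself, tractography, and
watershed cell detection — so errors in those stages appear here only as
(unmodeled) noise. FDR family definitions and the exclusion rule's
signed/absolute and normalization conventions are configurable precisely
because the methodology does not pin them down; results should be
reported with the conventions stated. Large-scale network analyses beyond
the six-ROI corticothalamic system are out of scope.
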