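# thalcon

Quantification pipeline for **lateralized secondary thalamic pathology
after experimental traumatic brain injury**, built for longitudinal
multimodal rodent studies: resting-state fMRI corticothalamic
connectivity under motion-aware segment selection, lesion-artifact voxel
exclusion, TSPO-PET uptake quantification, diffusion-tensor scalar
metrics, histological cell-density and myelin quantification — and the
lateralization (Δ) correlation analysis that ties them together. A
synthetic-cohort generator with stored ground truth makes every stage
testable end to end without access to raw animal data.

It is written for imaging scientists analysing focal-injury models (e.g.
lateral fluid-percussion injury in the rat) who need a transparent,
testable reference implementation of the quantification layer that sits
between preprocessed images and group statistics.

## The analysis in brief

For each animal and timepoint (baseline, 2 weeks, 2 months, 6 months):

* **fMRI connectivity.** Framewise displacement from the six rigid-body
  parameters, FD(t) = Σ|Δd| + r·Σ|Δθ| (rotation radius r = 5 mm);
  selection of the contiguous 300-volume window minimising mean FD after
  excluding the first 300 volumes; OLS motion regression within the
  window; Pearson correlation of ROI mean series, analysed as Fisher
  z = atanh(r). Scans losing > 20 of 30 ICA components are discarded.
* **Lesion exclusion.** Globally-normalized mean images; a voxel is
  excluded when |post − baseline| > 2.5 × the cohort-mean baseline
  intensity; ROIs with > 30% excluded voxels are omitted.
* **PET.** Duration-weighted frame summation over 15–60 min
  post-injection, normalized so uptake U (%/ml) integrates to 100 over
  the rostro-thoracic body mask; per-ROI mean U; injection QC from the
  early time-activity curve.
* **DTI.** Log-linear tensor fit (log S = log S₀ − b gᵀDg); FA, MD = (λ₁+λ₂+λ₃)/3,
  AD = λ₁, RD = (λ₂+λ₃)/2; ROI means.
* **Histology.** Nuclear-area classification by mean ± 2 SD training
  thresholds (neuronal 52–215 µm², glial 8–34 µm²); cell density
  CD = CC / ROI area; corrected optical density OD = (I_ROI − I_BG)/I_WM;
  three-section averages.
* **Lateralization statistics.** Per-animal Δ = ipsi − contra for every
  metric (z-scale for connectivity); Student/paired t with
  Benjamini–Hochberg q-values; Spearman correlation of ΔU (subacute PET
  uptake) against every other Δ across animals, the package's central
  result grid.

The six canonical ROIs are `VPNi`/`VPNc` (ventral posterior nucleus),
`LNi`/`LNc` (lateral nuclei), `RS` and `CG` (retrosplenial and cingulate
cortex); suffix `i`/`c` marks the hemisphere ipsi-/contralateral to the
injury.

## Worked example

Single scan — displacement, window, connectivity:

```r
library(thalcon)
C      <- default_fc_target()                          # 6x6 target correlations
series <- generate_roi_timeseries(C, n_volumes = 1500, seed = 8)
motion <- generate_motion_trace(1500, seed = 8)

glance(framewise_displacement(motion))
#> # A tibble: 1 × 4
#>   n_volumes mean_fd max_fd rotation_radius_mm
#>       <int>   <dbl>  <dbl>              <dbl>
#> 1      1500  0.0530  0.230                  5

res <- scan_connectivity(series, motion)
res$window
#> # A tibble: 1 × 3
#>   start length mean_fd
#>   <int>  <int>   <dbl>
#> 1   682    300  0.0513
dplyr::slice_head(tidy(res$fc), n = 3)
#> # A tibble: 3 × 5
#>   roi1  roi2      r     z     n
#>   <chr> <chr> <dbl> <dbl> <int>
#> 1 VPNi  VPNc  0.362 0.379   300
#> 2 VPNi  LNi   0.418 0.445   300
#> 3 VPNi  LNc   0.598 0.690   300
```

Mean FD of 0.053 mm says this is a quiet scan; the least-motion window
(volumes 682–981) is analysed. Individual sample correlations scatter
around their targets with the shared sampling variability of n = 300
volumes; calibration holds in the mean across scans.

Full cohort — generate, analyse, and read the Δ-correlation grid:

```r
cohort   <- generate_cohort(synth_config(seed = 42))
cohort
#> <synth_cohort: 47 subjects (36 TBI, 11 SHAM), seed 42>
analysis <- analyze_cohort(cohort)

scan_retention(analysis$scan_qc)
#> # A tibble: 1 × 5
#>   n_scans n_retained n_discarded retained_percent discarded_percent
#>     <int>      <int>       <int>            <dbl>             <dbl>
#> 1     188        174          14             92.6              7.45

dplyr::filter(analysis$delta_corr, nucleus == "LN",
              timepoint %in% c("M2", "M8"))
#> # A tibble: 9 × 9
#>   nucleus metric timepoint     n    rho  p_value significant     slope intercept
#>   <chr>   <chr>  <chr>     <int>  <dbl>    <dbl> <lgl>           <dbl>     <dbl>
#> 1 LN      ad     M2           26  0.865 1.16e- 8 TRUE          2.53e-6   4.73e-5
#> 2 LN      cd_gl  M8           20  0.889 1.65e- 7 TRUE          5.16e+0   8.08e+1
#> 3 LN      cd_ne  M8           20 -0.831 5.64e- 6 TRUE         -1.83e+0  -4.53e+1
#> 4 LN      fa     M2           26  0.172 4.01e- 1 FALSE         1.44e-4  -5.79e-3
#> 5 LN      fc_CG  M2           26 -0.906 2.02e-10 TRUE         -4.63e-3  -5.41e-2
#> 6 LN      fc_RS  M2           26 -0.838 9.23e- 8 TRUE         -4.18e-3  -7.54e-2
#> 7 LN      md     M2           26  0.902 3.04e-10 TRUE          1.67e-6   3.59e-5
#> 8 LN      od     M8           20 -0.926 4.64e- 9 TRUE         -1.81e-3  -1.02e-2
#> 9 LN      rd     M2           26  0.871 7.29e- 9 TRUE          1.25e-6   3.03e-5

autoplot(analysis$delta_corr)   # heatmap of the full grid
```

Reading the grid: in this synthetic cohort the lateralized subacute
uptake ΔU tracks the 2-month diffusivity increases (positive rho for MD,
AD, RD), the terminal glial density increase and neuronal/myelin loss
(signed as expected), and the 2-month connectivity deficit (negative rho
for the z-scale ΔFC) — while FA, generated without severity coupling,
stays non-significant. `n` differs by cell because PET, connectivity QC
and histology each restrict the available animals.

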