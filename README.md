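# histotomo

Quantitative cell-level phenotyping for whole-animal X-ray histotomography.

Synchrotron micro-CT optimised for soft tissue ("histotomography") images
whole PTA-stained larval zebrafish at ~0.74 µm isotropic voxels — fine
enough to resolve individual cell nuclei in 3D across the entire animal.
Turning such volumes into numbers requires a chain of computational steps,
and `histotomo` implements that chain as a tested R library for image
analysts and fish-phenomics researchers:

* **Beam-energy selection.** For a stained detail in an absorbing
  background, with Beer–Lambert transmission and reconstruction noise
  variance `var_i ∝ 1/I_i`, the package evaluates the relative
  contrast-to-noise ratio
  `CNR(E) = |µ₁(E) − µ₂(E)| / sqrt(var₁ + var₂)`,
  where `µ₂ = µ_bg + ρ_c·(µ/ρ)_c(E)`, over bundled water/tungsten
  mass-attenuation tables with the tungsten L-edge discontinuities.
* **Nucleus detection.** Per-slice 2D voxel features (Gaussian smoothing,
  gradients, Laplacian/difference of Gaussians, structure-tensor and
  Hessian eigenvalues) feed one probability random forest per orthogonal
  plane; the maps fuse voxelwise as
  `P_total = P_coronal · P_sagittal · P_transverse`, and objects are
  26-connected components with `P_total ≥ 0.80` and ≥ 8 voxels. Detections
  are validated against reference centroids by greedy one-to-one matching
  (TP/FP/FN, precision, recall, F1) with F1-based threshold calibration.
* **Morphometry.** Object volume, moment-based elongation
  (`sqrt(λ_max/λ_min)` of the second central moments), striation-period
  estimation by refined autocorrelation, and line-profile modulation depth.
* **Atlas mapping.** Landmark least-squares affine and 3D thin-plate-spline
  (`U(r) = r`) transforms, nearest-neighbour label-map transfer, per-nucleus
  brain-region assignment, and spherical-neighborhood cell-density maps
  (30-voxel ≈ 22 µm radius).
* **Cohort statistics.** Per-region counts/volumes across specimens with
  mean / sample SD / relative SD and rank-order concordance of region
  proportions; the five-larva reference count and volume tables ship with
  the package.
* **Synthetic phantoms.** Every stage is exercised on generated volumes
  with exact ground truth — ellipsoidal nuclei of configurable class
  elongations, textured background, noise, optional phase-contrast-like
  halos, warped multi-region atlases, and cohorts with per-specimen density
  multipliers — so the full pipeline runs and validates on a laptop with no
  external data.

## Worked example

```r
library(histotomo)

## five-fish reference tables ------------------------------------------
s <- cohort_summary(zf_table2())
print(s)
#> <cohort_summary> n = 5 specimens
#>   total: mean 75,413, SD 8,547, RSD 11.3%

pr <- proportion_ranks(zf_table2())
pr$ranks["Myelencephalon", ]
#> specimen_1 specimen_2 specimen_3 specimen_4 specimen_5
#>          1          1          1          1          1

## beam-energy choice ---------------------------------------------------
sc <- cnr_scenario(zf_attenuation("water"), d_bg_cm = 0.3,
                   zf_attenuation("tungsten"), d_c_cm = 5e-4, rho_c = 0.05)
curve <- cnr_curve(sc, energy_grid(zf_attenuation("tungsten")))
attr(curve, "E_opt")
#> [1] 12.0998

## detect nuclei in a phantom ------------------------------------------
ph <- generate_nuclei_phantom(phantom_spec())   # 96^3 voxels, 500 nuclei
lab <- sparse_labels_from_truth(ph$truth)       # emulated sparse annotation
res <- detect_nuclei(ph$volume, lab)            # ~2 min on one CPU
match_detections(res$nuclei, ph$truth$centroids_um)
#> <match_result> TP 500  FP 0  FN 0 | precision 1.000 recall 1.000 F1 1.000
```

The cohort mean of 75,413 nuclei with 11.3 % relative SD summarises the
five bundled specimens' brain counts; the CNR optimum just above the
tungsten L1 edge (12.1 keV) is why larval acquisitions run near 13.8 keV;
and the phantom match result shows the calibrated detector (threshold 0.80,
8-voxel filter) recovering every synthetic nucleus under default noise.

## Package layout

| Area | Files |
| --- | --- |
| Phantoms & ground truth | `R/phantom.R`, `R/volume.R` |
| Beam physics | `R/attenuation.R`, `R/cnr.R`, `inst/extdata/mu_*.csv` |
| Detection | `R/features.R`, `R/classifier.R`, `R/segment.R`, `src/cclabel.cpp` |
| Morphometry | `R/morphometry.R` |
| Atlas & density | `R/atlas.R`, `R/density.R` |
| Cohort statistics | `R/region_stats.R`, `inst/extdata/table*.csv` |

The methods vignette (`vignettes/histotomography-methods.Rmd`) documents the
models, parameter defaults, numerical choices and limitations in detail.
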