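---
title: "Quantitative cell-level phenotyping of whole-animal histotomography: models and methods"
author: "histotomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative cell-level phenotyping of whole-animal histotomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histotomo)
```

## Overview

Synchrotron micro-CT tuned for soft tissue ("histotomography") images whole
small vertebrates such as larval zebrafish at ~1 µm isotropic voxels, so that
individual PTA-stained cell nuclei are resolvable in 3D across the entire
animal. `histotomo` implements the downstream quantitative pipeline as a
reusable, fully testable library:

1. **Phantom generation** — synthetic volumes with voxel-level ground truth,
   so every stage can be validated without multi-gigabyte scan data.
2. **Beam-energy selection** — a contrast-to-noise (CNR) model over tabulated
   mass-attenuation coefficients, including absorption-edge structure.
3. **Nucleus detection** — per-plane random-forest voxel classification,
   orthogonal-plane probability fusion, and threshold/size segmentation.
4. **Morphometry** — volume, moment-based elongation, line-profile
   periodicity and modulation depth.
5. **Atlas mapping** — landmark affine + thin-plate-spline transforms,
   label-map transfer, per-nucleus region assignment, and
   spherical-neighborhood density maps.
6. **Cross-specimen statistics** — per-region counts/volumes, cohort
   means/SD/RSD, and rank-order concordance of region proportions, with the
   package's five-fish reference tables bundled as fixtures.

## The synthetic phantom and what it does (and does not) emulate

`phantom_spec()` describes a volume of randomly oriented, non-overlapping
ellipsoidal nuclei rendered *brighter* than the background (attenuation
convention — the histology-style dark-nuclei look is purely a display
inversion). The defaults are chosen to emulate crowded larval brain tissue at
the acquisition scale of the imaging problem:

* **Voxel size 0.743 µm** isotropic (the larval acquisition scale; juvenile
  data use 1.43 µm).
* **Nucleus geometry**: minor semi-axes drawn from 1.1–1.6 µm with a
  per-class major/minor ratio; the default near-spherical class (ratio 1.1)
  yields ~13 µm³ nuclei, the typical brain-nucleus volume the morphometry
  stage should recover. Elongated classes (e.g. 1.9 for red-blood-cell-like
  and 1.3 for motor-neuron-like shapes) can be mixed in.
* **Default grid 96³ voxels with 500 nuclei** (~71 µm cube). This matches
  the realistic brain packing fraction — ~75,000 nuclei in ~15.5 × 10⁶ µm³ —
  within a factor of ~2, while keeping a full desk-scale pipeline run in the
  low minutes. The problem sizes used by the test-suite (48³/40 nuclei for
  module tests, 96³/500 for the end-to-end run, 128³ for the density-map
  oracle) were fixed once as representative desk-scale conditions.
* **Background texture** (smooth Gaussian field, 6 µm correlation length,
  SD 6) and **additive Gaussian noise** (SD 12 against a nucleus contrast of
  60) emulate low-frequency tissue variation and reconstruction noise at a
  moderate 5:1 contrast-to-noise per voxel.
* **Minimum surface separation 1.5 µm** (two voxels) between nuclei,
  enforced by conservative bounding-sphere dart throwing with a bounded
  retry budget (100 × n attempts, then an explicit "overcrowded" error).
* An optional **edge halo** — a signed difference-of-Gaussians ring at
  object boundaries — mimics propagation phase-contrast fringes; the real
  effect is tuned qualitatively at the beamline, so a single amplitude
  scalar is deliberately the only knob.

The phantom does **not** simulate projection/reconstruction physics (noise
is applied in image space), stitching of segmented acquisitions, pigment
artifacts, or the full morphological diversity of real tissue. Passing the
phantom-based tests therefore demonstrates that the *computational* stages
are correct and calibrated, not that the classifier generalises to arbitrary
real scans; the real-data step that is emulated here — interactive sparse
annotation — is represented by `sparse_labels_from_truth()`, which converts
ground truth inside three 75-voxel training cubes into annotation-like
labels. (The training-region edge is specified in voxels; the corresponding
physical extent at the larval voxel size is ~56 µm.)

Determinism is a design contract: one `phantom_spec` + seed gives
bit-identical volumes and truth, and cohort seeds are derived arithmetically
from a master seed.

## Beam-energy optimisation

For a small contrasting detail (path `d_c`, stain concentration `rho_c`)
centred in an absorbing background (path `d_bg`), the linear attenuations
are `mu1(E) = mu_bg(E)` and `mu2(E) = mu_bg(E) + rho_c * (mu/rho)_c(E)`,
each the product of a density and a tabulated mass-attenuation coefficient.
Transmission is Beer–Lambert, and the reconstructed noise variance at the
image centre is inversely proportional to transmitted intensity,
`var_i = k / I_i`. The contrast-to-noise ratio is

```
CNR(E) = |mu1 - mu2| / sqrt(var1 + var2)
```

The constant `k` is only known up to proportionality, so it is fixed at 1
and every CNR is **relative**: rank order across energies never depends on
`k`, and absolute photon-calibrated CNR is out of scope.

Numerical choices:

* **Log–log interpolation** of `mu/rho` between tabulated energies — the
  standard convention for photon cross sections, which are near power laws
  between edges.
* **Absorption edges as duplicated energies**: the earlier row is the
  pre-edge value, the later the post-edge value; querying the edge energy
  itself returns the post-edge branch while approach from below follows the
  pre-edge branch. The CNR curve is therefore discontinuous exactly at the
  tabulated edges, and nowhere else.
* **No extrapolation**: energies outside the table raise an error.

The bundled water and tungsten tables (8–30 keV, with the tungsten L3
10.2068 keV, L2 11.544 keV and L1 12.0998 keV edges) are condensed from
standard reference tabulations of photon mass-attenuation coefficients, with
intermediate grid energies filled by the same log–log rule. For a water
background of up to 3 mm — a larval-zebrafish-scale specimen — the model
places the optimum just above the tungsten L1 edge:

```{r cnr}
s <- cnr_scenario(zf_attenuation("water"), d_bg_cm = 0.3,
                  zf_attenuation("tungsten"), d_c_cm = 5e-4, rho_c = 0.05)
curve <- cnr_curve(s, energy_grid(zf_attenuation("tungsten")))
attr(curve, "E_opt")
```

consistent with the monochromator operating points used in practice
(13.8 keV for larvae; 16.2 keV for thicker juveniles, where the peak
broadens). `estimate_throughput()` exposes the screening-campaign
arithmetic; set-up time is charged per multiplexed batch (not per specimen),
a deliberate reading of an ambiguous convention, with every assumption a
parameter.

## Nucleus detection

Detection follows the interactive-classification workflow: 2D features per
slice in each of the three orthogonal planes, a probability random forest
per plane, and voxelwise fusion

```
P_total(x,y,z) = P_coronal * P_sagittal * P_transverse
```

so that a voxel survives only if all three views agree. Objects are the
26-connected components of `P_total >= 0.80` containing at least 8 voxels
(~3.3 µm³ at 0.743 µm voxels; the voxel count is the normative filter).

* **Features**: per scale σ ∈ {0.7, 1.0, 1.6, 3.5, 5} voxels — smoothed
  intensity, gradient magnitude, Laplacian of Gaussian, difference of
  Gaussians (σ vs 1.6σ), structure-tensor eigenvalues and
  Hessian-of-Gaussian eigenvalues; reflective boundary handling. The
  families follow the established interactive-segmentation feature bank;
  the scale set is the conventional default since the original analysis did
  not record one.
* **Forest**: 100 trees, class-balanced case weights, fixed seed, one
  thread — reproducible bit-for-bit.
* **2D-per-plane rather than one 3D classifier** is deliberate fidelity to
  the described workflow; the fusion product is what restores 3D
  consistency.
* **Connectivity 26** merges diagonal touches; it is configurable (6)
  and documented because the original choice is unrecorded.
* **Matching**: detected and reference centroids are paired greedily by
  ascending distance (deterministic tie-break by reference then detection
  index) within a 3 µm radius — about the radius of a typical brain
  nucleus; the radius is a parameter since no criterion was recorded.
  Precision, recall and F1 follow from the confusion counts; F1 is computed
  pooled over the volume. `optimize_threshold()` sweeps the threshold grid
  and reports the full F1 curve with a smallest-threshold tie-break.

On the default 500-nucleus phantom the calibrated pipeline reaches F1 ≥ 0.9
(the acceptance suite recomputes this end-to-end; in practice it is ~1.0 on
phantom conditions, which lack the hard ambiguities of real tissue).

## Morphometry

* **Volume** is voxel count × voxel volume; rasterised ellipsoids agree
  with 4/3·π·abc to well under 15 % once semi-axes reach 2 voxels.
* **Elongation** is `sqrt(lambda_max / lambda_min)` of the voxel
  coordinates' second-central-moment matrix — rotation- and
  scale-invariant, with single-voxel objects defined as exactly 1 and
  degenerate (coplanar) sets as `Inf`. Moments were chosen over bounding
  boxes or Feret diameters because "axis" was never defined operationally
  in the source workflow; this should be kept in mind when comparing with
  reported class means (1.9 red blood cells, 1.3 motor neurons, 1.1 brain
  nuclei — the phantom's class targets). Note the reference RBC/motor-neuron
  volumes include cytoplasm; the module measures whatever voxel set it is
  given and does not attempt nucleus/cytoplasm decomposition.
* **Line profiles**: the dominant period is the first autocorrelation peak
  (1/(n−k) normalisation, search bounded by the stated longest expected
  period) refined parabolically and then sharpened on a high-order
  harmonic peak, whose sub-sample error divides by the cycle count;
  noiseless periods of 3–20 samples are recovered to well under one sample.
  Aperiodic and constant profiles raise an explicit "no period detected"
  error. **Modulation depth** is Michelson contrast of the detrended
  profile (moving-average baseline, window three times the longest
  expected period, extrema evaluated only where the window is fully
  supported): 0 for constant input, `a/m` for a sinusoid of amplitude `a`
  about mean `m`.

## Atlas mapping

* **Affine fit**: least squares over ≥ 4 non-coplanar landmark pairs;
  exact on affinely consistent data, explicit degeneracy diagnostics.
* **Thin-plate spline**: the 3D biharmonic kernel `U(r) = r` (the
  dimensionally correct fundamental form in 3D, not the 2D `r² log r`)
  plus an affine polynomial, solved per output coordinate with the usual
  side conditions by block elimination — numerically stable from `lambda
  = 0` (exact landmark interpolation, residual < 1e−6 µm) through the
  stiff limit, where the transform collapses onto the least-squares
  affine.
* **Label transfer** is pull-back resampling: each target voxel centre is
  mapped fixed → moving and takes the nearest-neighbour label (0 outside
  the moving grid). Forward splatting would leave holes;
  nearest-neighbour keeps labels integral and never invents regions.
* **Region assignment** is by centroid containment — matching per-nucleus
  point counting — rather than majority vote over the voxel set; the
  label at the containing voxel wins, label 0 or out-of-grid centroids
  are reported "unassigned", and counts always sum to the number of
  centroids.
* **Density maps** count nuclei within a Euclidean ball of 30 voxels
  (~22 µm at the larval voxel size — about five cell diameters, the scale
  of a small brain region) around every in-mask voxel. The radius is
  defined in voxels because that is how the neighbourhood was specified.
  Balls are truncated at volume boundaries and **raw counts** are
  reported (the reference analysis reports counts, not per-µm³
  densities); `normalize = TRUE` divides by the truncated in-volume ball
  volume. The implementation accumulates precomputed ball offsets per
  centroid and is tested voxel-for-voxel against a brute-force
  distance-counting oracle.

## Cross-specimen statistics

`region_table` holds specimens × regions counts or volumes; the bundled
five-fish tables (`zf_table2()`, counts; `zf_table3()`, volumes in µm³) are
the package's reference dataset. Conventions, each validated by the test
suite against every printed caption value of those tables:

* **Sample SD with the n−1 denominator** — the population-SD alternative
  gives 7,645 for the count totals and is inconsistent with the reference
  dispersion of 8,547.
* **Report-time rounding only**: means to integers, RSD to one decimal with
  round-half-even; all internal values stay full precision.
* Proportions per specimen sum to 1; ranks are dense with ties broken by
  region index; concordance is reported as Spearman correlation plus top-k
  agreement.

```{r stats}
cohort_summary(zf_table2())
```

## Known limitations

* Phantom realism: ellipsoidal nuclei with sharp boundaries and stationary
  Gaussian noise; no reconstruction artifacts, rings, or stain gradients.
* The classifier is trained and evaluated per volume; no cross-specimen
  transfer of a trained model is attempted.
* Only landmark-driven transforms are provided — intensity-driven
  deformable registration (as done by dedicated registration suites) is
  out of scope, as are web viewers and VR export.
* The CNR model is monochromatic and relative; polychromatic (pink-beam)
  spectral weighting and detector response are not modelled.
* Elongation of near-spherical rasterised objects carries a small
  discretisation bias (~±5 % at semi-axes of a few voxels); comparisons
  against continuous-ellipsoid expectations should use objects of at least
  2-voxel semi-axes, as the volume metric also requires.
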