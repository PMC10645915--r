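---
title: "Validating PET attenuation correction with synthetic lesion insertion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating PET attenuation correction with synthetic lesion insertion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petlesionsim)
```

## The problem

Simultaneous PET/MRI cannot measure 511 keV photon attenuation directly:
MRI signal reflects proton density and relaxation, not electron density, so
the attenuation map (the "μ-map", linear attenuation coefficients in
cm⁻¹) must be inferred from MR images. Cranial bone is the hard case —
it is nearly invisible to conventional MR sequences yet attenuates
strongly — and mis-modelling it biases reconstructed brain uptake,
especially in cortex adjacent to the skull. The accepted reference is a
CT-derived map (CTAC), since CT Hounsfield units map almost directly to
electron density.

`petlesionsim` implements a desk-scale, vendor-free version of the
standard validation loop for MR-derived attenuation correction (MRAC):
insert synthetic lesions of known activity into PET *projection space*
with full physics modelling, reconstruct the same count data with a
reference and several candidate μ-maps, and score each candidate by the
ROI-level activity bias it induces relative to the reference
reconstruction. Because the data are synthetic, ground truth is known
exactly, and the whole experiment is reproducible from one integer seed.

## The pipeline

For each synthetic subject the pipeline runs:

1. **Phantom** (`generate_phantom`, `cohort`): an analytic digital head —
   nested ellipsoids for scalp, skull, cortical gray-matter ribbon
   (partitioned into ≥ 16 named sectors), a deep gray band and a
   white-matter core — with piecewise-constant emission (gray > white) and
   a CT-like HU volume (air −1000, soft tissue 30–60 HU, skull
   700–1200 HU).
2. **μ-maps** (`hu_to_lac`, `derive_mrac_family`): HU are converted to
   511 keV LACs by the standard bilinear model, and four MRAC-style
   candidate maps are derived as controlled degradations of the truth
   (details below).
3. **Projection-space insertion** (`rasterize_roi`, `assign_activity`,
   `lesion_to_expected_counts`, `estimate_scatter`, `sample_poisson`,
   `merge_into_patient`): lesion ROIs are smoothed by the scanner PSF,
   forward-projected, multiplied by attenuation and normalization factor
   sinograms, calibrated by `sensitivity × duration`, given a scatter
   estimate, Poisson-sampled, and added to (or substituted for) the
   simulated patient counts.
4. **Reconstruction** (`osem_reconstruct`, `reconstruct_all`):
   attenuation- and normalization-corrected OSEM of the *same* counts with
   each of the five μ-maps.
5. **Evaluation** (`relative_bias`, `cohort_summary`, `paired_t_bh`):
   per-ROI relative bias (in percent)
   $100\,(\mathrm{PET}_{\mathrm{MRAC}} -
   \mathrm{PET}_{\mathrm{CTAC}})/\mathrm{PET}_{\mathrm{CTAC}}$ and its
   absolute value, cohort medians with type-7 IQRs, and two-sided paired
   t-tests of each candidate against the best map, adjusted by
   Benjamini–Hochberg.

Three conditions are always scored by the same code path on different
image pairs: lesions inserted **with** the emission background, lesions
reconstructed **alone**, and the lesion-free **original** reconstructions
evaluated with the same ROI masks.

## The attenuation-map family

The clinical map families this emulates come from vendor sequences and a
trained network; none is reproducible from published numbers. What the
validation actually exercises is their *bone fidelity ordering*, so the
candidates are parametric degradations of ground truth:

| method | bone model | default degradation |
|---|---|---|
| `ctac` | truth | — (reference) |
| `dixon` | none — skull set to soft tissue (0.096 cm⁻¹) | — |
| `ute` | single binary compartment at one fixed LAC | 0.11 cm⁻¹, 5 % of shell-boundary voxels misclassified |
| `dixonbone` | continuous but biased bone | LAC × 0.9, shell eroded 2 mm |
| `dl_dixon` | pseudo-CT ≈ truth | voxelwise Gaussian noise, σ = 0.002 cm⁻¹ |

All candidates except `dl_dixon` equal the truth exactly on brain-interior
voxels, so every bias downstream is attributable to the bone model. The
whole-volume μ RMSE ordering dixon > ute ≥ dixonbone > dl_dixon holds by
construction under the defaults and is asserted by test.

## Tunable parameters that matter

* **Bilinear HU→LAC model** (`bilinear_params`): soft segment through
  (−1000 HU, 0) and (0 HU, 0.096 cm⁻¹); bone slope 5.1 × 10⁻⁵ cm⁻¹/HU
  (≈ 0.147 cm⁻¹ at 1000 HU, conventional cortical bone at 511 keV); break
  at 0 HU; clip at 0.3 cm⁻¹. Vendor slope constants are not standardized,
  so all four numbers are configuration.
* **Geometry** (`sinogram_geometry`): generic multi-slice parallel-beam,
  one sinogram slice per image slice, θ = 0 rays parallel to y, signed
  radial bins symmetric about 0, defaults `n_radial = 1.5 nx`,
  `n_angles = max(nx, 96)`, bin = in-plane voxel size. Real cylindrical
  scanner geometries with oblique planes are deliberately out of scope:
  attenuation-induced bias near bone is geometry-agnostic, and the
  parallel-beam model keeps the projector exact and fast.
* **Acquisition** (`acquisition_model`): duration 300 s; sensitivity
  2 × 10⁻⁴ counts per (Bq/mL·mm) per bin per second (chosen to give
  brain-background bins on the order of 10²  counts, i.e. realistically
  noisy but not photon-starved); scatter fraction 0.30; normalization
  defaults to all-ones and is user-suppliable as a factor sinogram.
* **Scatter** (`estimate_scatter`): a broad radial Gaussian convolution
  (FWHM 80 mm) of the expected trues, rescaled so scatter/(trues+scatter)
  equals the scatter fraction exactly. A single-scatter simulation would
  add realism but no discriminating power between μ-maps.
* **PSF**: isotropic Gaussian, FWHM 4 mm, applied in image space before
  projection (lesion insertion) and as the post-reconstruction filter.
* **OSEM** (`recon_config`): 3 iterations × 21 subsets by default;
  21 follows the pipeline convention this emulates, while 24 — also in
  circulation for the same scanner class — is available by configuration.
  Subsets are angle-interleaved (angle *i* → subset *i* mod *n*). Scatter
  enters the denominator as a known additive term. ε = 10⁻¹² guards all
  divisions; zero-sensitivity voxels are frozen at 0.
* **Lesions** (`lesion_spec`): spheres of radius 4 mm by default, one in
  the superior-frontal cortical ribbon (skull-adjacent), one deep at the
  volume center, both at lesion-to-background ratio 2. LBR 2 is a
  conventional "clearly visible, not extreme" focal uptake choice; the
  clinical pattern it stands in for varies by tracer and disease, so it is
  a parameter, not a claim.

## What the synthetic cohort emulates — and what it does not

`cohort()` draws per-subject variability from seeds derived from one
master seed: head size ±5 %, skull thickness ±20 %, skull HU uniform in
700–1200, scalp HU in 30–60, per-region activity multipliers ±10 %. These
ranges bracket ordinary adult anatomical variation and give each subject a
distinct bias magnitude, which is what the paired statistics need.

Because the anatomy is jittered per subject, the default lesion positions
are re-derived from each subject's own geometry (mid-ribbon along +y, and
the volume center), mirroring how per-patient atlas parcellations define
ROIs in patient space. User-supplied lesion lists are taken as fixed world
coordinates and are *not* adapted.

The phantom is deliberately simple: piecewise-constant uptake, elliptical
cross-sections, no CSF gap, no air sinuses, no MR-specific artifacts
(susceptibility, truncation), and layers nested in-plane only (the nested
shells share the skin's axial semi-axis, so shell geometry is exact on
every axial slice — where the parallel-beam rays live — at the price of
no bone "cap" along the scanner axis). Passing tests therefore show that
the *pipeline* orders attenuation-correction methods correctly and
propagates bone errors with the right sign and spatial gradient; they do
not certify performance on real patient data, where registration error,
atlas imperfection and tracer-specific uptake patterns add variance.

## Numerical choices

* The projector is an exact Siddon-style intersection-length traversal,
  one ray per bin center; back projection reuses the identical traversal,
  so the adjoint identity ⟨Px, y⟩ = ⟨x, Pᵀy⟩ holds to floating-point
  rounding (asserted at 10⁻⁶ over seeded random pairs).
* Attenuation factors are exp(−∑ μℓ) with path lengths converted mm→cm;
  correction "matrices" are applied multiplicatively as factors ≤ 1 (the
  reciprocal convention some vendors store is an implementation detail of
  their files, not of the physics).
* Gaussian convolutions (PSF, scatter kernel) use truncated (±4σ)
  normalized kernels with zero padding and a global rescale that conserves
  the image total exactly; a kernel whose FWHM is below half a voxel is
  the identity.
* `replace` insertion zeroes background only on bins where the expected
  lesion signal exceeds 10⁻³ of its maximum — the full ray support of a
  small sphere is a needlessly destructive footprint.
* Quantiles are type-7 (linear interpolation); zero-variance paired
  differences give p = 1 with a warning; the BH family is all tests
  produced in one `paired_t_bh()` call (the pipeline calls it once per
  condition). These conventions are stated because the upstream practice
  they mirror leaves them unspecified.
* All randomness flows through seeds derived deterministically from the
  master seed; no global RNG state leaks between stages
  (`withr::with_seed`).

## Problem sizes

The full-scale default (128 × 128 × 16 voxels at 2 × 2 × 6 mm) runs a
complete 11-subject experiment in minutes. The test suite and the
acceptance script use a "smoke" scale chosen to keep a laptop run under a
minute while preserving every qualitative result: 64 × 64 × 8 voxels at
4 × 4 × 12 mm, 48 angles, 96 radial bins, 2 OSEM iterations × 8 subsets,
cohorts of 1 and 5. Matched-model sanity checks (uniform cylinder
recovery, likelihood monotonicity) use 64 × 64 × 4 at 2 mm.

## Known limitations

* Parallel-beam multi-slice geometry: no oblique planes, TOF, randoms,
  dead time, detector gaps or arc effects.
* Static frames only; dynamic (multi-frame) noise is not simulated.
* The MRAC candidates are degradations of truth, not MR physics
  simulations; conclusions about any *specific* vendor sequence or network
  require that vendor's maps.
* Scatter is a scaled convolution, adequate for bias validation but not
  for scatter-correction research.
* The atlas is geometric; region names follow common neuroanatomical
  parcellation nomenclature for readability, not anatomical accuracy.
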