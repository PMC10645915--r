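# petlesionsim

Synthetic lesion insertion for validating PET attenuation correction.

PET/MRI scanners must infer the 511 keV attenuation map from MR images,
and the hard part is cranial bone: invisible to conventional MR sequences,
strongly attenuating, and therefore the dominant source of quantitative
bias in brain PET reconstructed with MR-derived attenuation correction
(MRAC). `petlesionsim` implements the standard validation loop for such
methods at desk scale and with no vendor dependencies:

1. generate an analytic digital head phantom (emission, CT-like HU volume,
   ≥ 16-region brain atlas) — or a seeded cohort of jittered subjects;
2. convert HU to 511 keV linear attenuation coefficients (bilinear model)
   and derive four MRAC-style candidate maps as controlled degradations of
   the CT-based truth (`dixon` — no bone, `ute` — binary bone,
   `dixonbone` — biased continuous bone, `dl_dixon` — near-truth
   pseudo-CT);
3. insert spherical or atlas-region lesions into projection space with
   PSF smoothing, exact ray-traced forward projection, attenuation and
   normalization factors, activity calibration, convolution scatter and
   Poisson noise, added to (or replacing) the simulated patient counts;
4. reconstruct the *same* counts with attenuation-corrected OSEM under
   each of the five maps;
5. score each candidate by the ROI relative bias it induces against the
   CT-based reference,

   relative bias (%) = 100 · (PET_MRAC − PET_CTAC) / PET_CTAC,

   with cohort medians/IQRs and paired t-tests under Benjamini–Hochberg
   FDR control.

The projector and OSEM are exact and fast (Siddon-style C++ ray tracing;
back projection is the literal adjoint), the whole experiment is a pure
function of one integer seed, and every stage is exposed as an ordinary R
function with a classed S3 value.

## Worked example

A five-subject cohort at smoke scale (64 × 64 × 8 voxels, 48 angles,
2 OSEM iterations × 8 subsets; ~30 s on one CPU):

```r
library(petlesionsim)

ec <- experiment_config(
  phantom = phantom_config(shape = c(64, 64, 8), voxel_size_mm = c(4, 4, 12)),
  recon   = recon_config(n_iterations = 2, n_subsets = 8),
  n_subjects = 5, master_seed = 1, n_angles = 48)
res <- run_experiment(ec)

ab <- cohort_summary(res$records, "absolute_bias_pct")
subset(ab, roi_name == "superior_frontal_sphere" & condition == "with_background")
#>     method roi_id                roi_name       condition median_pct   q1_pct   q3_pct n_subjects
#>      dixon      1 superior_frontal_sphere with_background   8.355617 7.709407 9.786530          5
#>  dixonbone      1 superior_frontal_sphere with_background   2.482625 2.204906 2.966489          5
#>   dl_dixon      1 superior_frontal_sphere with_background   1.668942 1.564445 1.736489          5
#>        ute      1 superior_frontal_sphere with_background   6.384913 5.307862 6.400829          5
```

Reading: for a 4 mm sphere inserted in the superior frontal cortex (at the
vicinity of the skull) and reconstructed together with the brain
background, ignoring bone entirely (`dixon`) costs a median 8.4 % absolute
activity error against the CT-based reference; a binary bone compartment
(`ute`) reduces it to 6.4 %, model-based continuous bone (`dixonbone`) to
2.5 %, and a near-truth pseudo-CT (`dl_dixon`) to 1.7 %. The paired
comparisons against the best map:

```r
subset(res$stats, condition == "with_background" & roi_id == 1)
#>        condition roi_id            comparison t_statistic      p_value  p_adjusted n_pairs
#>  with_background      1     dl_dixon vs dixon    9.693503 0.0006339092 0.001727542       5
#>  with_background      1 dl_dixon vs dixonbone    2.786797 0.0494736163 0.059368340       5
#>  with_background      1       dl_dixon vs ute    8.945458 0.0008637710 0.001727542       5
```

Every stage is also available piecewise (`generate_phantom()`,
`derive_mrac_family()`, `simulate_acquisition()`, `merge_into_patient()`,
`osem_reconstruct()`, …), and a thin command-line front end with verbs
`phantom`, `mumaps`, `insert`, `recon`, `evaluate` and `run` is installed
at `system.file("cli/petlesionsim.R", package = "petlesionsim")`. Volumes
are read and written as NIfTI-1, sinograms as NIfTI-1 plus a JSON geometry
sidecar, reports as tidy CSV + JSON.

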