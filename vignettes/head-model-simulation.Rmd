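---
title: "Quantifying template-head-model error in simulated ERP source localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying template-head-model error in simulated ERP source localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

EEG source imaging estimates the cortical currents that generated a scalp
recording.  Its accuracy is limited by the *forward model* (head model): the
mapping from a unit dipole at a known brain location to the potentials it
produces at the electrodes.  The most accurate head models are built from each
subject's own MRI; in practice, many event-related-potential (ERP) studies
have no subject MRIs and substitute a *template* model built from an average
anatomy.  `erplocsim` quantifies what that substitution costs when the data
contain several simultaneously active brain regions, by running a fully
synthetic, seeded version of the whole analysis chain:

1. generate a cohort of per-subject head geometries plus a template built
   from the cohort mean (`make_cohort()`),
2. simulate four-region ERP networks in source space, project them through
   each subject's own detailed forward model and add pink noise calibrated to
   a target SNR (`simulate_epochs()`),
3. reconstruct every epoch with eLORETA after noise pre-whitening
   (`eloreta_weights()`, `apply_inverse()`),
4. score each reconstruction against the simulated ground truth with
   cluster-based metrics (`evaluate_reconstruction()`),
5. sweep cohort x network x SNR x head-model variant (`run_experiment()`).

## Head models: concentric spheres as the anatomy stand-in

Real studies build FEM or BEM models from MRI segmentations.  Without MRIs,
this package uses the classical analytic alternative: concentric spherical
shells with per-shell conductivities, for which the dipole potential has an
exact Legendre-series solution.  Two model families preserve the contrast the
study design needs:

* **detailed** (FEM-analogue): 4 shells, brain / CSF / skull / scalp — the
  model family that can represent cerebrospinal fluid;
* **simple** (BEM-analogue): 3 shells, brain / skull / scalp — no CSF
  compartment, the defining limitation of three-surface models.

Three conductivity presets are provided (S/m, innermost to outermost):

| preset | shells | values |
|---|---|---|
| `fem_meta` | 4 | 0.47, 1.71, 0.006, 0.41 |
| `fem_default` | 4 | 0.33, 1.79, 0.008, 0.43 |
| `bem_default` | 3 | 0.33, 0.006, 0.33 |

The two 4-shell presets are the gray-matter / CSF / compact-bone / scalp
values of a conductivity meta-analysis and of a common software default,
respectively; comparing them isolates the effect of conductivity uncertainty
from geometry.  Tissues that concentric shells cannot represent (white
matter, spongy bone, eyes, blood, muscle) are dropped; the four retained
compartments dominate EEG volume conduction.  Default radii are 83/87/92/100
mm (4-shell) and 87/92/100 mm (3-shell), common spherical-head conventions.

The series solver propagates per-harmonic coefficients through the shell
interfaces with 2x2 transfer matrices (radii normalized to the outer radius
for conditioning) and truncates adaptively once a term contributes less than
`1e-10` of the running sum, capped at 200 terms.  In the equal-conductivity
limit it matches an independently derived closed form (generating-function
sum of the homogeneous-sphere series) to better than `1e-6` relative error,
and doubling the truncation order changes potentials by less than `1e-8`;
both checks are part of the test suite.

## Source space, montage, and what "anatomy" means here

Dipoles sit on a Fibonacci lattice over the sphere at 0.85 of the brain
radius, at a nominal 3 mm spacing (the area per dipole is `spacing^2`, and
`per_dipole_volume = spacing^3` keeps the volume-based dispersion metric
well-defined on a surface grid).  A sphere has no cortex, so dipole
orientations are radial in the simulation while the inverse solution keeps
free 3-component orientations — the reconstruction must not be told the true
orientation model.  The electrode montage is a Fibonacci lattice over the
upper 120 degrees of the scalp sphere, 128 sensors by default, emulating a
high-density cap without face or neck electrodes.

## The synthetic cohort and the template

Each subject's shell radii are the base radii scaled by independent lognormal
factors (sd 5%), re-sorted to stay increasing; the template uses the exact
arithmetic mean of the subject radii.  Radius jitter alone, however, is
almost a global scaling of a concentric geometry: it barely changes the
*angular* relationship between sensors and sources, which is what
localization actually depends on, so by itself it cannot reproduce the
mislocalizations that make template models interesting.  The generator
therefore also perturbs each subject's *cap placement*: the electrode cap is
rigidly rotated about a random axis (angle sd 5 degrees, about 9 mm at the
scalp — typical cap-placement / co-registration error).  Subject-specific
models use the true, rotated electrode positions, as an MRI-plus-digitizer
pipeline would; the template model assumes the standard cap.  This mirrors
the electrode-position component of template-model error documented in the
ESI literature, where template-based pipelines show localization
discrepancies up to about 2 cm.  Setting both `radius_jitter_sd = 0` and
`cap_rotation_sd_deg = 0` collapses every subject onto the template exactly,
which the tests exploit as a degenerate-limit check.

What this cohort does **not** emulate: cortical folding, skull thickness
maps, anisotropic conductivity, per-subject conductivity variation (the two
FEM presets vary conductivity *globally* instead), or displaced candidate
source support in the template grid.  Passing tests therefore show that the
analysis chain behaves correctly and that the studied orderings hold under
geometric and electrode-placement mismatch; they do not certify absolute
error magnitudes on real heads.

## ERP simulation

Each network activates four regions of interest (two per hemisphere,
mirrored): every dipole within 10 mm of the ROI center carries a half-cycle
5 Hz sine (100 ms lobe).  ROIs 1 and 2 start at 100 and 110 ms post-stimulus
at full amplitude; ROIs 3 and 4 start at 120 ms at 80% amplitude.  Four named
presets place the ROI centers at fixed angular positions chosen to preserve
the qualitative coverage contrasts of the anatomical regions they stand for
(occipital pole posterior; inferior temporal lateral-inferior, near the edge
of the cap; inferior frontal anterior-inferior; supramarginal
superior-lateral): `temporo_occipital`, `fronto_parietal`,
`fronto_occipital`, `temporo_parietal`.

Epochs are 1000 ms at 250 Hz with a 200 ms pre-stimulus window; 80 epochs per
run, half carrying ERP plus noise and half noise only.  The two-condition
design lets the evaluation subtract condition-independent reconstruction
bias, and the noise-only epochs double as the noise-covariance estimate.

**Noise.**  Pink (1/f) noise is generated by spectral shaping of white
Gaussian noise (exact zero mean, unit variance per channel).  By default,
independent pink-noise currents are placed on *every dipole* (radial moments)
and projected through the generating forward model, so the noise has the
spatial structure of brain activity; spatially-white sensor noise is
available via `noise_site = "sensor"`.  The source-space default follows the
description of the simulated data as brain activity *including noise*
projected to the scalp, and it reproduces the reported operating regime of
the original analysis (high subject-specific precision at -10 dB), which
spatially-white sensor noise does not — under sensor noise the cluster
analysis degenerates into near-chance behavior at the same nominal SNR.

**SNR.**  The SNR is the ratio of the peak amplitude of the ERP component to
the pre-stimulus peak-to-peak amplitude, in dB: the sensor with the largest
post-stimulus absolute amplitude of the noiseless ERP component is selected,
`A_peak` is that component amplitude, and `A_pp` is the mean over erp epochs
of the single-epoch pre-stimulus peak-to-peak amplitude at that sensor
(`20 log10(A_peak / A_pp)`).  The component peak is read off the clean
waveform rather than the noisy condition average deliberately: a peak taken
from the noisy average is itself inflated by noise and saturates the measure
near -16 dB, which would make the lower end of the studied range (-20 dB)
unreachable by any noise scale.  The noise scale is calibrated by bisection
against the very noise realizations that enter the epochs, so the measured
SNR of the delivered epochs is within 0.05 dB of the target (the acceptance
checks use the looser 0.5 dB bound).  The simulated dipole moment magnitude
is arbitrary (1 a.u.): only amplitude ratios and the SNR matter.

## Inverse solution

Reconstruction uses eLORETA, the weighted minimum-norm estimator whose
per-source symmetric 3x3 weight blocks satisfy the fixed point

```
W_i = [ K_i' (K W^-1 K' + a H)^+ K_i ]^(1/2)
```

with `K` the (pre-whitened) leadfield, `H` the average-reference centering
operator and `a` the regularization.  This choice gives exact localization of
single point sources in the noise-free case, which the tests verify by brute
force (50/50 random sources on a ~2000-dipole grid).  Numerical choices:

* noise covariance from the noise-only epochs (cleanest estimate available
  in the two-condition design; pre-stimulus windows are the alternative),
  with diagonal loading `0.05 * mean(diag)`;
* whitening by the inverse symmetric matrix square root of the covariance;
* `alpha = 1/9` by default (an evoked-data SNR-of-3 prior), rescaled by
  `trace(K W^-1 K')/n_sensors` each iteration so that a global rescaling of
  covariance, data and leadfield leaves the solution's shape unchanged;
* pseudo-inverses by eigendecomposition with a `1e-12` relative eigenvalue
  floor (handles the average-reference rank deficiency);
* the leadfield is rescaled to unit median column norm before iteration;
  current source density (CSD) is reported in arbitrary units;
* convergence when the largest relative weight-block change falls below
  `1e-6` (cap 100 iterations); non-convergence is reported, never silent.

Each epoch is reconstructed separately; the per-sample CSD is the Euclidean
norm of the estimated moment 3-vector (orientation discarded); per-condition
evoked CSD is the pointwise mean over epochs.

## Evaluation

Per subject and model variant: the noise-condition evoked CSD is subtracted
from the ERP-condition evoked CSD, averaged over 100-220 ms post-stimulus
(inclusive sample endpoints; 31 samples at 250 Hz), and thresholded to the
top 5% of dipoles (`ceiling(0.05 n)`, signed values, ties broken by dipole
index).  Active dipoles closer than 5 mm are adjacent; connected components
with at least 5 dipoles survive as clusters.  Cluster centers are unweighted
centroids (amplitude-weighted available), volumes are
`size * per_dipole_volume`.

ROIs with a cluster center within the classification radius (30 mm standard;
10 and 50 mm variants) are true positives, the rest false negatives; clusters
near no ROI are false positives.  One cluster within range of two ROIs
validates both — the rule is applied literally.  Sensitivity is
`TP/(TP+FN)` over ROIs; precision `TP/(TP+FP)` mixes ROI-level TPs with
cluster-level FPs, exactly as defined (flagged here because the two counts
live on different units).  Localization error averages center-to-center
distances of qualifying clusters per TP ROI; spatial dispersion is
`(sum of qualifying cluster volumes - ROI volume)/ROI volume`.  With no TP
ROIs, localization error and dispersion are `NA`; with no clusters at all,
precision is `NA` (undefined, never 0).  Thresholding signed rather than
absolute differences is deliberate: CSD is non-negative, and negative
differences mark noise-condition dominance, not ERP sources.

## The factorial experiment

`run_experiment()` crosses subjects x networks x SNR levels
(−20...0 dB) x head-model variants (subject/template x fem_meta /
fem_default / bem collapse) x classification radii.  The generating model is
always the subject's own `fem_meta`; the `subject_fem_meta` cell is thus the
inverse crime and upper bound.  Per-cell seeds derive from the master seed
and the cell's factor indices through a fixed integer hash, so cells are
order-independent and individually reproducible; with an output directory,
finished cells are written as CSV and reused on re-runs.  `ordering_report()`
condenses the study's qualitative claims into testable cohort medians:
subject-specific sensitivity at least the template's, subject-specific
localization error at most the template's, conductivity-preset effects
smaller than the subject-vs-template effect, and TP counts monotone in the
classification radius.

## Problem sizes

The package default keeps the 3 mm dipole spacing (about 7,000 dipoles).
The bundled acceptance-scale runs use reduced sizes chosen as this package's
desk-scale study conditions: a 6 mm grid (~1,700 dipoles) for the
exact-localization check, a 4 mm grid (~4,300 dipoles, still finer than the
5 mm adjacency rule so clustering behaves) with 6 subjects, 2 networks and
−10 dB for the ordering experiment, and a 6 mm grid for the SNR calibration
target.  All are plain parameters; scaling them up changes runtimes, not
code paths.

## Known limitations

* Spheres have no cortex: absolute sensitivity/precision/error magnitudes are
  not comparable to MRI-based pipelines; only orderings and mechanism are.
* Symmetric ROI pairs close in angle (e.g. the two occipital-pole analogues)
  can merge into one cluster, capping attainable sensitivity.
* The template error model covers geometry scale and cap placement only.
* The precision metric inherits the ROI-vs-cluster unit mix of its
  definition.
* No trial-to-trial latency or amplitude jitter, no artifacts, no real-EEG
  preprocessing; those belong to pipelines with access to real data.
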