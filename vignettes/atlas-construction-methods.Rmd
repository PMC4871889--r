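---
title: "Atlas propagation, groupwise templates and laterality: methods and design choices"
author: "chronoatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas propagation, groupwise templates and laterality: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoatlas)
```

## The problem

Parcellated brain atlases assign an anatomical region ID to every voxel of
a reference image. Most richly labeled atlases describe the adult brain,
while neonatal images differ from adult ones in size, shape and — because
myelination reverses the gray/white intensity ordering of T1-weighted
images — in tissue contrast. Registering an adult atlas directly onto a
neonate therefore fails or is badly biased. `chronoatlas` implements the
standard remedy: walk the labels *down* a ladder of age-specific templates
(adult → late childhood → … → neonate), where each rung is a small,
tractable registration problem, and compose the per-rung transforms into a
single mapping. On top of this it provides groupwise template construction
(including a left-right symmetric variant for laterality studies),
majority-vote label fusion, EM tissue classification, regional volumetry
and an asymmetry index, plus a synthetic-phantom generator so that the
entire pipeline can be exercised and validated without any clinical data.

## Coordinate and transform model

All grids are regular and axis-aligned; the world position of voxel
`i` (0-based) is `origin + i * spacing` (mm). A registration's output
transform follows the *pull-back* convention: it maps target-space
coordinates into source space, so source intensities can be sampled onto
the target grid. A composite transform is evaluated literally as

$$T(\mathbf{x}) = A\mathbf{x} + \mathbf{t} + D(\mathbf{x}),$$

an affine part plus a dense displacement field that lives on the target
grid and is interpolated linearly between its nodes. Chains of such
transforms (`concat_chain()`) are applied link by link; label maps are
resampled **once**, through the whole chain, with nearest-neighbour
interpolation (ties at an exact half-voxel round toward the lower index —
a documented, deterministic rule), which avoids the cumulative
nearest-neighbour erosion that per-rung resampling would cause. Intensity
images use cubic B-spline interpolation with the standard recursive
prefilter, so grid values are reproduced exactly and polynomials up to
cubic degree are represented exactly away from the grid boundary (the
mirror boundary condition perturbs the prefilter within a few voxels of
the edges). Voxels mapping outside the source domain are filled with 0 for
both intensities and labels.

## Registration

Each pairwise registration runs an affine stage followed by a symmetric
diffeomorphic stage, both on a four-level Gaussian image pyramid
(downsampling by 2 with anti-aliasing sigma 0.85 voxels) with per-level
iteration caps of 100, 100, 100 and 20 and a convergence test on the
relative metric change over five iterations (tolerance `1e-5`).

**Affine.** A similarity transform (translation, rotation, per-axis scale)
is initialized from thresholded-mask image moments — the centre of mass
matches the translation and the second moments the scale; because the mask
ignores intensity values, the initialization is immune to contrast
inversion — and refined by Nelder-Mead on the image metric.

**Diffeomorphic.** The deformation is a stationary velocity field `v` on
the fixed grid, exponentiated by scaling-and-squaring, so the forward map
`exp(v)` and inverse `exp(-v)` are mutual inverses by construction and
fold-free for smooth `v` (positive Jacobian, checked each iteration; a
folding update is halved and retried). Demons-style update forces are
computed in both directions — fixed versus warped moving, and the same
expression with the image roles exchanged — and antisymmetrized. Updates
are smoothed with sigma 1 voxel, clamped per voxel at 0.25 voxels, and the
velocity is smoothed with sigma 2 voxels after each update. These are
algorithm defaults, all overridable through `registration_config()`.

**Metrics.** Normalized cross-correlation (NCC) drives intra-modality
steps; Studholme normalized mutual information, `(H(A)+H(B))/H(A,B)`,
drives steps whose contrast differs, since it is invariant under any
bijective remapping of histogram bins. Two numerical choices matter here:

* the optimizers evaluate NMI on a joint histogram smoothed with a 1-bin
  Parzen kernel, so the objective varies smoothly with small transform
  changes (the reported NMI remains the plain histogram estimate);
* because the demons force is a difference force, NMI-driven registration
  first remaps the warped moving intensities through the joint-histogram
  transfer function (the mean fixed intensity per moving-intensity bin).
  The conditional-mean transfer carries a small systematic bias in
  partial-volume ramps, which — integrated over hundreds of iterations —
  can materialize as a spurious sub-voxel boundary drift. Differences
  smaller than 4% of the intensity range (well below any modeled tissue
  contrast) are therefore treated as matched ("deadband"); this removed a
  roughly one-voxel rim contraction per chain link in our validation runs
  while leaving genuine misalignment forces (which are of edge-contrast
  magnitude) untouched.

## Temporal propagation

`build_temporal_chain()` registers the target to the youngest template,
each template to its older neighbour, and the oldest template to the
labeled reference, and concatenates the pull-back transforms. Inter-stage
and template-to-reference links use NMI; the final target-side link is
intra-modality and uses NCC. The chain records per-link convergence and
post-warp NCC; `evaluate_chain_cc()` reports the per-step NCC between each
warped older template and its younger neighbour, the standard accuracy
summary for spatio-temporal ladders. The ladder length is left to the
caller: beyond a certain density additional rungs yield no measurable
benefit, so the module accepts any sequence of two or more templates.

## Groupwise (symmetric) templates

`build_template()` alternates, for a fixed number of outer iterations
(default 4): (a) diffeomorphic registration of every subject to the
current template; (b) an appearance update — the voxelwise mean of the
warped subjects (a plain mean; no Laplacian sharpening); and (c) a shape
update that applies a fraction (`shape_step = 0.25`) of the inverse of the
mean forward displacement field, so the template drifts toward the group
mean shape. Subjects are expected to be affinely pre-aligned; the
registrations inside the build use identity affine initialization.

Initialization matters for the diagnostics: when the build starts from the
voxelwise mean of the subjects, the first-iteration template is blurred,
the registrations under-recover displacement, and the mean per-subject
displacement *rises* as the template sharpens. Started from a sharp
external template — the intended study design, where an age-matched
external template initializes the build — the mean per-subject
displacement decreases or plateaus, the mean residual field shrinks well
below half a voxel (shape centering) and the template sharpness (mean
gradient magnitude) is non-decreasing. The diagnostics table reports both
quantities (`mean_disp_mm`, `mean_field_mm`) per iteration.

The symmetric variant mirrors every subject along the left-right axis
(first grid axis) and treats the mirrored images as independent subjects.
Label maps for the mirrored subjects must be mirrored **and** have their
left/right partner IDs swapped (`flip_labels_lr()`); without the swap the
fused parcellation would be anatomically inconsistent. Pairing is an
explicit scheme table rather than ID parity arithmetic, because real label
schemes break parity (an unpaired midline structure between paired IDs).

## Fusion, volumetry and laterality

`majority_vote()` takes the per-voxel most frequent label with ties broken
toward the smallest ID (deterministic and reproducible). Volumes are voxel
counts times voxel volume, in cm³; lobar volumes are reported as
percentages of a brain-mask volume. The asymmetry coefficient

$$S = \frac{2\,|V_L - V_R|}{V_L + V_R} \in [0, 2]$$

is computed per paired region; a perfectly symmetric template with
error-free fusion gives \(S = 0\) everywhere, so the maximum \(S\) over
regions of the symmetric atlas is a direct measure of residual
construction error.

## EM tissue segmentation

`em_tissue_segment()` fits per-class Gaussian intensity models modulated
by spatial prior maps: the E-step multiplies class likelihoods by the
priors and normalizes per voxel; the M-step re-estimates means and
variances from the posteriors. Class means initialize from prior-weighted
intensity averages, falling back to intensity quantiles when the priors
are uninformative (with flat priors the procedure is exactly a plain
Gaussian-mixture EM). Variances are floored at `1e-6` of the intensity
range (flagged when hit); the log-likelihood is asserted non-decreasing.
There is no Markov-random-field term and no bias-field estimation inside
EM — bias correction is treated as an upstream preprocessing step —
which is a documented simplification of the full published model. Cohort
tissue probability maps are voxelwise means of per-subject posteriors,
renormalized to sum to one.

## The synthetic generator

`make_phantom()` builds a concentric "head" (CSF rim, gray-matter ribbon,
white-matter core) with four pairs of deep blobs, an unpaired midline bar,
and five named landmarks at structure extrema. Intensities are piecewise
constant per tissue with mild partial-volume smoothing (sigma 1 voxel) —
deliberately simple, so metric behaviour stays analyzable. A laterality
factor scales a pair's left blob to a chosen volume ratio, giving a known
ground-truth \(S\).

`make_cohort()` warps the phantom by random Gaussian-smoothed stationary
velocity fields (amplitude 3 voxels, smoothness sigma 4 voxels by
default — a realistic inter-subject shape variation at this grid scale),
exponentiated so every true warp is fold-free, then applies a smooth
multiplicative bias field (default amplitude 0.05, emulating the residual
inhomogeneity left *after* upstream bias correction, since registration
inputs in the modeled pipeline are bias-corrected) and Gaussian noise
(default 2% of the intensity range). True labels, transforms, landmark
positions and velocities are retained so recovery can be measured exactly.
`make_aging_sequence()` emulates the developmental ladder: structure size
shrinks monotonically (default scales 1.0 → 0.8 over six stages) and the
white-matter intensity crosses the fixed gray level exactly once (0.9 →
0.3 around gray 0.5), reproducing the contrast inversion that motivates
NMI for inter-stage registration.

What the phantoms deliberately do **not** model: MRI acquisition physics,
anatomically realistic cortical folding, through-plane effects (the test
conditions are 2D; all algorithms are rank-generic and accept 3D arrays),
and texture inside tissue classes. The last point has a methodological
consequence: within large flat regions the true deformation is
unobservable in principle (the aperture problem), so endpoint-error
recovery is assessed on coherent localized deformations
(`make_bump_deformation()`), which are observable wherever they act, while
random-field cohort warps are validated through landmark transfer and
label overlap instead. Passing these tests demonstrates correct mechanics
and calibrated accuracy on controlled geometry; it does not by itself
certify performance on clinical images.

## Validation toolkit

Landmark transfer error is the Euclidean distance (mm) between true and
transferred landmark positions. Rater agreement uses the intraclass
correlation coefficient in its two-way mixed, single-measures, consistency
form — ICC(3,1), `(MS_targets − MS_error) / (MS_targets + (k−1) MS_error)`
— the common reading of a "two-way mixed effects model" for repeated
landmark placement by a fixed set of raters. Label overlap uses the Dice
coefficient.

## Problem sizes and seeds

The bundled study conditions are 2D: cohorts of 8 subjects on 128×128
grids for the symmetric-template analysis, a 6-stage 128×128 ladder for
the chain-quality analysis, and 10 subjects on 96×96 grids at 1 mm spacing
for landmark validation; the test suite uses 64×64 analogues of the same
generators. Every random quantity derives from an explicit integer seed
through a fixed mixing function, so all outputs are bit-reproducible; the
end-to-end driver writes a manifest with config and output checksums.

## Known limitations

* 2D conditions are the tested regime; 3D code paths share the same
  rank-generic implementation but carry 3D-specific cost (B-spline
  stencils of 64 taps) and are not exercised at scale by the suite.
* The demons-style optimizer recovers deformation only where image
  evidence exists; flat-region displacement is filled in by the smoothing
  prior, not estimated.
* The affine stage covers translation, rotation and per-axis scale;
  shear is not optimized.
* Oblique or sheared grid orientations, 4D containers and sub-voxel
  origin bookkeeping beyond the stated convention are out of scope.
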