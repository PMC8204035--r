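---
title: "Measuring canine eruption from paired CBCT: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring canine eruption from paired CBCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(erupt3d)
```

# The measurement model

Two CBCT volumes of the same patient are taken months apart. Between them the
head was repositioned (a global rigid motion of everything) and the tooth of
interest erupted (an additional local rigid motion of the tooth alone; we
treat the tooth as a rigid body and ignore resorption, which shows up only as
a small volume change in the reports). The measurement question is: what is
the local motion, expressed in clinically meaningful axes?

The pipeline answers it in three steps. First, rigid registration of the
follow-up scan onto the baseline over a *stable* bony region estimates the
inverse of the global motion. Applying it cancels repositioning, so whatever
motion remains at the tooth is eruption. Second, the tooth is segmented in
both (now co-registered) volumes. Third, the rigid transform between the two
tooth surfaces is estimated by ICP and decomposed into three translations and
three rotations in the tooth's anatomical frame.

The decisive modelling assumption is the choice of the registration region:
it must contain only structures that neither surgery nor growth altered
(bone away from the dentition). If the moving tooth leaked into the region,
the registration would "chase" it and the measured eruption would shrink
toward zero. The test suite checks this discrimination property directly:
with zero local motion and a non-zero global motion, all six reported
components must vanish (within 0.2 mm / 0.5 degrees), and with both motions
present the local one must be recovered.

# Rigid registration by mutual information

The similarity between the baseline intensities \(F\) and the transformed
follow-up intensities \(M \circ T^{-1}\) is mutual information,
\(MI = H(F) + H(M) - H(F,M)\), computed in bits from a joint histogram over
the voxels of the region of interest. Mutual information needs no intensity
calibration between the scans, which matters because CBCT units are not
standardized across devices.

Numeric choices (all package defaults, reported in the registration
metadata):

* **Histogram**: 64 x 64 bins; the fixed image contributes its stored voxel
  values (binned over the masked range), the moving image is sampled by
  trilinear interpolation and binned over its global range, so the bin edges
  do not move with the pose. Voxels mapping outside the moving field of view
  are dropped; at least 10% of the region must remain.
* **Pose parameterization**: axis-angle rotation about the ROI center plus
  translation. Axis-angle avoids Euler singularities inside the optimizer;
  centering the rotation at the ROI decorrelates rotation from translation.
* **Optimization**: three resolution levels (mean-pooled shrink factors
  4/2/1) with Nelder-Mead at each level. The initial simplex step is set to
  about one voxel at each level: a simplex started much smaller than the
  expected motion stalls on the flat, noisy parts of the MI surface (this is
  the single most failure-prone knob in the whole pipeline). At the coarsest
  level the search also restarts from the identity when a non-identity
  initialization is supplied, and keeps the better basin: same-patient scans
  are always near-aligned, and this makes the method insensitive to the
  operator's starting guess. At the finest level the search
  finishes on a *lightly smoothed* copy of both volumes (separable
  1/4-1/2-1/4 kernel), restarting the simplex with a shrinking scale until
  the pose stops moving (< 5e-4 mm/deg). The smoothing matters: the raw-intensity
  MI of a large flat bone face locks onto the voxel grid and develops
  shallow secondary maxima about one voxel away from the true pose, which
  occasionally trap the raw-metric search; the smoothed metric has no such
  ridge, so the polish walks out of the trap and also removes the
  staircase-induced bias of the raw optimum (typical phantom registration
  errors drop from ~0.06 mm to ~0.02 mm). Together these give run-to-run
  repeatability in the micrometre range. Poses beyond
  ±10 mm / ±15 degrees are rejected by a soft penalty: for same-patient
  follow-up imaging such a pose means the optimizer is lost, not that the
  head moved that far.
* **Sampling**: all ROI voxels, deterministically (a sampling fraction below
  1 is available and seed-controlled, but full sampling keeps the
  reliability re-enactment exactly reproducible).

# Tooth segmentation

Two routes produce the tooth surface.

**Livewire contouring** follows the interactive paradigm: on each traced
axial slice the user (here: the observer emulation) places anchor points near
the boundary and the computer finds the minimum-cost path between consecutive
anchors on the 8-connected pixel graph (Dijkstra; diagonal steps scaled by
sqrt(2); a step costs its length times the mean of the two endpoint costs).
The per-pixel cost is
\(w_g (1 - g/g_{max}) + w_z z + w_d d\) with Sobel gradient magnitude
\(g\), a binary Laplacian zero-crossing term \(z\), and a gradient-direction
incoherence term \(d\) computed per pixel from the 3x3 neighbourhood
(classical livewire scores direction agreement per *link*; the per-pixel
variant keeps the cost image independent of the path search and is what the
path oracle in the tests assumes). Default weights 0.43/0.43/0.14. An
important property of this edge-seeking segmentation is that it lands on the
gradient maximum regardless of the absolute intensity levels on either side,
unlike a global threshold, whose surface placement is biased wherever one
tissue interface (tooth against bone) has different levels than another
(tooth against soft tissue).

The traced contours are fused by **shape-based interpolation**: each closed
contour is rasterized on its slice and converted to a signed distance field
(negative inside; Euclidean distance via `EBImage::distmap`); distance
fields are interpolated linearly between traced slices along the stack axis
and thresholded at zero. Coronal/sagittal contours act as carving
constraints (the result must lie inside every covering contour) rather than
as fully fused distance fields; this preserves the multi-view idea while
keeping the operation monotone and testable. Slices beyond the first/last
contour stay empty, so the reconstruction can never extrapolate.

**Thresholding** (`threshold_segment` / `auto_segment`) selects an intensity
band, keeps the largest 6-connected component and extracts the surface. It
is the unattended route used in the automated pipeline runs.

**Surfacing** uses marching tetrahedra: each grid cube is split into the six
Kuhn tetrahedra around its main diagonal, a translation-invariant
decomposition whose shared faces agree between neighbouring cubes, so the
surface is watertight by construction (the classic 256-case cube table needs
disambiguation to guarantee this). Vertices are placed by linear
interpolation of the field along grid edges: for a binary mask this is the
edge midpoint, but for thresholding the package isosurfaces the *gray*
values, so the vertex lands at the interpolated threshold crossing. That
sub-voxel placement is what lets the part-comparison MAD resolve
registration differences of a few micrometres on a 0.2 mm grid — a binary
surface would quantize them away entirely.

# ICP and the six clinical components

The pre-operative tooth surface is registered onto the registered
post-operative surface by ICP: nearest point-to-triangle correspondences
(exact distances; a uniform-grid spatial index changes speed, never values)
alternate with the closed-form Kabsch/SVD rigid fit. A centroid alignment
warm-starts the iteration. Up to 3000 seeded sample vertices are used;
convergence is declared when the RMS change or the maximum pose-update
displacement drops below 1e-5 mm. Trimming a fraction of the worst
correspondences is available for surfaces with local artifacts, but the
default is no trimming: the extreme mesiodistal crown points are exactly the
ones that observe rotation about the tooth's long axis, and trimming them
degrades yaw recovery by an order of magnitude on the phantoms.

The recovered transform \(T\) is decomposed in the anatomical frame (rows:
mesiodistal, palatofacial, incisoapical; Gram-Schmidt orthonormalized;
supplied per case from landmarks or defaulting to scan axes for phantoms).
The rotation is expressed as \(R' = A R A^\top\) and split into extrinsic
Euler angles in the fixed order pitch (about M/D), roll (about P/F), yaw
(about I/A); positive angles are counter-clockwise. Euler orders do not
commute, so the order is printed in every report. Translation is reported as
the displacement of the pre-operative tooth centroid, \(T(c) - c\),
projected on the frame axes — not the raw translation column, which depends
on the rotation's lever arm and has no clinical reading. With |roll| within
0.5 degrees of 90 the pitch/yaw split is ill-conditioned and the result
carries a degeneracy flag. For right-side teeth the sign of the mesiodistal
component is flipped so + mesial reads the same on both sides; rotation
signs are reported in the scanner sense.

# Registration validation (part comparison)

Both co-registered volumes are cropped to the registration ROI, thresholded
to the bone band, surfaced, and the unsigned distance from every baseline
surface vertex to the follow-up surface is summarized as MAD ± SD (SD with
the population denominator n; the distances are already an exhaustive
census of the surface, not a sample). Distances are measured from the
baseline surface to the follow-up surface; a symmetrized average and signed
distances are available as options and the direction is declared in the
output. Note that cropping closes the surfaces at the ROI faces; those
closure faces sit at identical grid positions in both volumes and contribute
near-zero distances, so the whole-surface MAD is conservative relative to a
"bone surface only" reading. The tests therefore check the unregistered-
shift case on the flat bone face specifically.

# Reliability statistics

Agreement between repeated runs is ICC(2,1): two-way random effects,
absolute agreement, single measurement, from the ANOVA mean squares, with
the F-based 95% confidence interval. The absolute-agreement form is the
right one for two observers measuring the same quantity — a constant offset
between observers lowers it, unlike a consistency ICC. The form is printed
in every report. The Wilcoxon signed-rank test drops zero differences
(reporting their count), uses average ranks for ties, and computes the
two-sided p exactly for up to 25 retained pairs via the distribution of the
positive-rank sum over all sign assignments (a dynamic program over doubled
ranks, identical to full enumeration); beyond that a tie- and
continuity-corrected normal approximation is used. No multiple-testing
correction is applied across the component-wise comparisons, and the
reports say so.

# The phantom: what it emulates, and what it does not

Patient scans cannot ship with a software artifact, so validation runs on a
synthetic phantom that reproduces the *geometry of the measurement problem*:
a bone-like block containing trabecular-like pores of varied sizes (the
structure the registration locks onto), an embedded canine-like tooth, a
known global "repositioning" motion, a known local tooth motion, and
additive Gaussian intensity noise (default SD 5 on a background/bone/tooth
scale of 0/100/160, i.e. 5% of bone).

The tooth is a superellipsoid crown fused to a tapered cone root. The crown
is mesiodistally wide and palatofacially narrow (default semi-axes 5.0 and
3.5 mm, exponent 3), as canine crowns are; geometrically this is also what
makes rotation about the long axis observable at all — a surface of
revolution would leave yaw undetermined for any surface-matching method.
Default dimensions give a volume of ~369 mm^3, within the 300–600 mm^3
range of canine volumes at mixed-dentition age. The solid has a closed-form
volume, which anchors the segmentation accuracy tests to an analytic oracle.
Volumes are voxelized by voxel-center inclusion against the implicit solid
(exact and oracle-friendly); cohort motions are drawn uniformly up to
±3 mm / ±8 degrees per component (bracketing reported six-month eruption
magnitudes with margin) plus a smaller ±1 mm / ±2 degree repositioning.

What the phantom does *not* emulate: partial-volume blur, beam hardening,
scatter, metal artifacts, cleft-defect anatomy, neighbouring teeth, or bone
remodelling. Passing the phantom study therefore shows that the method's
geometry, numerics and statistics are sound under realistic noise and
motion; it does not certify performance on clinical image quality, where
segmentation is the step most exposed to the missing artifacts.

# The observer emulation

The reliability study design needs two independent "observers" per case. In
the original workflow the operator-dependent steps are the hand-cropped
registration region, the registration starting pose, and the livewire anchor
clicks. The emulation perturbs exactly these: each ROI face is shrunk inward
by up to 0.3 mm (shrink-only, so the unstable dentate region can never leak
in), the initialization is perturbed by up to ±0.5 mm / ±0.5 degrees, and
every anchor is jittered by up to ±1 voxel, all from a per-case, per-run
seeded stream. Because the registration is deliberately robust to its
initialization (identity multi-start), the between-run variability is driven
by the ROI crop and the anchor jitter — which matches the real situation,
where two trained observers differ in what they crop and where they click,
not in what the optimizer does. A scale knob multiplies all amplitudes; the
tests check that measured between-run disagreement grows with it.

# Problem sizes and budgets

The validation suite uses 20 phantom pairs for end-to-end transform
recovery, a 10-pair x 2-run study for the reliability re-enactment (both at
the clinical 0.2 mm voxel size on a 116 x 116 x 176 grid), and a coarser
0.4 mm phantom for unit tests of the pipeline plumbing. These sizes keep a
full run on one CPU in the tens of minutes while leaving every tolerance
comfortably non-trivial: the recovery thresholds (0.2 mm / 1.0 degree per
component) sit 2–5x above the observed worst-case errors, and the
reliability thresholds are the inter-observer values a two-human study of
this design reports.

# Known limitations

* The registration assumes the two scans are of the same patient and
  near-aligned; there is no global search and no deformable model.
* The tooth is treated as rigid; root resorption appears only as a volume
  difference, not as a shape analysis.
* Shape-based interpolation is anchored on axial contours with orthogonal
  carving; a full 3D variational fusion of arbitrarily oriented contours is
  out of scope.
* The DICOM reader supports single-series, uncompressed little-endian
  slices only (reading; writing uses MetaImage/NIfTI, plus a minimal DICOM
  writer for fixtures).
* ICC forms other than ICC(2,1) agreement are not provided.
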