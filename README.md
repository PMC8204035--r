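# erupt3d

Quantifying three-dimensional tooth eruption from paired CBCT scans.

After secondary alveolar bone grafting in patients born with unilateral cleft
lip and palate, clinicians need to know how far (and in which directions) the
maxillary canine has moved between the pre-operative scan and a follow-up
scan. Landmark- and cephalometry-based measurements are noisy; `erupt3d`
implements a landmark-free, registration-based measurement:

1. **Stable-region registration.** The follow-up volume is rigidly registered
   onto the baseline by maximizing mutual information
   `MI = H(F) + H(M) − H(F, M)` over a region of interest restricted to bone
   that surgery and eruption do not alter. This removes head repositioning
   while leaving true tooth motion in the data.
2. **Tooth segmentation.** The canine is delineated either by livewire
   contouring (minimum-cost boundary paths between anchor points, with
   shape-based interpolation of the contour stack through signed distance
   fields) or, for unattended use, by intensity thresholding; surfaces are
   extracted at sub-voxel precision by marching tetrahedra.
3. **Motion decomposition.** The rigid motion between the pre-operative and
   registered post-operative tooth surfaces is recovered by iterative closest
   point (Kabsch/SVD per iteration) and decomposed in the tooth's anatomical
   frame into six clinical components: mesiodistal, palatofacial and
   incisoapical translation of the tooth centroid (mm) and pitch, roll, yaw
   (degrees, extrinsic, about the M/D, P/F and I/A axes respectively).
4. **Validation machinery.** Registration accuracy is summarized as the mean
   absolute surface distance (MAD ± SD) between thresholded ROI surfaces
   ("part comparison"); measurement reliability as ICC(2,1) with 95% CI plus
   Wilcoxon signed-rank comparisons; a synthetic phantom generator produces
   paired CBCT-like volumes with known ground-truth motions so the whole
   pipeline can be validated without patient data.

## Worked example

Generate a synthetic case with a known tooth motion and measure it:

```r
library(erupt3d)
cohort <- batch_generate(1, phantom_spec(), seed_list = 3)
pair <- cohort$pairs[[1]]
case <- run_case(pair$pre, pair$post, roi = pair$roi, frame = pair$frame,
                 tooth_band = c(130, Inf), bone_band = c(50, 130))
print(case)
```

```
Tooth motion (anatomical frame, left side):
  translation  M/D -1.968  P/F +1.816  I/A -0.719  mm
  rotation   pitch -2.414  roll +1.585  yaw +1.609  deg  (extrinsic pitch(M/D) -> roll(P/F) -> yaw(I/A))
  volume     pre 368.11  post 368.04  mm^3
registration part comparison: MAD 0.0282 +/- 0.0521 mm (110504 vertices)
```

The six numbers are the tooth's displacement and rotation between the two
time points: here the tooth moved 1.97 mm distally (negative M/D), 1.82 mm
facially and 0.73 mm apically, with small rotations about all three axes.
The part-comparison MAD (0.028 mm, far below the voxel size of 0.2 mm) says
the stable-bone registration is sound. The generator's ground truth for this
case is −1.977 / +1.872 / −0.691 mm and −2.756 / +1.634 / +1.670 degrees, so
every component is recovered within 0.06 mm / 0.35 degrees.

A thin CLI over the same functions is installed with the package
(`system.file("cli", "erupt3d", package = "erupt3d")`) with subcommands
`simulate`, `register`, `segment`, `analyze`, `validate-reg`, `validate`,
`run` and `config`.

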