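---
title: "Quantifying dynamic wrist movement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynamic wrist movement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

carpo quantifies carpal kinematics from 2D+time wrist images acquired during
continuous radial--ulnar deviation ("waving"): per frame it derives the
scapholunate (SL) gap width, the lunotriquetral (LT) gap width and the wrist
angle from a multi-class semantic segmentation of eight bone classes
(radius, ulna, scaphoid, lunate, triquetrum, hamate, capitate,
trapezium/trapezoid). The processing chain is

1. intensity preprocessing (percentile clipping, Z-score, biquadratic 2x
   upsampling),
2. U-Net segmentation with a summed Dice + Hausdorff-distance loss,
3. post-processing (mean-field CRF, Gaussian-weighted temporal label
   voting, morphological cleanup with largest-component selection),
4. measurement (proximal-row fusion, carpal-arc centerline, gap widths,
   bounding-box wrist angle), and
5. evaluation (per-class Dice, Bland--Altman agreement, subject-level
   splits, movement-cycle frame selection).

Because annotated dynamic wrist MRI is not redistributable, the package
ships a synthetic articulated-wrist phantom that generates image sequences
with pixel-perfect label masks and known gap/angle truth curves; every
stage is validated end-to-end against this truth channel.

# The synthetic phantom

## Geometry

Bones are parametric shapes rasterized at arbitrary resolution. The radius
and ulna are superellipses (exponent 3.5) fixed in the frame; the distal
row (hamate, capitate, trapezium/trapezoid) consists of superellipses rigid
with the moving carpus. The proximal row (scaphoid, lunate, triquetrum) is
laid out along a carpal arc of radius 30 mm, and each proximal bone is a
*rounded annulus sector*: its end faces lie along radii of the arc. This
choice matters for measurement fidelity: with tangent-oriented
superellipses the facing cortices of adjacent bones form a wedge of roughly
25 degrees, so the apparent gap varies by ~0.25 mm for every 0.5 mm the
measurement line deviates from the arc -- which would make sub-half-pixel
gap recovery impossible at 0.5 mm/px. With radial end faces the inter-bone
separation is nearly constant across the width of the row and equals the
prescribed arc-length gap.

Dimensions approximate an adult wrist (forearm bone shafts 10--13 mm wide,
carpal bones 9--14 mm). The articulated wrist needs a field of view of at
least 84 mm at every pose; `generate_sequence()` refuses smaller frames.

## Motion model

The pose angle follows a cosine-eased sweep
`angle(t) = min + (max - min) * (1 - cos(2 pi t / T)) / 2`
from the radial extreme (default -15 deg) to the ulnar extreme (default
+35 deg) over the first half of the sequence and back, emulating one full
"waving" cycle per acquisition. The true per-subject motion profile of a
volunteer is unknowable; the cosine easing is a modelling choice that gives
smooth, bounded angular velocity.

The carpus (both rows) rotates rigidly about the centre of the forearm
bounding box. An anatomical pivot sits near the capitate head, but the
package's wrist-angle definition -- the angle between the forearm-box and
distal-row-box centres, referenced to the forearm long axis -- recovers the
pose angle exactly only when the rotation pivot coincides with the forearm
box centre; with a capitate-head pivot the centre-to-centre angle
underestimates the pose by the lever-arm ratio (about 2.5x at 35 deg). We
prioritise geometric consistency between the generator and the measurement
definition, so the phantom uses the forearm-box-centre pivot. Consequences:
the proximal row translates laterally across the radius at extreme poses,
which a real wrist does not do; none of the measured quantities depend on
this.

## Gap truth

Healthy wrists keep near-constant gaps with a slight linear decrease during
ulnar deviation: SL 1.70 mm at neutral with slope -0.002 mm/deg, LT 1.30 mm
with slope -0.003 mm/deg. The SL-injury mode is piecewise linear: SL stays
at about 4 mm up to +10 deg and collapses to 1 mm at +35 deg; LT starts at
0.7 mm and rises to 1.2 mm. Both functions can be replaced by arbitrary
`angle -> mm` mappings in `phantom_spec()`.

The intra-row layout is recomputed every frame so that the arc-length
separations equal the truth functions; the truth channel therefore provides
exact per-frame `(angle, sl, lt)` triplets alongside the masks. Masks are
rasterized on a grid `mask_scale` times finer than the native image
(default 2, matching the upsampled working resolution); a gap narrower than
one mask pixel raises a degenerate-geometry error, since it cannot be
represented.

## Image formation and noise

Intensities are two-level (bone 1.0, background 0.15) with partial-volume
edges from 3x sub-pixel supersampling, plus additive Gaussian noise on the
normalized intensities (default SD 0.05, a conservative SNR for a 1.5 T
radial FLASH acquisition). Rician noise, coil-sensitivity profiles,
undersampling streaks, soft tissue texture and out-of-plane motion are
deliberately absent: passing the package's tests demonstrates correctness
of the algorithms under controlled conditions, not robustness to the full
complexity of in vivo MRI.

# Preprocessing

Each frame is clipped to its own 10th/99th percentiles (linear-interpolation
percentile convention), Z-scored per image (population-SD convention, so a
balanced two-valued image maps exactly onto {-1, +1}), and upsampled 2x by
separable quadratic (order-2) interpolation after a Gaussian anti-aliasing
pre-filter (SD 0.5 px), halving the pixel spacing (168 px at 1.0 mm/px
becomes 336 px at 0.5 mm/px). Note that percentile clipping by construction
pins the lower ~10% of pixels to the band edge. Vector polygon annotations
are scaled by the same factor of 2.

Augmentation (training only) draws Gaussian noise SD from [0, 0.2],
mirroring along x, horizontal shifts up to +/-10% of the width, in-plane
rotations within +/-15 deg and zoom within +/-10%, composed into a single
affine map applied with nearest-neighbour resampling to image and mask
alike; noise is applied to the image only. Out-of-frame pixels are filled
with the median intensity (the background mode after Z-scoring) in the
image and with background in the mask.

# Segmentation network

`unet_spec()` describes a classic symmetric U-Net: per level two 3x3
convolutions each followed by batch normalization and ReLU, 2x2 max-pooling,
a symmetric decoder with 2x2 transposed convolutions and skip
concatenations, and a 1x1 head mapping the final 64 feature channels to the
class scores. The eight foreground classes are complemented by an explicit
background channel under a per-pixel softmax, so every pixel carries a
label; the losses are computed over foreground classes only.

Two loss terms are summed unweighted:

* **Soft Dice**: `1 - (2 sum(p t) + s) / (sum(p) + sum(t) + s)` with
  smoothing `s = 1e-6`, averaged over the foreground classes present in the
  target.
* **Distance-transform Hausdorff surrogate**: per present class, the
  squared score error is weighted by the sum of squared Euclidean distance
  transforms of the target and of the hard prediction (normalized by the
  squared image diagonal), so a mislabeled pixel contributes proportionally
  to its squared distance from the target. The prediction's distance
  transform is treated as constant in the gradient, which makes the loss
  piecewise differentiable.

With foreground-only losses, a class that happens to blanket the image
early in training receives vanishing Dice gradients (the denominator grows
quadratically) and optimization can stall in that state. `build_unet()`
therefore initializes the head bias at +2 logits for the background
channel: training starts from an all-background prediction and foreground
classes grow outward from their targets, where the Dice gradient is
informative.

Training uses Adam (default learning rate 0.1, weight decay 1e-8, 500
epochs, batch size 4) under a multi-step schedule (gamma 0.1 at epochs 10,
50, 100, 150, 250), mirroring the full-scale protocol. The 0.1 rate is
aggressive and retained for fidelity; the documented stable alternative for
small CPU runs -- used by the package's own tests -- is `lr = 1e-3` with no
milestones. Forward/backward passes are implemented on im2col + BLAS gemm
(single-precision inside the convolution kernels; parameters, activations
and reductions in double).

# Post-processing

**CRF.** Mean-field inference with two truncated Gaussian pairwise kernels
under Potts compatibility: an appearance kernel over position and intensity
(SDs 8 px and 0.5 Z-units) and a smoothness kernel over position (SD 3 px);
5 iterations. Messages are normalized by the spatial kernel mass, so the
mixing weights (defaults 2 and 1) live on the scale of the unary log-odds:
a unanimous neighbourhood contributes at most `w` to a label's potential,
and the CRF cannot steamroll a confident unary. An un-normalized variant
with the same SDs would apply pairwise potentials two orders of magnitude
above the unaries and visibly erode correct boundaries.

**Temporal voting.** Per frame, class and pixel, the binary allocations of
a five-frame window (two before, two after) are combined with Gaussian
weights discretized at offsets -2..2 and normalized to sum to 5, so the
cumulative allocation ranges from 0 (never assigned) to 5 (always
assigned). The mean allocation (cumulative / 5) is compared with the 0.6
threshold; failing pixels become background, and when several classes pass,
the highest mean wins. Window truncation at the sequence ends renormalizes
the weights to the truncated length. The Gaussian width is 1.2 frames: with
a width of 1.0 the centre weight is 2.013 and a pixel missing from only the
centre frame scores (5 - 2.013)/5 = 0.597 < 0.6, so the stage would punch
single-frame holes into stable segmentations; at 1.2 the centre weight is
1.717, a single-frame flicker scores 0.343 (removed) and a single-frame
dropout 0.657 (kept). Voting consumes hard labels, and the threshold
applies to the mean rather than the cumulative sum.

**Morphology.** Per class: binary opening then closing with the 5-pixel
cross (centre + 4-neighbours), then retention of the largest 4-connected
component. Opening with the cross necessarily clips sharp rasterized
corners (a square loses its four corner pixels); at the 0.5 mm/px working
resolution this effect is negligible, which is one reason the package
performs all label-domain post-processing at the upsampled resolution.

# Measurements

**Fusion.** The scaphoid, lunate and triquetrum masks are united and closed
with a disc whose radius escalates from 5 px until the union is a single
connected region (up to 12 px; beyond that a fusion error is raised). At
0.5 mm/px the default bridges gaps up to about 5 mm, enough for an injured
SL gap of 4 mm.

**Centerline.** The fused region is skeletonized (Zhang--Suen thinning),
the longest geodesic path through the 8-connected skeleton is extracted by
a double breadth-first sweep, and the path is smoothed by cubic smoothing
splines in arc-length parameterization (degrees of freedom scale with path
length, capped at 12). Because the medial axis stops about half a region
width short of the region ends, the curve is extrapolated along its end
curvature (algebraic circle fit of the last segment, straight-tangent
fallback) until it exits the region. The curve is oriented
radial-to-ulnar using the scaphoid centroid.

**Gap widths.** Walking the centerline, the SL gap is the Euclidean
distance between the point where the curve leaves the scaphoid and the
point where it enters the lunate; LT analogously for lunate/triquetrum.
Crossings are located at the 0.5 level of each bone's binary mask smoothed
with a Gaussian of SD 1.3 px and sampled bilinearly along the curve: the
smoothed coverage field localizes the rasterized cortex with sub-pixel
accuracy, roughly halving both the quantization error and the dependence of
the measurement on the grid orientation compared with raw binary crossings.
Bones touching along the curve yield a zero gap; a curve that misses a bone
flags the affected gap invalid.

**Wrist angle.** Minimum-area (rotated) bounding rectangles are computed
for the forearm group (radius + ulna) and the distal row (hamate +
capitate + trapezium/trapezoid) by rotating calipers over the convex hull
of the pixel centres. The angle is measured between the vector joining the
two box centres and the long axis of the forearm box, with the sign
resolved via the radius/ulna centroids (radial deviation negative, ulnar
positive). The forearm long axis -- rather than the image vertical -- is
the reference because the forearm is mechanically fixed during acquisition
and manual protocols draw the reference vector along the forearm.

Gap measurement operates at the interpolated (0.5 mm/px) resolution; the
upsampling exists precisely to refine the gap definition.

# Evaluation utilities

Per-class Dice coefficients are computed per image and class, then
averaged (mean +/- SD per class plus a pooled overall row); a class absent
from both masks scores 1. Bland--Altman agreement reports the mean
difference, its SD and the limits of agreement (mean +/- 1.96 SD).
Subject-level splits keep both wrists of a subject on the same side and
reproduce the study arithmetic (28 subjects x 2 wrists x 15 frames with 21
training subjects gives 630/210 images). Movement-cycle selection picks n
frames at equal temporal spacing across one radial-to-ulnar cycle
(`identify_cycle()` provides an angle-extrema heuristic; on real data the
cycle was chosen by a radiologist, and no fidelity to that manual choice is
claimed).

# Problem sizes used by the test suite

The full-scale protocol (336 x 336 inputs, depth-4/64-channel U-Net, 500
epochs) is far beyond a desk-scale CPU budget, and reproducing the study's
real-data Dice tables is out of scope. The package's own experiments use:

* phantom sequences at the study matrix (168 px, 1.0 mm/px) for counting
  and measurement-recovery checks (30 s / 100 ms gives 300 frames;
  recovery uses 30 frames across the full sweep, truth masks at 336 px);
* a desk-scale learning experiment with an 84 px phantom upsampled to
  168 px (the study's working scale in every respect except the matrix
  size), a depth-2/base-16 U-Net, 64 training and 16 held-out frames,
  14 epochs at `lr = 1e-3` -- enough for held-out mean foreground Dice
  well above 0.9 -- followed by full post-processing on a 40-frame
  consecutive block at the study's per-frame motion rate.

# Known limitations

* DICOM input is not supported (no DICOM reader in the R dependency
  stack); NIfTI, multi-page TIFF and CSV are.
* The phantom is 2D and rigid-per-row: no flexion/extension, out-of-plane
  rotation, or per-bone kinematics; noise is Gaussian, not Rician.
* The CRF parameters are package defaults, not learned; the temporal
  stage assumes slow motion relative to the frame interval (at the study's
  ~10 frames/s a boundary moves well under a pixel per frame).
* Training at the full protocol scale is supported by the code but not
  exercised by the tests; no claim is made about real-data segmentation
  accuracy.
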