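---
title: "Mosaicking aerial crop-field video: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mosaicking aerial crop-field video: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldmosaic)
```

## The problem

Freely flown drone video of a crop field should yield a single field-scale
mosaic in which every plant keeps its relative position, using only the
imagery — no GPS, telemetry, or ground control points. Crop fields make this
hard in a specific way: the scene is thousands of visually similar plants
arranged in a periodic row/alley lattice, so feature matching is starved of
unique landmarks, and small per-pair registration errors accumulate as the
frame-to-frame homographies are chained across hundreds of frames.

`fieldmosaic` implements a 2-D mosaicking pipeline built around three ideas:

1. **Temporal structure.** Video frames are ordered; consecutive frames
   overlap heavily. Registration is only ever attempted between temporally
   adjacent images, which makes the pipeline linear in the number of frames.
2. **Grouped chaining.** Frames are organised into groups that share one
   *reference* frame; each frame registers directly to its reference
   (`H_CR`), references register to the previous reference (`H_RR`), and
   references chain to the shot's *base* frame (`H_RB`). A frame reaches
   mosaic coordinates through `H_CB = H_RB %*% H_CR`, so the error chain has
   length "number of groups", not "number of frames".
3. **Shot segmentation.** Abrupt viewpoint changes break the smoothness
   assumption. The video is first segmented into *shots* (scene-consistent
   segments); each shot yields a mini-mosaic, and mini-mosaics are merged
   into a meta-mosaic where they overlap.

## The planar model

All geometry is projective: a 3x3 homography `H` (normalized so
`H[3, 3] = 1`) maps 0-based pixel-center coordinates of one planar view into
another. This assumes the field is approximately planar and plants do not
move between overlapping frames; both assumptions degrade gracefully (local
blur) rather than catastrophically in practice, but they are assumptions —
see *Limitations*.

Homographies are estimated from point correspondences by the
Hartley-normalized direct linear transformation, robustified by RANSAC
(random 4-point samples, symmetric-transfer-error scoring, least-squares
refit on the consensus set), and then *photometrically refined*: a
Gauss-Newton minimization of the intensity difference between the reference
image and the warped current image over a subsampled pixel grid, with the
worst 10% of residuals trimmed each iteration. The refinement exists because
feature-only estimates carry a small localization bias that is correlated
across keypoints (all corner estimates share the same interpolation phase);
the bias is invisible per pair (well under half a pixel) but accumulates
coherently along a chain. On noiseless synthetic flights the refinement
reduces the 100-frame chain error from several pixels to well under one.
It is enabled by default (`register_policy(refine = TRUE)`) and disabled
automatically when registering mini-mosaics to each other, whose unfilled
canvas regions would bias an intensity criterion.

## Descriptor ladder

Three descriptor rungs sit behind one interface, tried in order by
`adaptive_register()` until the post-RANSAC inlier ratio reaches the
acceptance threshold (default 0.40, applied per pair):

* `"st"` — structure-tensor corners: the minimum eigenvalue of the smoothed
  gradient outer-product, with at most one keypoint per 8x8 micro-block and
  a raw normalized 9x9 patch descriptor. Fast, upright; the workhorse for
  large-overlap pairs.
* `"fast_local"` — dense non-max-suppressed corners with larger (15x15,
  spacing 1.5) illumination-normalized patches. More keypoints and more
  context, still upright.
* `"affine_robust"` — as `"fast_local"`, but each patch is rotated to the
  keypoint's dominant gradient orientation (36-bin magnitude-weighted
  histogram, parabolic peak interpolation), making the descriptor invariant
  to in-plane rotation. This rung is what recovers registration across
  abrupt viewpoint jumps; full affine tilt sampling is not implemented, so
  robustness to extreme out-of-plane tilt is limited.

Keypoints are capped at the strongest 5000 per frame (detector response,
deterministic `(y, x)` tie-break); matching is nearest-neighbour with a 0.75
ratio test and greedy one-to-one assignment. RANSAC uses a 2 px tolerance
and at most 2000 iterations with the standard adaptive early stop; all
sampling is seeded, so registrations are reproducible.

## Grouping and chaining rules

Scanning a shot in order, a frame joins the open group unless the group
already holds 40 members (the 41st member starts a new group) or the frame
center, mapped through `H_CR`, has moved more than one third of the frame
width in x or of the frame height in y. The displacement test uses the frame
*center* (corners exaggerate rotation; translation components ignore it) and
is axis-wise, matching the "height or width" reading of the rule. The frame
that triggers a split becomes the new reference, and the registration just
computed against the old reference is kept as the group's `H_RR` — so
`H_RR` is always a direct registration, never a composition.

`H_RB(g) = H_RB(g-1) %*% H_RR(g)` with `H_RB(1) = I`; the base frame's
`H_CB` is exactly the identity. The canvas is the axis-aligned bounding box
of all `H_CB`-warped frame corners, computed after the whole chain is known
(two passes over the shot, no canvas reallocation).

Blending is *pixel filling*: within the new frame's footprint, only canvas
pixels never written before receive values, so every mosaic pixel comes from
exactly one frame, re-blending is a no-op, and a per-pixel provenance map
records which frame supplied each pixel. Warping is inverse (canvas to
frame) with bilinear sampling.

Meta-mosaicking registers each mini-mosaic to its predecessor with the same
adaptive ladder and chains sequentially. If the best registration between
two adjacent mini-mosaics stays below the inlier-ratio threshold, the pair
is declared unmergeable — between whole mosaics, a sub-threshold "best
guess" is evidence of missing scene overlap — and both mosaics are emitted
individually. A graph-based global refinement could replace this sequential
rule behind the same interface.

## Shot detection

The boundary statistic is the cumulative-histogram difference: per channel,
64-bin normalized intensity histograms of consecutive frames are
accumulated into CDFs and the L1 distance between CDFs is summed over bins
and channels. The statistic is zero for identical frames, maximal for
black-versus-white, and insensitive to the spatial arrangement of pixels —
which is exactly what makes it respond to scene changes rather than to
smooth motion.

Deciding which energies are boundaries is done in two stages:

1. An exact 1-D two-means split of the energies. If the between-cluster
   separation is at most 4 low-cluster standard deviations, the sequence is
   declared boundary-free. The factor is 4 rather than the tempting 2
   because splitting *any* unimodal sample in two yields a separation of
   about 2.65 low-cluster standard deviations (the half-normal split), so a
   factor of 2 would hallucinate boundaries in every boundary-free video.
2. Each candidate boundary must be an isolated discontinuity: its energy
   must exceed 5x the median energy of its 11-pair temporal neighbourhood
   and lie 10 median absolute deviations above the sequence median. Smooth
   within-shot energy bursts (fast panning over high-contrast parts of the
   field) elevate their whole neighbourhood and fail the first test; the
   weaker of two unequal genuine jumps can land in the low two-means
   cluster, which is why cluster membership itself is not trusted for the
   final call. On 135 synthetic flights (15 seeds x 3 trajectory kinds x
   0/1/2 injected jumps) this rule finds every injected boundary within one
   frame and flags nothing else.

All thresholds are scale-invariant (multiplying every energy by a positive
constant changes nothing). Shots shorter than 5 frames are merged into
their neighbour, since a mini-mosaic needs several frames to be useful.

## Quality metrics

SSIM follows the classic windowed formulation: 11x11 Gaussian window
(sigma 1.5), stabilization constants `(0.01 L)^2` and `(0.03 L)^2` with
`L = 1`, population (weighted) covariances, mean over all fully valid
windows; color images are converted to Rec. 601 luminance first. This exact
variant was chosen so the implementation can be checked against the
reference implementation in scikit-image to single-float precision (the
suite freezes one such oracle value).

* `SSIM_f(t)` compares the warped frame `t` with the mosaic as it stood
  after frame 1, over the region where both are filled.
* `SSIM_p(t)` compares the warped frame `t` with the mosaic accumulated
  from frames 1..t-1, before frame `t` is blended.
* Scene integrity is the fraction of frames whose footprint region in the
  finished mosaic reaches at least 0.5 SSIM against the warped frame. The
  0.5 threshold is configurable and always reported next to the score; the
  metric is designed to saturate at 1 for any sane reconstruction and fall
  towards 0 when the chain is destroyed, and both endpoints are exercised
  in the tests.

Restricting windowed SSIM to a region uses only windows fully inside the
region (falling back to 95%-covered windows when the region is thinner than
a window); a frame with empty overlap is skipped and flagged rather than
scored.

## The synthetic-flight simulator

Real flight videos are large, external, and truthless; the simulator is the
package's instrument for end-to-end validation with known ground truth. It
emulates, by construction:

* a planar field texture with the row/alley checkerboard (cosine bands with
  48 px row period and 64 px alley period by default), seeded plant-scale
  speckle (Gaussian noise blurred at sigma 1.5) so features exist but
  repeat, patch-scale variation (sigma 7) emulating soil-moisture/vigor
  patches, a smooth random illumination field (about +/-5%), and a
  deterministic illumination ramp (about +/-20% across the field, the
  sun-angle/vignetting surrogate). The ramp is what gives distant regions
  of the field distinct intensity statistics, so abrupt viewpoint jumps are
  visible to histogram-based shot detection no matter where they land; the
  patch-scale component is what makes SSIM keep degrading smoothly out to
  tens of pixels of misalignment instead of saturating at the plant scale.
* smooth camera trajectories (out-and-back, two-pass serpentine, orbit, and
  a serpentine-orbit composite) expressed as per-frame frame-to-scene
  similarity transforms, with per-frame jitter (0.5 px, 0.2 degrees by
  default). Step lengths are solved from the requested consecutive-footprint
  overlap (default IoU 0.9) with a safety margin, and a constructive check
  shortens any step that jitter pushed below target, so the overlap
  contract holds pair by pair, not just on average.
* abrupt viewpoint jumps at requested shot breaks: the remaining path is
  rigidly displaced by 1.25x(frame width + height) — enough to guarantee
  zero footprint overlap for any direction — and rotated by 25 degrees, so
  smoothness *within* the new shot is preserved exactly.
* per-frame ground-truth homographies, footprint polygons, consecutive-pair
  IoU, the true orthomosaic, and optional sensor noise and linear
  illumination drift, all deterministic given one seed.

What the simulator does *not* model: non-planar terrain, rolling shutter,
plant motion between frames, perspective foreshortening from oblique poses
(trajectories are similarity transforms), motion blur, and compression
artifacts. Passing the suite therefore demonstrates that the algorithmic
machinery is correct and accurate under the planar model, not that the
pipeline is robust to every field condition.

## Numerical choices and degenerate inputs

* Bilinear interpolation everywhere, constant (black) fill outside sources;
  integer-translation renders are bit-exact, which the tests exploit.
* DLT is Hartley-normalized; RANSAC rejects minimal samples with any three
  collinear points and keeps iterating; a fully collinear correspondence
  set raises a classed registration-failure error.
* Downsampling is exact area averaging (sparse operator per axis), which
  preserves constants and mean intensity; upsampling is refused.
* Undistortion applies the Brown-Conrady radial-tangential model by direct
  sampling; the simulation of distortion (for tests) inverts the model by
  fixed-point iteration. With all coefficients zero both are exact
  identities. The default pipeline order is undistort-then-downsample,
  because distortion coefficients are defined for native sensor geometry;
  the order is configurable.
* A single-frame shot returns the frame itself as its mini-mosaic; a
  single mini-mosaic passes through meta-mosaicking bit-identically.
* Seeds: every stochastic step (RANSAC, simulator jitter, noise) takes a
  seed and restores the caller's RNG state; per-pair RANSAC seeds are
  derived from the policy seed and the frame indices.

## Validation problem sizes

The test-suite and the acceptance script exercise the pipeline at desk
scale: 160x120 px frames for accuracy runs (100 frames for chain recovery,
200 for the drift comparison), 120x90 px for shot-detection sweeps (60
frames, 10+ seeds) and quality-degradation curves (10 frames, 20 seeds,
error magnitudes 0-20 px). These sizes were chosen so the full validation
runs in minutes on one CPU while every decision rule (group size 40,
one-third displacement, 40% inlier escalation, 5000-keypoint cap) is
exercised at its exact boundary. Accuracy at larger frame sizes improves if
anything, since more features enter each registration.

## Known limitations

* The planar-scene assumption is structural: crowned or sloping fields
  produce the characteristic trapezoidal distortions 2-D mosaicking cannot
  remove.
* Sequential meta-mosaicking accumulates error across many shots; a global
  (graph/bundle) refinement is the natural replacement behind the same
  interface.
* The rotation-invariant rung handles in-plane rotation, not strong
  out-of-plane tilt.
* Pixel filling preserves provenance and sharpness but makes no attempt at
  seam smoothing or gain compensation; exposure steps between frames remain
  visible at footprint boundaries.
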