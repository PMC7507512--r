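# fieldmosaic

Mosaicking of aerial crop-field video by grouped homography chaining.

`fieldmosaic` turns a freely flown drone video of an (approximately planar)
crop field into a single 2-D mosaic, using only the imagery — no GPS,
vehicle telemetry, or ground control points. It is aimed at plant
phenotyping and crop-scouting workflows where the field is a repetitive
row/alley lattice: thousands of near-identical plants that starve feature
matchers of unique landmarks and make chained registration drift.

## Method

Every frame *i* is related to the mosaic by a 3×3 planar homography. The
pipeline controls drift by keeping the chain of estimated transforms short:

1. **Shot detection.** Consecutive-frame *cumulative-histogram difference*
   energies are clustered (exact 1-D two-means plus robust outlier tests);
   isolated high-energy pairs mark abrupt viewpoint changes, splitting the
   video into scene-consistent *shots*.
2. **Adaptive registration.** Within a shot, frames are registered by a
   descriptor ladder — structure-tensor micro-block corners (`st`), dense
   patch corners (`fast_local`), orientation-normalized patches
   (`affine_robust`) — keeping the strongest 5000 keypoints, matching with
   a 0.75 ratio test, filtering with seeded RANSAC (DLT, 2 px symmetric
   transfer error), and escalating to the next rung whenever the inlier
   ratio falls below 40%. Accepted homographies are photometrically
   refined (Gauss–Newton on the intensity residual).
3. **Grouped chaining.** Frames form groups of at most 40 sharing a
   reference frame; a frame whose center moves more than ⅓ of the frame
   width/height starts a new group. With H<sub>CR</sub> (current→reference),
   H<sub>RR</sub> (reference→previous reference) and
   H<sub>RB</sub>(g) = H<sub>RB</sub>(g−1)·H<sub>RR</sub>(g), every frame
   reaches the shot's base frame through
   H<sub>CB</sub> = H<sub>RB</sub>·H<sub>CR</sub> — a chain whose length is
   the number of groups, not frames.
4. **Canvas + pixel filling.** The canvas is the bounding box of all warped
   frame corners; blending writes each canvas pixel at most once, so every
   pixel has exactly one provenance frame. Per-shot mini-mosaics are merged
   into a meta-mosaic by the same machinery.
5. **Quality.** SSIM<sub>f</sub> (warped frame vs the initial mosaic),
   SSIM<sub>p</sub> (vs the mosaic up to t−1), and *scene integrity* (the
   fraction of frames recognizably placed in the final mosaic, 0–1).

A synthetic-flight simulator — periodic row/alley texture, seeded speckle,
illumination structure, smooth trajectories with per-frame ground-truth
homographies and injectable viewpoint jumps — provides the ground truth the
whole pipeline is validated against. See the methods vignette
(`vignettes/mosaicking-methods.Rmd`) for models, parameter rationale, and
limitations.

## Worked example

```r
library(fieldmosaic)

spec <- trajectory_spec("out_and_back", n_frames = 40,
                        frame_size = c(160, 120), overlap_target = 0.9)
flight <- simulate_flight(spec, seed = 1)
flight$scene
#> <fm_scene: 640 x 480 px, row period 48, alley period 64>

shots <- detect_shots(sequence_energies(flight$frames), n_frames = 40)
shots
#>   shot start end base
#> 1    1     1  40    1

mosaic <- build_mini_mosaic(flight$frames, mosaic_config())
mosaic$canvas
#> <fm_canvas: 285 x 128 px, 40 frame(s), 97.0% filled>

quality <- mosaic_quality(flight$frames, mosaic$chain)
quality
#> <fm_quality: 40 frames, mean SSIM_f 0.9987, mean SSIM_p 0.9988, scene integrity 1.000>
```

The 40-frame smooth flight forms one shot; the mosaic canvas (285×128 px)
covers the swept strip of the field; SSIM values near 1 say each incoming
frame agrees with the mosaic built so far almost perfectly, and scene
integrity 1.0 says every frame is correctly placed. On a real video you
would start from a frame directory instead:

```r
cfg <- pipeline_config("frames/", "out/", camera = "camera.yaml",
                       target_width = 1920)
run_pipeline(cfg)
```

which writes per-shot mosaics, the meta-mosaic, homography chains,
footprints, the shots manifest, the registration log (the
features → strongest-K → matches → inliers funnel per frame), and the
quality report under `out/`. A command-line front end with `mosaic`,
`simulate` and `evaluate` subcommands is installed at
`inst/cli/fieldmosaic.R`.

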