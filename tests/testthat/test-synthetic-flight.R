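test_that("field texture is deterministic and validates its arguments", {
  t1 <- make_field_texture(200, 150, seed = 9)
  t2 <- make_field_texture(200, 150, seed = 9)
  expect_identical(t1$texture, t2$texture)
  t3 <- make_field_texture(200, 150, seed = 10)
  expect_false(identical(t1$texture, t3$texture))
  expect_error(make_field_texture(-5, 100), class = "fm_invalid_argument")
  expect_error(make_field_texture(100, 100, row_period = 0),
               class = "fm_invalid_argument")
})

test_that("deterministic texture is periodic with the row period", {
  tex <- make_field_texture(256, 256, row_period = 32, alley_period = 32,
                            seed = 1, speckle = 0, illum_scale = 0,
                            ramp_scale = 0)$texture
  # exact periodicity along both axes
  expect_equal(tex[1:224, , ], tex[33:256, , ], tolerance = 1e-12)
  expect_equal(tex[, 1:224, ], tex[, 33:256, ], tolerance = 1e-12)
  # autocorrelation of a column peaks at the row period
  col <- tex[, 8, 2]
  ac <- sapply(1:48, function(l) {
    stats::cor(col[1:(256 - l)], col[(1 + l):256])
  })
  expect_equal(which.max(ac), 32)
})

test_that("row-band count follows floor(height / row_period)", {
  tex <- make_field_texture(4000, 3000, row_period = 60, seed = 1,
                            speckle = 0, illum_scale = 0,
                            ramp_scale = 0)$texture
  col <- tex[, 10, 2]  # green channel carries the row signal
  n <- length(col)
  peaks <- sum(col[2:(n - 1)] > col[1:(n - 2)] &
               col[2:(n - 1)] >= col[3:n])
  # interior maxima plus the band starting at the first row
  expect_equal(peaks + 1L, floor(3000 / 60))
  rm(tex); gc(verbose = FALSE)
})

test_that("single-frame trajectory is a pure axis-aligned placement", {
  scene <- make_field_texture(640, 480, seed = 2)
  spec <- trajectory_spec("out_and_back", n_frames = 1,
                          frame_size = c(160, 120), jitter = c(0, 0))
  gt <- make_trajectory(spec, scene, seed = 1)
  H <- gt$homographies[[1]]
  expect_equal(H[1:2, 1:2], diag(2), tolerance = 1e-12)
  fp <- gt$footprints[[1]]
  expect_equal(fp[1, 2], fp[2, 2], tolerance = 1e-9)  # axis-aligned
  expect_equal(fp[2, 1], fp[3, 1], tolerance = 1e-9)
})

test_that("overlap contract holds and matches an independent IoU oracle", {
  for (kind in c("out_and_back", "serpentine", "orbit", "composite")) {
    fl <- test_flight(25, kind = kind, seed = 4)
    expect_true(all(fl$truth$pair_iou >= 0.9 - 1e-9), label = kind)
    # generator-reported IoU agrees with the rasterized oracle
    for (i in c(1, 12, 24)) {
      expect_lt(abs(fl$truth$pair_iou[i] -
                    raster_iou(fl$truth$footprints[[i]],
                               fl$truth$footprints[[i + 1]])), 0.02)
    }
  }
})

test_that("shot breaks force footprint overlap below 0.1 exactly once", {
  fl <- test_flight(40, seed = 6, shot_breaks = 20L)
  low <- which(fl$truth$pair_iou < 0.1)
  expect_identical(low, 20L)
  expect_true(all(fl$truth$pair_iou[-20] >= 0.9 - 1e-9))
})

test_that("trajectory specs validate their invariants", {
  expect_error(trajectory_spec("orbit", 0), class = "fm_invalid_argument")
  expect_error(trajectory_spec("orbit", 10, overlap_target = 0),
               class = "fm_invalid_argument")
  expect_error(trajectory_spec("orbit", 10, shot_breaks = c(5L, 5L)),
               class = "fm_invalid_argument")
  expect_error(trajectory_spec("orbit", 10, shot_breaks = 10L),
               class = "fm_invalid_argument")
  # infeasible: trajectory cannot fit a tiny texture
  scene <- make_field_texture(200, 150, seed = 1)
  spec <- trajectory_spec("out_and_back", 200, frame_size = c(160, 120))
  expect_error(make_trajectory(spec, scene), class = "fm_config_error")
})

test_that("rendering reproduces exact crops for identity-like homographies", {
  scene <- make_field_texture(400, 300, seed = 5)
  spec <- trajectory_spec("out_and_back", n_frames = 1,
                          frame_size = c(100, 80), jitter = c(0, 0))
  gt <- make_trajectory(spec, scene, seed = 1)
  gt$homographies[[1]] <- homography_translation(50, 40)
  gt$footprints[[1]] <- footprint_polygon(gt$homographies[[1]], 100, 80)
  fr <- render_frames(scene, gt)[[1]]
  expect_identical(fr$image, scene$texture[41:120, 51:150, ])
  # identity placement
  gt$homographies[[1]] <- diag(3)
  gt$footprints[[1]] <- footprint_polygon(diag(3), 100, 80)
  fr0 <- render_frames(scene, gt)[[1]]
  expect_identical(fr0$image, scene$texture[1:80, 1:100, ])
})

test_that("rotate/unrotate round trip loses less than 2 intensity levels", {
  scene <- make_field_texture(500, 400, seed = 7)
  spec <- trajectory_spec("out_and_back", n_frames = 1,
                          frame_size = c(160, 120), jitter = c(0, 0))
  gt <- make_trajectory(spec, scene, seed = 1)
  fc <- c(79.5, 59.5)
  Hrot <- gt$homographies[[1]] %*%
    homography_similarity(30 * pi / 180, 1, 0, 0, center = fc)
  gt$homographies[[1]] <- normalize_homography(Hrot)
  gt$footprints[[1]] <- footprint_polygon(Hrot, 160, 120)
  rot <- render_frames(scene, gt)[[1]]
  # unrotate: treat the rotated frame as a scene, sample through the inverse
  scene2 <- scene
  scene2$texture <- rot$image
  spec2 <- trajectory_spec("out_and_back", n_frames = 1,
                           frame_size = c(80, 60), jitter = c(0, 0))
  gt2 <- make_trajectory(spec2, scene2, seed = 1)
  Hback <- homography_similarity(-30 * pi / 180, 1, 0, 0, center = fc) %*%
    homography_translation(40, 30)
  gt2$homographies[[1]] <- normalize_homography(Hback)
  gt2$footprints[[1]] <- footprint_polygon(Hback, 80, 60)
  back <- render_frames(scene2, gt2)[[1]]
  direct <- render_frames(scene, local({
    g <- gt
    g$homographies[[1]] <- normalize_homography(
      gt$homographies[[1]] %*% Hback)
    g$footprints[[1]] <- footprint_polygon(g$homographies[[1]], 80, 60)
    g$spec$frame_size <- c(80, 60)
    g
  }))[[1]]
  rmse <- sqrt(mean((back$image - direct$image)^2))
  expect_lt(rmse * 255, 2)
})

test_that("frames, noise and illumination drift are seed-deterministic", {
  fl1 <- test_flight(6, seed = 8, noise_sd = 0.02, illum_drift = 0.1)
  fl2 <- test_flight(6, seed = 8, noise_sd = 0.02, illum_drift = 0.1)
  for (i in 1:6) expect_identical(fl1$frames[[i]]$image,
                                  fl2$frames[[i]]$image)
  expect_equal(fl1$frames[[6]]$meta$illum, 1.05)
  expect_equal(fl1$frames[[1]]$meta$illum, 0.95)
})

test_that("footprints leaving the texture raise an out-of-bounds error", {
  scene <- make_field_texture(400, 300, seed = 1)
  spec <- trajectory_spec("out_and_back", n_frames = 2,
                          frame_size = c(100, 80), jitter = c(0, 0))
  gt <- make_trajectory(spec, scene, seed = 1)
  gt$homographies[[2]] <- homography_translation(380, 0)
  gt$footprints[[2]] <- footprint_polygon(gt$homographies[[2]], 100, 80)
  expect_error(render_frames(scene, gt), class = "fm_out_of_bounds",
               regexp = "frame 2")
})

test_that("dataset writer emits frames, ground truth and orthomosaic", {
  fl <- test_flight(5, seed = 2)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(fl, dir)
  expect_length(list.files(dir, pattern = "^frame_.*png$"), 5L)
  expect_true(file.exists(file.path(dir, "orthomosaic.png")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$n_frames, 5L)
  expect_equal(nrow(gt$homographies), 5L)  # row-major, one row per frame
  H1 <- matrix(gt$homographies[1, ], 3, 3, byrow = TRUE)
  expect_equal(H1, fl$truth$homographies[[1]], tolerance = 1e-12)
})
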