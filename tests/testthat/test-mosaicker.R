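# planted registration: every frame translated by (dx, dy) per step relative
# to the current reference
planted_translation <- function(dx, dy = 0) {
  function(i, ref) list(H = homography_translation((i - ref) * dx,
                                                   (i - ref) * dy),
                        inlier_ratio = 1)
}

test_that("the 41st member of a group starts a new group", {
  groups <- assign_groups(1:45, c(160, 120), planted_translation(0.5),
                          max_group_size = 40)
  expect_length(groups, 2L)
  expect_identical(groups[[1]]$members, 1:40)
  expect_identical(groups[[2]]$reference, 41L)
  expect_identical(groups[[2]]$members, 41:45)
  # the split registration is reused as H_RR (direct registration)
  expect_equal(groups[[2]]$h_rr$H, homography_translation(40 * 0.5, 0))
})

test_that("one-third frame displacement splits, smaller does not", {
  H <- 120
  # displacement jumps straight to f * frame height at frame 4
  disp_fn <- function(f) function(i, ref) {
    d <- if (i - ref >= 3) f * H else 1
    list(H = homography_translation(0, d), inlier_ratio = 1)
  }
  g_split <- assign_groups(1:6, c(160, H), disp_fn(0.34))
  expect_length(g_split, 2L)
  expect_identical(g_split[[2]]$reference, 4L)
  g_keep <- assign_groups(1:6, c(160, H), disp_fn(0.30))
  expect_length(g_keep, 1L)
  # the same fractions trigger on width for x displacements
  disp_x <- function(f) function(i, ref) {
    d <- if (i - ref >= 3) f * 160 else 1
    list(H = homography_translation(d, 0), inlier_ratio = 1)
  }
  expect_length(assign_groups(1:6, c(160, H), disp_x(0.34)), 2L)
  expect_length(assign_groups(1:6, c(160, H), disp_x(0.30)), 1L)
})

test_that("zero motion keeps all frames in a single group", {
  groups <- assign_groups(1:10, c(160, 120),
                          function(i, ref) list(H = diag(3),
                                                inlier_ratio = 1))
  expect_length(groups, 1L)
  expect_identical(groups[[1]]$members, 1:10)
})

test_that("chained homographies equal brute-force matrix products", {
  set.seed(21)
  for (rep in 1:10) {
    ng <- sample(1:5, 1)
    sizes <- sample(1:40, ng, replace = TRUE)
    h_rr <- c(list(NULL), replicate(max(ng - 1, 0), random_homography(),
                                    simplify = FALSE))
    h_cr <- lapply(sizes, function(s) {
      c(list(diag(3)),
        replicate(s - 1, random_homography(), simplify = FALSE))
    })
    idx <- 0
    groups <- list()
    for (g in seq_len(ng)) {
      members <- idx + seq_len(sizes[g])
      idx <- idx + sizes[g]
      groups[[g]] <- list(index = g, reference = members[1],
                          members = members, h_cr = h_cr[[g]],
                          h_rr = if (g == 1) NULL else list(H = h_rr[[g]]),
                          regs = vector("list", sizes[g]))
    }
    chain <- chain_homographies(groups, c(160, 120))
    oracle <- brute_force_chain(h_rr, h_cr)
    for (i in seq_along(oracle)) {
      expect_lt(max(abs(chain$h_cb[[i]] - oracle[[i]])) /
                  max(abs(oracle[[i]])), 1e-10)
    }
  }
})

test_that("identity inputs chain to identities and the base stays fixed", {
  groups <- assign_groups(1:8, c(100, 80),
                          function(i, ref) list(H = diag(3),
                                                inlier_ratio = 1))
  chain <- chain_homographies(groups, c(100, 80))
  for (H in chain$h_cb) expect_equal(H, diag(3))
  expect_equal(chain$h_cb[[1]], diag(3))
})

test_that("two translated groups compose as in the transformation model", {
  groups <- list(
    list(index = 1, reference = 1, members = 1:2,
         h_cr = list(diag(3), homography_translation(3, 0)),
         h_rr = NULL, regs = vector("list", 2)),
    list(index = 2, reference = 3, members = 3:4,
         h_cr = list(diag(3), homography_translation(3, 0)),
         h_rr = list(H = homography_translation(10, 0)),
         regs = vector("list", 2))
  )
  chain <- chain_homographies(groups, c(100, 80))
  expect_equal(chain$h_cb[[4]], homography_translation(13, 0))
  expect_equal(chain$h_cb[[3]], homography_translation(10, 0))
  # missing H_RR breaks the chain with a named gap
  groups[[2]]$h_rr <- NULL
  expect_error(chain_homographies(groups, c(100, 80)),
               class = "fm_chain_break", regexp = "group 2")
})

test_that("canvas estimation covers warped corners with no negative indices", {
  mk_chain <- function(h_cb, w = 100, h = 80) {
    structure(list(frames = seq_along(h_cb),
                   group_of = rep(1L, length(h_cb)),
                   h_cr = h_cb, h_cb = h_cb, h_rr = list(NULL),
                   h_rb = list(diag(3)), frame_size = c(w, h)),
              class = "fm_chain")
  }
  s1 <- estimate_canvas(mk_chain(list(diag(3))))
  expect_equal(c(s1$width, s1$height), c(100L, 80L))
  expect_equal(s1$offset, c(0, 0))
  s2 <- estimate_canvas(mk_chain(list(diag(3),
                                      homography_translation(100, 0))))
  expect_equal(s2$width, 200L)
  s3 <- estimate_canvas(mk_chain(list(diag(3),
                                      homography_translation(-50, -50))))
  expect_equal(s3$offset, c(50, 50))
  expect_equal(c(s3$width, s3$height), c(150L, 130L))
  bad <- mk_chain(list(matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3)))
  expect_error(estimate_canvas(bad), class = "fm_degenerate_transform")
})

test_that("pixel filling writes unfilled pixels once and is idempotent", {
  fl <- test_flight(3, seed = 14, jitter = c(0, 0))
  f1 <- fl$frames[[1]]; f2 <- fl$frames[[2]]
  H12 <- normalize_homography(solve(fl$truth$homographies[[1]]) %*%
                              fl$truth$homographies[[2]])
  spec <- list(width = 200L, height = 120L, offset = c(10, 10))
  cv <- new_canvas(spec)
  cv <- warp_and_blend(cv, f1, diag(3), frame_index = 1L)
  expect_identical(sort(unique(as.vector(cv$provenance))), c(0L, 1L))
  expect_equal(sum(cv$provenance == 1L), 120L * 90L)
  # the first frame lands exactly on its pixels
  expect_equal(cv$image[11:100, 11:130, ], f1$image, tolerance = 1e-12)
  # re-blending the same frame is a no-op
  cv2 <- warp_and_blend(cv, f1, diag(3), frame_index = 9L)
  expect_identical(cv2$image, cv$image)
  expect_identical(cv2$provenance, cv$provenance)
  # a second overlapping frame only fills fresh pixels
  cv3 <- warp_and_blend(cv, f2, H12, frame_index = 2L)
  overlap <- cv$provenance == 1L
  expect_identical(cv3$provenance[overlap], cv$provenance[overlap])
  expect_gt(sum(cv3$provenance == 2L), 0)
  expect_identical(cv3$image[overlap], cv$image[overlap])
  # filled-pixel count never decreases
  expect_gte(sum(cv3$provenance > 0), sum(cv$provenance > 0))
})

test_that("blending order decides provenance symmetrically", {
  fl <- test_flight(2, seed = 15, jitter = c(0, 0))
  H12 <- normalize_homography(solve(fl$truth$homographies[[1]]) %*%
                              fl$truth$homographies[[2]])
  spec <- list(width = 220L, height = 140L, offset = c(20, 20))
  ab <- warp_and_blend(new_canvas(spec), fl$frames[[1]], diag(3), 1L)
  ab <- warp_and_blend(ab, fl$frames[[2]], H12, 2L)
  ba <- warp_and_blend(new_canvas(spec), fl$frames[[2]], H12, 2L)
  ba <- warp_and_blend(ba, fl$frames[[1]], diag(3), 1L)
  both <- ab$provenance > 0 & ba$provenance > 0
  overlap <- both & ab$provenance != ba$provenance
  # in the contested region each order keeps its first-blended frame
  expect_true(all(ab$provenance[overlap] == 1L))
  expect_true(all(ba$provenance[overlap] == 2L))
  # the filled region itself is order-independent
  expect_identical(ab$provenance > 0, ba$provenance > 0)
})

test_that("footprints outside the canvas raise an overflow error", {
  spec <- list(width = 50L, height = 50L, offset = c(0, 0))
  cv <- new_canvas(spec)
  img <- array(0.3, c(40, 40, 3))
  expect_error(warp_and_blend(cv, img, homography_translation(30, 0), 1L),
               class = "fm_canvas_overflow")
})

test_that("a single-frame shot returns the frame as its mini-mosaic", {
  fl <- test_flight(2, seed = 16)
  mos <- build_mini_mosaic(fl$frames[1], mosaic_config())
  expect_equal(dim(mos$canvas$image), dim(fl$frames[[1]]$image))
  expect_equal(mos$canvas$image, fl$frames[[1]]$image, tolerance = 1e-12)
  expect_equal(mos$chain$h_cb[[1]], diag(3))
})

test_that("mini-mosaics reconstruct a noiseless flight against ground truth", {
  fl <- test_flight(30, seed = 17, frame_size = c(160, 120),
                    jitter = c(0, 0))
  mos <- build_mini_mosaic(fl$frames, mosaic_config())
  tchain <- ground_truth_chain(fl$truth)
  errs <- vapply(seq_along(mos$chain$h_cb), function(i) {
    max_corner_err(mos$chain$h_cb[[i]], tchain$h_cb[[i]], 160, 120)
  }, numeric(1))
  expect_lt(max(errs), 2)
  proj <- project_scene_to_canvas(fl$scene, fl$truth, mos$canvas)
  m <- (mos$canvas$provenance > 0) & proj$mask
  expect_gt(fieldmosaic:::ssim_masked(mos$canvas$image, proj$image, m),
            0.95)
  # registration funnel log is emitted for every non-reference frame
  expect_equal(nrow(mos$log), 29L)
  expect_true(all(c("n_features", "n_matches", "n_inliers",
                    "inlier_ratio") %in% names(mos$log)))
})

test_that("footprint stacking in canvas coordinates matches ground truth", {
  fl <- test_flight(15, seed = 18, frame_size = c(160, 120),
                    jitter = c(0, 0))
  mos <- build_mini_mosaic(fl$frames, mosaic_config())
  fps <- lapply(mos$canvas$footprints, `[[`, "corners")
  for (i in seq_len(14)) {
    iou_rec <- polygon_iou(fps[[i]], fps[[i + 1]])
    expect_lt(abs(iou_rec - fl$truth$pair_iou[i]), 0.05)
  }
})

test_that("a single mini-mosaic passes through meta-mosaicking unchanged", {
  fl <- test_flight(6, seed = 19)
  mos <- build_mini_mosaic(fl$frames, mosaic_config())
  meta <- meta_mosaic(list(mos))
  expect_identical(meta$canvas$image, mos$canvas$image)
})

test_that("overlapping shots merge; disjoint shots raise unmergeable", {
  fl <- test_flight(50, seed = 20, frame_size = c(120, 90),
                    jitter = c(0, 0))
  m1 <- build_mini_mosaic(fl$frames[1:28], mosaic_config())
  m2 <- build_mini_mosaic(fl$frames[22:50], mosaic_config())
  meta <- meta_mosaic(list(m1, m2), register_policy())
  expect_false(any(meta$log$low_confidence))
  # the merged canvas must cover at least 95% of the union of the true
  # frame footprints (trajectories are rigid translations here, so scene
  # areas transfer to canvas pixel counts unchanged)
  fps <- fl$truth$footprints[c(1:28, 22:50)]
  all_pts <- do.call(rbind, fps)
  xs <- seq(floor(min(all_pts[, 1])), ceiling(max(all_pts[, 1])), by = 1)
  ys <- seq(floor(min(all_pts[, 2])), ceiling(max(all_pts[, 2])), by = 1)
  px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
  covered <- rep(FALSE, length(px))
  for (fp in fps) {
    xr <- range(fp[, 1]); yr <- range(fp[, 2])
    covered <- covered | (px >= xr[1] & px <= xr[2] &
                          py >= yr[1] & py <= yr[2])
  }
  union_area <- sum(covered)
  expect_gt(sum(meta$canvas$provenance > 0), 0.95 * union_area)
  # disjoint halves of the field cannot merge
  sep <- test_flight(60, seed = 21, frame_size = c(120, 90),
                     shot_breaks = 30L)
  d1 <- build_mini_mosaic(sep$frames[1:30], mosaic_config())
  d2 <- build_mini_mosaic(sep$frames[31:60], mosaic_config())
  err <- tryCatch(meta_mosaic(list(d1, d2), register_policy()),
                  fm_unmergeable_shots = function(e) e)
  expect_s3_class(err, "fm_unmergeable_shots")
  expect_length(err$mosaics, 2L)
})

test_that("grouped chains drift less than naive frame-to-frame chains", {
  fl <- test_flight(60, seed = 22, frame_size = c(160, 120),
                    jitter = c(0, 0))
  mos <- build_mini_mosaic(fl$frames, mosaic_config())
  naive <- frame_to_frame_chain(fl$frames)
  tchain <- ground_truth_chain(fl$truth)
  n <- length(fl$frames)
  g_err <- max_corner_err(mos$chain$h_cb[[n]], tchain$h_cb[[n]], 160, 120)
  n_err <- max_corner_err(naive$h_cb[[n]], tchain$h_cb[[n]], 160, 120)
  expect_lt(g_err, n_err)
})
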