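test_that("strongest-K selection is exact and deterministic", {
  # a large noisy frame yields well over 5000 corner candidates
  set.seed(42)
  big <- matrix(runif(360 * 480), 360, 480)
  f1 <- detect_features(big, "fast_local", max_keep = 5000)
  expect_identical(nrow(f1$pts), 5000L)
  f2 <- detect_features(big, "fast_local", max_keep = 5000)
  expect_identical(f1$pts, f2$pts)
  expect_identical(f1$desc, f2$desc)
  # strengths are sorted non-increasing and the cut is at the 5000 strongest
  expect_true(all(diff(f1$strength) <= 1e-12))
  fall <- detect_features(big, "fast_local", max_keep = 100000)
  expect_gt(nrow(fall$pts), 5000)
  expect_equal(f1$strength, fall$strength[1:5000])
})

test_that("fewer detections than max_keep returns them all", {
  fl <- test_flight(2, seed = 2)
  f <- detect_features(fl$frames[[1]], "st", max_keep = 5000)
  expect_lt(nrow(f$pts), 5000)
  f2 <- detect_features(fl$frames[[1]], "st", max_keep = 100000)
  expect_identical(nrow(f$pts), nrow(f2$pts))
})

test_that("constant frames raise a low-texture error", {
  flat <- array(0.5, c(120, 160, 3))
  expect_error(detect_features(flat, "st"), class = "fm_low_texture")
  expect_error(detect_features(flat, "fast_local"),
               class = "fm_low_texture")
  expect_error(detect_features(matrix(0.2, 100, 100), "st", max_keep = 2),
               class = "fm_invalid_argument")
})

test_that("a feature set matched against itself is the identity matching", {
  fl <- test_flight(2, seed = 3)
  f <- detect_features(fl$frames[[1]], "st")
  m <- match_features(f, f)
  expect_identical(nrow(m$src_pts), nrow(f$pts))
  expect_equal(m$src_pts, m$dst_pts)
  expect_true(all(m$score < 1e-3))
})

test_that("matches across a known translation displace by that translation", {
  scene <- make_field_texture(500, 380, seed = 6)
  spec <- trajectory_spec("out_and_back", n_frames = 2,
                          frame_size = c(160, 120), jitter = c(0, 0))
  gt <- make_trajectory(spec, scene, seed = 1)
  H1 <- gt$homographies[[1]]
  gt$homographies[[2]] <- normalize_homography(
    H1 %*% homography_translation(7, 3))
  gt$footprints[[2]] <- footprint_polygon(gt$homographies[[2]], 160, 120)
  fr <- render_frames(scene, gt)
  fa <- detect_features(fr[[2]], "st")
  fb <- detect_features(fr[[1]], "st")
  m <- match_features(fa, fb)
  expect_gt(nrow(m$src_pts), 30)
  d <- m$dst_pts - m$src_pts
  good <- abs(d[, 1] - 7) <= 1 & abs(d[, 2] - 3) <= 1
  expect_gt(mean(good), 0.9)
})

test_that("descriptor kinds cannot be cross-matched", {
  fl <- test_flight(2, seed = 3)
  fa <- detect_features(fl$frames[[1]], "st")
  fb <- detect_features(fl$frames[[2]], "fast_local")
  expect_error(match_features(fa, fb), class = "fm_invalid_argument")
})

test_that("RANSAC recovers an exact 4-point homography", {
  H <- homography_similarity(0.2, 1.1, 15, -5)
  src <- matrix(c(10, 10, 90, 15, 85, 70, 5, 75), 4, 2, byrow = TRUE)
  m <- manual_matches(src, apply_homography(H, src))
  r <- ransac_filter(m, reproj_tol = 2, seed = 1)
  expect_lt(max_corner_err(r$homography$H, normalize_homography(H),
                           100, 100), 1e-6)
  expect_equal(r$matches$inlier_ratio, 1)
})

test_that("RANSAC separates a planted model from uniform outliers", {
  set.seed(9)
  H <- homography_similarity(-0.15, 0.95, 30, 12)
  src <- cbind(runif(100, 0, 200), runif(100, 0, 150))
  dst <- apply_homography(H, src)
  out_idx <- 81:100
  dst[out_idx, ] <- cbind(runif(20, 0, 200), runif(20, 0, 150))
  m <- manual_matches(src, dst)
  r <- ransac_filter(m, reproj_tol = 2, seed = 4)
  expect_true(all(r$matches$inlier_mask[1:80]))
  expect_lt(max_corner_err(r$homography$H, normalize_homography(H),
                           200, 150), 0.5)
  # seeded determinism
  r2 <- ransac_filter(m, reproj_tol = 2, seed = 4)
  expect_identical(r$matches$inlier_mask, r2$matches$inlier_mask)
  expect_identical(r$homography$H, r2$homography$H)
})

test_that("collinear samples are rejected without derailing the estimate", {
  set.seed(10)
  H <- homography_translation(5, 9)
  line <- cbind(seq(0, 100, length.out = 50), seq(0, 50, length.out = 50))
  good <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  src <- rbind(line, good)
  dst <- apply_homography(H, src)
  r <- ransac_filter(manual_matches(src, dst), reproj_tol = 2, seed = 2)
  expect_lt(max_corner_err(r$homography$H, H, 100, 100), 1e-6)
  # a fully collinear correspondence set cannot produce a model
  m_bad <- manual_matches(line[1:10, ], line[1:10, ] + 3)
  expect_error(ransac_filter(m_bad, seed = 1),
               class = "fm_registration_failure")
  expect_error(ransac_filter(manual_matches(line[1:3, ], line[1:3, ])),
               class = "fm_degenerate_input")
})

test_that("self-registration returns the identity transform", {
  fl <- test_flight(2, seed = 5)
  reg <- adaptive_register(fl$frames[[1]], fl$frames[[1]])
  expect_lt(max_corner_err(reg$H, diag(3), 120, 90), 1e-6)
  expect_false(reg$low_confidence)
})

test_that("forward and backward registrations invert each other", {
  fl <- test_flight(3, seed = 6, jitter = c(0, 0))
  ab <- adaptive_register(fl$frames[[2]], fl$frames[[1]])
  ba <- adaptive_register(fl$frames[[1]], fl$frames[[2]])
  expect_lt(max_corner_err(ab$H %*% ba$H, diag(3), 120, 90), 0.5)
})

test_that("the descriptor ladder escalates exactly at the 40% rule", {
  planted <- function(ratios) {
    function(frame, reference, kind, policy) {
      list(H = diag(3), inlier_ratio = ratios[[kind]], n_features = 100,
           n_matches = 50, n_inliers = round(50 * ratios[[kind]]),
           rms = 0.5, descriptor = kind)
    }
  }
  fl <- test_flight(2, seed = 1)
  pol <- register_policy()
  # 0.39 on the first rung escalates; 0.40 and 0.41 are accepted
  r39 <- adaptive_register(fl$frames[[1]], fl$frames[[2]], pol,
    register_fn = planted(list(st = 0.39, fast_local = 0.9,
                               affine_robust = 0.9)))
  expect_identical(r39$descriptor, "fast_local")
  r40 <- adaptive_register(fl$frames[[1]], fl$frames[[2]], pol,
    register_fn = planted(list(st = 0.40, fast_local = 0.9,
                               affine_robust = 0.9)))
  expect_identical(r40$descriptor, "st")
  r41 <- adaptive_register(fl$frames[[1]], fl$frames[[2]], pol,
    register_fn = planted(list(st = 0.41, fast_local = 0.9,
                               affine_robust = 0.9)))
  expect_identical(r41$descriptor, "st")
  # all rungs below threshold: best returned, flagged
  rlow <- adaptive_register(fl$frames[[1]], fl$frames[[2]], pol,
    register_fn = planted(list(st = 0.1, fast_local = 0.25,
                               affine_robust = 0.2)))
  expect_true(rlow$low_confidence)
  expect_identical(rlow$descriptor, "fast_local")
})

test_that("in-plane rotation defeats upright rungs but not the robust rung", {
  scene <- make_field_texture(800, 600, seed = 4)
  spec <- trajectory_spec("out_and_back", n_frames = 2,
                          frame_size = c(160, 120), jitter = c(0, 0))
  gt <- make_trajectory(spec, scene, seed = 1)
  fc <- c(79.5, 59.5)
  H2 <- gt$homographies[[1]] %*%
    homography_similarity(45 * pi / 180, 1, 5, 3, center = fc)
  gt$homographies[[2]] <- normalize_homography(H2)
  gt$footprints[[2]] <- footprint_polygon(H2, 160, 120)
  fr <- render_frames(scene, gt)
  reg <- adaptive_register(fr[[2]], fr[[1]])
  expect_identical(reg$descriptor, "affine_robust")
  expect_false(reg$low_confidence)
  Htrue <- solve(gt$homographies[[1]]) %*% gt$homographies[[2]]
  expect_lt(max_corner_err(reg$H, Htrue, 160, 120), 1)
})

test_that("pairwise registration tracks ground truth on a noiseless flight", {
  fl <- test_flight(8, seed = 7, frame_size = c(160, 120), jitter = c(0, 0))
  for (i in 2:8) {
    reg <- adaptive_register(fl$frames[[i]], fl$frames[[i - 1]])
    Ht <- solve(fl$truth$homographies[[i - 1]]) %*%
      fl$truth$homographies[[i]]
    expect_lt(max_corner_err(reg$H, normalize_homography(Ht), 160, 120), 1)
  }
})
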