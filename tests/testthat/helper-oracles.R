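# Independent oracles and small fixture builders used across the suite.

# Rasterized polygon IoU: even-odd point-in-polygon test on a dense grid.
# Deliberately independent of the package's polygon-clipping code.
raster_iou <- function(a, b, step = 0.25) {
  lim <- function(p) c(floor(min(p)) - 1, ceiling(max(p)) + 1)
  xr <- range(c(lim(a[, 1]), lim(b[, 1])))
  yr <- range(c(lim(a[, 2]), lim(b[, 2])))
  xs <- seq(xr[1], xr[2], by = step)
  ys <- seq(yr[1], yr[2], by = step)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  inside <- function(poly) {
    n <- nrow(poly)
    inp <- rep(FALSE, length(px))
    j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]
      xj <- poly[j, 1]; yj <- poly[j, 2]
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inp <- xor(inp, crosses)
      j <- i
    }
    inp
  }
  ia <- inside(a); ib <- inside(b)
  u <- sum(ia | ib)
  if (u == 0) return(0)
  sum(ia & ib) / u
}

# Brute-force homography chaining directly from the recursive definitions,
# multiplying matrices frame by frame without reusing the package's chain
# bookkeeping.
brute_force_chain <- function(h_rr_list, h_cr_by_group) {
  ng <- length(h_cr_by_group)
  out <- list()
  for (g in seq_len(ng)) {
    # compose H_RB(g) = H_RR(2) ... H_RR(g) applied left to right from base
    H_rb <- diag(3)
    if (g > 1) {
      for (gg in 2:g) H_rb <- H_rb %*% h_rr_list[[gg]]
    }
    for (k in seq_along(h_cr_by_group[[g]])) {
      H <- H_rb %*% h_cr_by_group[[g]][[k]]
      out[[length(out) + 1]] <- H / H[3, 3]
    }
  }
  out
}

random_homography <- function() {
  H <- fieldmosaic::homography_similarity(
    theta = stats::runif(1, -0.3, 0.3),
    scale = stats::runif(1, 0.9, 1.1),
    tx = stats::runif(1, -40, 40), ty = stats::runif(1, -40, 40))
  # mild projective component
  H[3, 1:2] <- stats::runif(2, -1e-4, 1e-4)
  H / H[3, 3]
}

# Small synthetic flight shared by several tests.
test_flight <- function(n_frames = 12, kind = "out_and_back", seed = 3,
                        frame_size = c(120, 90), shot_breaks = integer(0),
                        jitter = c(0.5, 0.2), ...) {
  spec <- trajectory_spec(kind, n_frames = n_frames,
                          frame_size = frame_size, overlap_target = 0.9,
                          jitter = jitter, shot_breaks = shot_breaks)
  simulate_flight(spec, seed = seed, ...)
}

# Build an fm_matches object directly from point correspondences.
manual_matches <- function(src, dst, kind = "st") {
  structure(list(
    src_frame = 1L, dst_frame = 2L, kind = kind,
    src_pts = src, dst_pts = dst,
    score = rep(0, nrow(src)),
    inlier_mask = rep(NA, nrow(src)), inlier_ratio = NA_real_
  ), class = "fm_matches")
}

max_corner_err <- function(H_est, H_true, w, h) {
  fieldmosaic:::corner_error(H_est, H_true, w, h)
}
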