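# Synthetic-flight simulator: a planar crop-field texture, a smooth camera
# trajectory expressed as per-frame frame->scene homographies, rendered
# frames, and the true orthomosaic. Provides the ground truth against which
# the registration and mosaicking stages are validated.

#' Generate a planar crop-field texture
#'
#' Emulates the visual structure of a research nursery: parallel crop rows
#' crossed at right angles by alleys, forming a repetitive checkerboard that
#' deliberately stresses feature matching, plus seeded per-plant speckle so
#' that local features exist but repeat, and an optional low-frequency
#' illumination field that gives different regions of the field different
#' color statistics.
#'
#' @param width,height Texture dimensions in pixels.
#' @param row_period Pixels between successive crop rows (bands along y).
#' @param alley_period Pixels between successive alleys (bands along x).
#' @param seed Integer seed; the texture is deterministic given the seed.
#' @param speckle Amplitude of the stochastic texture components (0
#'   disables).
#' @param speckle_sigma Gaussian blur (pixels) of the fine, plant-scale
#'   speckle: the detail feature detectors lock onto.
#' @param patch_sigma Gaussian blur (pixels) of a coarser patch-scale
#'   variation (soil moisture / vigor patches); gives the field appearance
#'   structure between the plant scale and the row/alley scale.
#' @param illum_scale Amplitude of the low-frequency multiplicative
#'   illumination field (0 disables; 0.15 means roughly +/-15%).
#' @param ramp_scale Amplitude of a deterministic illumination ramp across
#'   the field (emulating sun angle / vignetting at field scale); gives
#'   distant regions distinct intensity statistics, which is what makes
#'   abrupt viewpoint jumps visible to histogram-based shot detection.
#' @return An object of class `fm_scene` with fields `texture` (H x W x 3
#'   array in [0, 1]), `row_period`, `alley_period`, `rng_seed`.
#' @export
make_field_texture <- function(width, height, row_period = 48,
                               alley_period = 64, seed = 1L,
                               speckle = 0.5, speckle_sigma = 1.5,
                               patch_sigma = 7, illum_scale = 0.05,
                               ramp_scale = 0.2) {
  if (width <= 0 || height <= 0 || row_period <= 0 || alley_period <= 0) {
    fm_stop("fm_invalid_argument",
            "texture dimensions and periods must be positive")
  }
  x <- 0:(width - 1L); y <- 0:(height - 1L)
  rowness <- 0.5 + 0.5 * cos(2 * pi * y / row_period)    # 1 on a crop row
  cropness <- 1 - 0.8 * (0.5 + 0.5 * cos(2 * pi * x / alley_period))
  density <- outer(rowness, cropness)                    # plant cover in [0,1]
  soil <- c(0.45, 0.36, 0.26)
  plant <- c(0.16, 0.55, 0.20)
  tex <- array(0, c(height, width, 3L))
  for (ch in 1:3) {
    tex[, , ch] <- soil[ch] + (plant[ch] - soil[ch]) * density
  }
  if (ramp_scale > 0 && height > 1L) {
    ramp <- 1 + ramp_scale * (2 * y / (height - 1) - 1)
    for (ch in 1:3) tex[, , ch] <- tex[, , ch] * ramp
  }
  with_seed(seed, {
    if (speckle > 0) {
      n <- matrix(stats::rnorm(height * width), height, width)
      n <- gaussian_smooth(n, speckle_sigma)
      n <- n / max(stats::sd(n), 1e-12)
      m <- matrix(stats::rnorm(height * width), height, width)
      m <- gaussian_smooth(m, patch_sigma)
      m <- m / max(stats::sd(m), 1e-12)
      wch <- c(0.6, 1.0, 0.6)
      for (ch in 1:3) {
        tex[, , ch] <- tex[, , ch] + 0.12 * speckle * wch[ch] * n +
          0.24 * speckle * m
      }
    }
    if (illum_scale > 0) {
      spacing <- 128
      gh <- max(2L, ceiling(height / spacing) + 1L)
      gw <- max(2L, ceiling(width / spacing) + 1L)
      g <- matrix(stats::rnorm(gh * gw), gh, gw)
      gx <- (x / (width - 1)) * (gw - 1)
      gy <- (y / (height - 1)) * (gh - 1)
      pts <- cbind(rep(gx, each = height), rep(gy, width))
      f <- matrix(sample_bilinear(g, pts[, 1L], pts[, 2L]), height, width)
      f <- 1 + illum_scale * pmax(pmin(f, 2), -2) / 2
      for (ch in 1:3) tex[, , ch] <- tex[, , ch] * f
    }
  })
  structure(list(
    texture = clamp01(tex),
    row_period = row_period,
    alley_period = alley_period,
    rng_seed = as.integer(seed)
  ), class = "fm_scene")
}

#' @export
print.fm_scene <- function(x, ...) {
  d <- dim(x$texture)
  cat(sprintf("<fm_scene: %d x %d px, row period %g, alley period %g>\n",
              d[2L], d[1L], x$row_period, x$alley_period))
  invisible(x)
}

#' Specify a synthetic camera trajectory
#'
#' @param kind One of `"serpentine"`, `"orbit"`, `"out_and_back"`,
#'   `"composite"` (out-and-back pass connected to an orbit).
#' @param n_frames Number of frames.
#' @param frame_size Frame `(width, height)` in pixels.
#' @param overlap_target Minimum footprint intersection-over-union between
#'   consecutive frames, in (0, 1].
#' @param jitter Length-2 vector `(pixels, degrees)`: standard deviation of
#'   the per-frame position and in-plane rotation perturbations.
#' @param shot_breaks Integer frame indices `b` at which an abrupt viewpoint
#'   jump is injected between frames `b` and `b + 1`; strictly increasing,
#'   each within `(1, n_frames)`.
#' @return An object of class `fm_trajectory_spec`.
#' @export
trajectory_spec <- function(kind = c("out_and_back", "serpentine", "orbit",
                                     "composite"),
                            n_frames, frame_size = c(160L, 120L),
                            overlap_target = 0.9, jitter = c(0.5, 0.2),
                            shot_breaks = integer(0)) {
  kind <- match.arg(kind)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) fm_stop("fm_invalid_argument", "n_frames must be >= 1")
  if (!(overlap_target > 0 && overlap_target <= 1)) {
    fm_stop("fm_invalid_argument", "overlap_target must be in (0, 1]")
  }
  shot_breaks <- as.integer(shot_breaks)
  if (length(shot_breaks)) {
    if (any(diff(shot_breaks) <= 0L) || any(shot_breaks <= 1L) ||
        any(shot_breaks >= n_frames)) {
      fm_stop("fm_invalid_argument",
              "shot_breaks must be strictly increasing within (1, n_frames)")
    }
  }
  structure(list(
    kind = kind, n_frames = n_frames,
    frame_size = as.numeric(frame_size),
    overlap_target = overlap_target,
    jitter = as.numeric(jitter),
    shot_breaks = shot_breaks
  ), class = "fm_trajectory_spec")
}

# Per-axis step length giving a translation-only footprint IoU of `o` for an
# axis of length L: IoU = (L - d)/(L + d).
axis_step <- function(L, o) L * (1 - o) / (1 + o)

# Conservative step length for steps of arbitrary direction: shrink both axes
# by the full step and require the intersection area to stay above the IoU
# threshold.
diag_step <- function(W, H, o) {
  a_min <- 2 * W * H * o / (1 + o)
  p <- W + H
  q <- W * H - a_min
  (p - sqrt(p^2 - 4 * q)) / 2
}

# Build the camera-center path and per-frame headings for a spec, in
# trajectory coordinates (placement into the scene happens later). Returns
# list(centers = n x 2, thetas = n). Deterministic given the RNG state.
build_path <- function(spec) {
  n <- spec$n_frames
  W <- spec$frame_size[1L]; H <- spec$frame_size[2L]
  # aim above the requested overlap so that the per-frame jitter does not
  # drag pairs below target
  o <- spec$overlap_target + 0.25 * (1 - spec$overlap_target)
  dx <- axis_step(W, o); dy <- axis_step(H, o); dd <- diag_step(W, H, o)
  centers <- matrix(0, n, 2L)
  if (n > 1L) {
    step_list <- switch(spec$kind,
      out_and_back = {
        n_out <- ceiling((n - 1L) / 2)
        c_steps <- list()
        for (i in seq_len(n_out)) c_steps[[length(c_steps) + 1L]] <- c(dx, 0)
        if (n - 1L > n_out) c_steps[[length(c_steps) + 1L]] <- c(0, dy)
        while (length(c_steps) < n - 1L) {
          c_steps[[length(c_steps) + 1L]] <- c(-dx, 0)
        }
        c_steps
      },
      serpentine = {
        k_conn <- max(1L, ceiling((H / 3) / dy))
        n_pass <- max(1L, (n - 1L - k_conn) %/% 2L)
        c_steps <- list()
        for (i in seq_len(n_pass)) c_steps[[length(c_steps) + 1L]] <- c(dx, 0)
        for (i in seq_len(k_conn)) c_steps[[length(c_steps) + 1L]] <- c(0, dy)
        while (length(c_steps) < n - 1L) {
          c_steps[[length(c_steps) + 1L]] <- c(-dx, 0)
        }
        c_steps
      },
      orbit = {
        r <- dd / (2 * sin(pi / n))
        phi <- 2 * pi * (0:(n - 1L)) / n
        pts <- cbind(r * cos(phi), r * sin(phi))
        lapply(seq_len(n - 1L), function(i) pts[i + 1L, ] - pts[i, ])
      },
      composite = {
        n_leg <- max(2L, floor(0.55 * n))
        n_orb <- n - n_leg
        c_steps <- list()
        for (i in seq_len(n_leg - 1L)) {
          c_steps[[length(c_steps) + 1L]] <- c(dx, 0)
        }
        if (n_orb > 0L) {
          n_circ <- max(n_orb + 1L, 8L)
          r <- dd / (2 * sin(pi / n_circ))
          phi <- 2 * pi * (0:n_orb) / n_circ
          pts <- cbind(r * cos(phi), r * sin(phi))
          for (i in seq_len(n_orb)) {
            c_steps[[length(c_steps) + 1L]] <- pts[i + 1L, ] - pts[i, ]
          }
        }
        c_steps
      }
    )
    for (i in seq_len(n - 1L)) {
      centers[i + 1L, ] <- centers[i, ] + step_list[[i]]
    }
  }
  thetas <- rep(0, n)
  if (any(spec$jitter > 0) && n > 1L) {
    centers <- centers + cbind(stats::rnorm(n, 0, spec$jitter[1L]),
                               stats::rnorm(n, 0, spec$jitter[1L]))
    thetas <- thetas + stats::rnorm(n, 0, spec$jitter[2L] * pi / 180)
  }
  # abrupt viewpoint jumps: rigidly displace and rotate the remaining path so
  # that within-shot smoothness and overlap are preserved after the jump
  jump_mag <- 1.25 * (W + H)
  jump_rot <- 25 * pi / 180
  sgn <- 1
  for (b in spec$shot_breaks) {
    offset <- c(0, sgn * jump_mag)
    th <- sgn * jump_rot
    Rm <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L, byrow = TRUE)
    tail_idx <- (b + 1L):n
    anchor <- centers[b + 1L, ]
    rel <- sweep(centers[tail_idx, , drop = FALSE], 2L, anchor)
    centers[tail_idx, ] <- sweep(rel %*% t(Rm), 2L, anchor + offset, "+")
    thetas[tail_idx] <- thetas[tail_idx] + th
    sgn <- -sgn
  }
  list(centers = centers, thetas = thetas)
}

#' Generate ground-truth homographies for a trajectory
#'
#' Places the camera path inside the scene texture and emits, for every
#' frame, the true frame-to-scene homography (a similarity transform:
#' translation plus in-plane rotation), the footprint polygon, and the
#' footprint IoU of every consecutive pair. Consecutive footprints overlap by
#' at least `overlap_target` except across `shot_breaks`, where a jump is
#' injected that forces the overlap below 0.1.
#'
#' @param spec An [trajectory_spec()] object.
#' @param scene An [make_field_texture()] scene.
#' @param seed Integer seed controlling the trajectory jitter.
#' @return An object of class `fm_ground_truth`: `homographies` (list of
#'   3x3 matrices, `H[3,3] == 1`), `footprints` (list of 4 x 2 corner
#'   matrices in scene coordinates), `centers`, `thetas`, `pair_iou`,
#'   `shot_breaks`, `spec`.
#' @export
make_trajectory <- function(spec, scene, seed = 1L) {
  stopifnot(inherits(spec, "fm_trajectory_spec"), inherits(scene, "fm_scene"))
  path <- with_seed(seed, build_path(spec))
  W <- spec$frame_size[1L]; H <- spec$frame_size[2L]
  tex_h <- nrow(scene$texture); tex_w <- ncol(scene$texture)
  margin <- sqrt(W^2 + H^2) / 2 + 2
  ctr <- path$centers
  mid <- c(mean(range(ctr[, 1L])), mean(range(ctr[, 2L])))
  shift <- c((tex_w - 1) / 2, (tex_h - 1) / 2) - mid
  ctr <- sweep(ctr, 2L, shift, "+")
  if (any(ctr[, 1L] < margin) || any(ctr[, 1L] > tex_w - 1 - margin) ||
      any(ctr[, 2L] < margin) || any(ctr[, 2L] > tex_h - 1 - margin)) {
    fm_stop("fm_config_error",
            paste0("trajectory does not fit inside the %d x %d texture with ",
                   "the requested overlap; enlarge the texture or reduce ",
                   "n_frames"), tex_w, tex_h)
  }
  fc <- c((W - 1) / 2, (H - 1) / 2)
  # enforce the overlap contract: when jitter drags a consecutive pair below
  # the target IoU, shorten that step (translating the whole remaining path
  # so later pairs keep their relative geometry)
  fp_of <- function(center, theta) {
    footprint_polygon(homography_similarity(theta, 1,
                                            tx = center[1L] - fc[1L],
                                            ty = center[2L] - fc[2L],
                                            center = fc), W, H)
  }
  n <- spec$n_frames
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (i %in% spec$shot_breaks) next
      iou_i <- function(t) {
        p <- ctr[i, ] + t * (ctr[i + 1L, ] - ctr[i, ])
        polygon_iou(fp_of(ctr[i, ], path$thetas[i]),
                    fp_of(p, path$thetas[i + 1L]))
      }
      if (iou_i(1) >= spec$overlap_target) next
      lo <- 0; hi <- 1
      for (b in 1:25) {
        mid <- (lo + hi) / 2
        if (iou_i(mid) >= spec$overlap_target) lo <- mid else hi <- mid
      }
      delta <- (lo - 1) * (ctr[i + 1L, ] - ctr[i, ])
      ctr[(i + 1L):n, ] <- sweep(ctr[(i + 1L):n, , drop = FALSE], 2L,
                                 delta, "+")
    }
  }
  hs <- vector("list", spec$n_frames)
  fps <- vector("list", spec$n_frames)
  for (i in seq_len(spec$n_frames)) {
    Hm <- homography_similarity(path$thetas[i], 1,
                                tx = ctr[i, 1L] - fc[1L],
                                ty = ctr[i, 2L] - fc[2L], center = fc)
    hs[[i]] <- normalize_homography(Hm)
    fps[[i]] <- footprint_polygon(hs[[i]], W, H)
  }
  iou <- if (spec$n_frames > 1L) {
    vapply(seq_len(spec$n_frames - 1L), function(i) {
      polygon_iou(fps[[i]], fps[[i + 1L]])
    }, numeric(1))
  } else numeric(0)
  structure(list(
    homographies = hs, footprints = fps,
    centers = ctr, thetas = path$thetas,
    pair_iou = iou, shot_breaks = spec$shot_breaks, spec = spec
  ), class = "fm_ground_truth")
}

#' @export
print.fm_ground_truth <- function(x, ...) {
  cat(sprintf("<fm_ground_truth: %d frames, kind '%s', %d shot break(s)>\n",
              length(x$homographies), x$spec$kind, length(x$shot_breaks)))
  invisible(x)
}

#' Render frames from a scene and ground-truth trajectory
#'
#' Frame `i` is the texture sampled through the true homography with bilinear
#' interpolation, optionally followed by a multiplicative illumination drift
#' and additive Gaussian sensor noise (both recorded in the frame metadata).
#'
#' @param scene An `fm_scene`.
#' @param ground_truth An `fm_ground_truth`.
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   units on [0, 1]; 0 disables).
#' @param illum_drift Total fractional illumination change across the
#'   sequence (linear ramp centered on 1; 0 disables).
#' @param seed Seed for the sensor noise.
#' @return List of [new_frame()] objects.
#' @export
render_frames <- function(scene, ground_truth, noise_sd = 0, illum_drift = 0,
                          seed = 1L) {
  stopifnot(inherits(scene, "fm_scene"),
            inherits(ground_truth, "fm_ground_truth"))
  tex <- scene$texture
  tex_h <- nrow(tex); tex_w <- ncol(tex)
  spec <- ground_truth$spec
  W <- spec$frame_size[1L]; H <- spec$frame_size[2L]
  xs <- rep(0:(W - 1L), each = H)
  ys <- rep(0:(H - 1L), W)
  n <- length(ground_truth$homographies)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      fp <- ground_truth$footprints[[i]]
      if (any(fp[, 1L] < 0) || any(fp[, 1L] > tex_w - 1) ||
          any(fp[, 2L] < 0) || any(fp[, 2L] > tex_h - 1)) {
        fm_stop("fm_out_of_bounds",
                "footprint of frame %d exits the scene texture", i)
      }
      p <- apply_homography(ground_truth$homographies[[i]], cbind(xs, ys))
      sam <- sample_bilinear(tex, p[, 1L], p[, 2L])
      img <- array(sam, c(H, W, 3L))
      illum <- 1
      if (illum_drift != 0 && n > 1L) {
        illum <- 1 + illum_drift * ((i - 1) / (n - 1) - 0.5)
        img <- img * illum
      }
      if (noise_sd > 0) {
        img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
      }
      if (illum_drift != 0 || noise_sd > 0) img <- clamp01(img)
      new_frame(img, i, meta = list(illum = illum, noise_sd = noise_sd))
    })
  })
}

#' True orthomosaic of a flight
#'
#' Crops the scene texture to the bounding box of all ground-truth
#' footprints: the ideal mosaic the pipeline should reconstruct.
#'
#' @inheritParams render_frames
#' @return List with `image` and `origin` (scene coordinates `(x, y)` of the
#'   crop's pixel (1,1)).
#' @export
true_orthomosaic <- function(scene, ground_truth) {
  all_pts <- do.call(rbind, ground_truth$footprints)
  x0 <- max(0L, floor(min(all_pts[, 1L])))
  x1 <- min(ncol(scene$texture) - 1L, ceiling(max(all_pts[, 1L])))
  y0 <- max(0L, floor(min(all_pts[, 2L])))
  y1 <- min(nrow(scene$texture) - 1L, ceiling(max(all_pts[, 2L])))
  list(image = scene$texture[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), ,
                             drop = FALSE],
       origin = c(x0, y0))
}

#' Simulate a complete synthetic flight
#'
#' Convenience wrapper: builds a field texture sized to contain the
#' trajectory (at least 4x the frame dimensions), generates the ground-truth
#' homographies, and renders the frames.
#'
#' @param spec An [trajectory_spec()].
#' @param seed Master seed (texture, jitter and sensor noise are derived
#'   from it).
#' @param noise_sd,illum_drift Passed to [render_frames()].
#' @param texture_args Extra arguments for [make_field_texture()].
#' @return List with `scene`, `truth`, `frames`, `spec`.
#' @export
simulate_flight <- function(spec, seed = 1L, noise_sd = 0, illum_drift = 0,
                            texture_args = list()) {
  path <- with_seed(seed, build_path(spec))
  W <- spec$frame_size[1L]; H <- spec$frame_size[2L]
  margin <- sqrt(W^2 + H^2) / 2 + 8
  ex <- diff(range(path$centers[, 1L]))
  ey <- diff(range(path$centers[, 2L]))
  tex_w <- max(4 * W, ceiling(ex + 2 * margin))
  tex_h <- max(4 * H, ceiling(ey + 2 * margin))
  args <- c(list(width = tex_w, height = tex_h, seed = seed), texture_args)
  scene <- do.call(make_field_texture, args)
  truth <- make_trajectory(spec, scene, seed = seed)
  frames <- render_frames(scene, truth, noise_sd = noise_sd,
                          illum_drift = illum_drift, seed = seed + 1L)
  list(scene = scene, truth = truth, frames = frames, spec = spec)
}

#' Write a synthetic dataset to disk
#'
#' Writes numbered PNG frames, the true orthomosaic PNG, and a ground-truth
#' JSON manifest (per-frame 3x3 homography row-major, footprint corners,
#' consecutive-pair IoU, shot-break indices).
#'
#' @param flight Result of [simulate_flight()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(flight, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- flight$frames
  for (f in frames) {
    write_image(f$image, file.path(dir, sprintf("frame_%04d.png", f$index)))
  }
  ortho <- true_orthomosaic(flight$scene, flight$truth)
  write_image(ortho$image, file.path(dir, "orthomosaic.png"))
  gt <- flight$truth
  manifest <- list(
    n_frames = length(frames),
    frame_size = gt$spec$frame_size,
    kind = gt$spec$kind,
    overlap_target = gt$spec$overlap_target,
    shot_breaks = gt$shot_breaks,
    orthomosaic_origin = ortho$origin,
    pair_iou = gt$pair_iou,
    homographies = lapply(gt$homographies, function(H) as.vector(t(H))),
    footprints = lapply(gt$footprints, function(fp) as.vector(t(fp)))
  )
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Project the true scene into mosaic-canvas coordinates
#'
#' Samples the scene texture through the base frame's true homography so the
#' ideal (ground-truth) mosaic is expressed on the same canvas as a
#' reconstructed one, for pixel-level comparison.
#'
#' @param scene An `fm_scene`.
#' @param ground_truth The `fm_ground_truth` whose first frame is the base.
#' @param canvas An `fm_canvas` (or a geometry list from
#'   [estimate_canvas()]).
#' @return List with `image` (canvas-sized) and `mask` (pixels that fall
#'   inside the texture).
#' @export
project_scene_to_canvas <- function(scene, ground_truth, canvas) {
  off <- canvas$offset
  Hc <- if (inherits(canvas, "fm_canvas")) nrow(canvas$provenance) else
    canvas$height
  Wc <- if (inherits(canvas, "fm_canvas")) ncol(canvas$provenance) else
    canvas$width
  H1 <- ground_truth$homographies[[1L]]
  xs <- rep(0:(Wc - 1L), each = Hc) - off[1L]
  ys <- rep(0:(Hc - 1L), Wc) - off[2L]
  p <- apply_homography(H1, cbind(xs, ys))
  tex <- scene$texture
  inside <- p[, 1L] >= 0 & p[, 1L] <= ncol(tex) - 1 &
    p[, 2L] >= 0 & p[, 2L] <= nrow(tex) - 1
  sam <- sample_bilinear(tex, p[, 1L], p[, 2L])
  list(image = array(sam, c(Hc, Wc, 3L)),
       mask = matrix(inside, Hc, Wc))
}
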