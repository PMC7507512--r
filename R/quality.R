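# Mosaic quality metrics. SSIM follows the classic windowed formulation:
# 11 x 11 Gaussian weights (sigma 1.5), stabilization constants
# C1 = (0.01 L)^2, C2 = (0.03 L)^2 with dynamic range L = 1, population
# (weighted) covariances, and the mean taken over all fully valid windows.
# Color images are converted to grayscale luminance first.
#
# SSIM_f compares the warped frame at time t with the mosaic as it stood
# after the first frame; SSIM_p compares it with the mosaic accumulated from
# frames 1..t-1; scene integrity is the fraction of frames whose footprint
# region in the final mosaic is structurally similar to the warped frame.

ssim_components <- function(a, b, sigma = 1.5, data_range = 1) {
  k <- gaussian_kernel1d(sigma)
  win <- length(k)
  if (min(dim(a)) < win) {
    r <- max(1L, (min(dim(a)) - 1L) %/% 2L)
    k <- gaussian_kernel1d(sigma, radius = r)
    win <- length(k)
  }
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  ux <- conv_valid_sep(a, k)
  uy <- conv_valid_sep(b, k)
  uxx <- conv_valid_sep(a * a, k)
  uyy <- conv_valid_sep(b * b, k)
  uxy <- conv_valid_sep(a * b, k)
  vx <- uxx - ux^2
  vy <- uyy - uy^2
  vxy <- uxy - ux * uy
  map <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  list(map = map, kernel = k)
}

#' Structural similarity index of two images
#'
#' @param image_a,image_b Images of identical dimensions (color images are
#'   converted to grayscale internally).
#' @param sigma Gaussian window standard deviation.
#' @param data_range Dynamic range of the data (1 for [0, 1] images).
#' @return Mean SSIM in [-1, 1].
#' @export
ssim <- function(image_a, image_b, sigma = 1.5, data_range = 1) {
  a <- rgb_to_gray(image_a); b <- rgb_to_gray(image_b)
  if (!identical(dim(a), dim(b))) {
    fm_stop("fm_invalid_argument", "images have mismatched dimensions")
  }
  mean(ssim_components(a, b, sigma, data_range)$map)
}

# SSIM restricted to a pixel mask: only windows fully inside the mask
# contribute; if no window is fully inside, windows with >= 95% coverage are
# used; if none qualify, NA is returned.
ssim_masked <- function(image_a, image_b, mask, sigma = 1.5, data_range = 1) {
  a <- rgb_to_gray(image_a); b <- rgb_to_gray(image_b)
  if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(mask))) {
    fm_stop("fm_invalid_argument", "images/mask have mismatched dimensions")
  }
  if (!any(mask)) return(NA_real_)
  # crop to the mask bounding box to keep the filtering cheap
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  a <- a[rows[1L]:rows[2L], cols[1L]:cols[2L], drop = FALSE]
  b <- b[rows[1L]:rows[2L], cols[1L]:cols[2L], drop = FALSE]
  m <- mask[rows[1L]:rows[2L], cols[1L]:cols[2L], drop = FALSE]
  a[!m] <- 0; b[!m] <- 0
  if (min(dim(a)) < 3L) return(NA_real_)
  cmp <- ssim_components(a, b, sigma, data_range)
  cov <- conv_valid_sep(m + 0, cmp$kernel)
  full <- cov > 1 - 1e-9
  if (!any(full)) full <- cov >= 0.95
  if (!any(full)) return(NA_real_)
  mean(cmp$map[full])
}

#' Warp a frame into canvas space
#'
#' @param frame An `fm_frame` or image array.
#' @param H_CB Current-to-base homography.
#' @param canvas_spec Canvas geometry from [estimate_canvas()].
#' @return List with `image` (canvas-sized) and `mask` (logical matrix of
#'   pixels covered by the warped frame).
#' @export
warp_frame_to_canvas <- function(frame, H_CB, canvas_spec) {
  img <- as_frame_image(frame)
  tmp <- new_canvas(canvas_spec,
                    channels = if (length(dim(img)) == 3L) 3L else 1L)
  tmp <- warp_and_blend(tmp, frame, H_CB, frame_index = 1L)
  list(image = tmp$image, mask = tmp$provenance > 0L)
}

#' SSIM of a warped frame against the initial mosaic (SSIM_f)
#'
#' Restricted to the region where both the warped frame and the mosaic
#' computed at t = 1 are filled; `NA` (with a message attribute) when the
#' overlap is empty.
#'
#' @param warped List with `image` and `mask` ([warp_frame_to_canvas()]).
#' @param mosaic_t1 List with `image` and `mask`: the mosaic after frame 1.
#' @export
ssim_f <- function(warped, mosaic_t1) {
  ssim_masked(warped$image, mosaic_t1$image, warped$mask & mosaic_t1$mask)
}

#' SSIM of a warped frame against the incremental mosaic (SSIM_p)
#'
#' As [ssim_f()] but against the mosaic accumulated from frames 1..t-1,
#' before frame t is blended.
#'
#' @param warped List with `image` and `mask`.
#' @param mosaic_prev List with `image` and `mask`: mosaic state before
#'   frame t.
#' @export
ssim_p <- function(warped, mosaic_prev) {
  ssim_masked(warped$image, mosaic_prev$image, warped$mask & mosaic_prev$mask)
}

#' Full quality report for a chain
#'
#' Replays pixel-fill blending along the chain and records, for every frame,
#' SSIM_f (against the mosaic at t = 1) and SSIM_p (against the mosaic up to
#' t - 1), then computes scene integrity on the finished mosaic: the
#' fraction of frames whose footprint region in the mosaic reaches at least
#' `match_threshold` SSIM against the warped frame.
#'
#' @param frames List of `fm_frame` objects.
#' @param chain An `fm_chain` whose `h_cb` entries correspond to `frames`
#'   in order.
#' @param match_threshold SSIM threshold defining a "matched" frame for
#'   scene integrity.
#' @return An object of class `fm_quality`: `trace` (data frame with
#'   `frame`, `ssim_f`, `ssim_p`, `match_ssim`), `mean_ssim_f`,
#'   `mean_ssim_p`, `scene_integrity`, `match_threshold`, `canvas`.
#' @export
mosaic_quality <- function(frames, chain, match_threshold = 0.5) {
  n <- length(frames)
  stopifnot(length(chain$h_cb) == n)
  spec <- estimate_canvas(chain)
  channels <- if (length(dim(frames[[1L]]$image)) == 3L) 3L else 1L
  canvas <- new_canvas(spec, channels)
  warped <- lapply(seq_len(n), function(t) {
    warp_frame_to_canvas(frames[[t]], chain$h_cb[[t]], spec)
  })
  sf <- sp <- rep(NA_real_, n)
  mosaic1 <- NULL
  for (t in seq_len(n)) {
    if (t > 1L) {
      state <- list(image = canvas$image, mask = canvas$provenance > 0L)
      sf[t] <- ssim_f(warped[[t]], mosaic1)
      sp[t] <- ssim_p(warped[[t]], state)
    }
    canvas <- warp_and_blend(canvas, frames[[t]], chain$h_cb[[t]],
                             frame_index = frames[[t]]$index)
    if (t == 1L) {
      mosaic1 <- list(image = canvas$image, mask = canvas$provenance > 0L)
      sf[1L] <- ssim_f(warped[[1L]], mosaic1)
    }
  }
  match_ssim <- vapply(seq_len(n), function(t) {
    ssim_masked(canvas$image, warped[[t]]$image, warped[[t]]$mask)
  }, numeric(1))
  matched <- !is.na(match_ssim) & match_ssim > match_threshold
  structure(list(
    trace = data.frame(frame = vapply(frames, function(f) f$index,
                                      integer(1)),
                       ssim_f = sf, ssim_p = sp, match_ssim = match_ssim),
    mean_ssim_f = mean(sf, na.rm = TRUE),
    mean_ssim_p = if (all(is.na(sp))) NA_real_ else mean(sp, na.rm = TRUE),
    scene_integrity = mean(matched),
    match_threshold = match_threshold,
    canvas = canvas
  ), class = "fm_quality")
}

#' @export
print.fm_quality <- function(x, ...) {
  cat(sprintf(
    "<fm_quality: %d frames, mean SSIM_f %.4f, mean SSIM_p %.4f, scene integrity %.3f>\n",
    nrow(x$trace), x$mean_ssim_f, x$mean_ssim_p, x$scene_integrity))
  invisible(x)
}

#' Scene integrity of a finished mosaic
#'
#' The ratio of input frames that "match" the mosaic: a frame matches when
#' the SSIM between its warped image and the mosaic over its footprint
#' exceeds `match_threshold`. Ranges from 0 (complete failure) to 1
#' (complete success).
#'
#' @param canvas The finished `fm_canvas`.
#' @param frames List of `fm_frame` objects.
#' @param chain An `fm_chain` aligned with `frames`.
#' @param match_threshold SSIM threshold for a match.
#' @export
scene_integrity <- function(canvas, frames, chain, match_threshold = 0.5) {
  spec <- list(width = ncol(canvas$provenance),
               height = nrow(canvas$provenance), offset = canvas$offset)
  vals <- vapply(seq_along(frames), function(t) {
    w <- warp_frame_to_canvas(frames[[t]], chain$h_cb[[t]], spec)
    s <- ssim_masked(canvas$image, w$image, w$mask)
    !is.na(s) && s > match_threshold
  }, logical(1))
  mean(vals)
}

#' Perturb a chain with a fixed-magnitude registration error
#'
#' Validation probe: composes every non-base transform with a translation of
#' `magnitude` pixels in a seeded random direction, emulating registration
#' error of a controlled size for quality-metric calibration.
#'
#' @param chain An `fm_chain`.
#' @param magnitude Translation error in pixels.
#' @param seed RNG seed for the directions.
#' @export
perturb_chain <- function(chain, magnitude, seed = 1L) {
  n <- length(chain$h_cb)
  with_seed(seed, {
    ang <- stats::runif(n, 0, 2 * pi)
    for (i in seq_len(n)) {
      if (i == 1L) next
      Tm <- homography_translation(magnitude * cos(ang[i]),
                                   magnitude * sin(ang[i]))
      chain$h_cb[[i]] <- normalize_homography(Tm %*% chain$h_cb[[i]])
    }
  })
  chain
}

#' Replace a chain with random transforms (negative control)
#'
#' Every non-base frame receives a random translation (within roughly the
#' chain's own canvas extent) and rotation, destroying registration while
#' keeping footprints finite. Used as the failure end-point when
#' calibrating scene integrity.
#'
#' @param chain An `fm_chain`.
#' @param seed RNG seed.
#' @export
randomize_chain <- function(chain, seed = 1L) {
  spec <- estimate_canvas(chain)
  W <- chain$frame_size[1L]; H <- chain$frame_size[2L]
  with_seed(seed, {
    for (i in seq_along(chain$h_cb)) {
      if (i == 1L) next
      chain$h_cb[[i]] <- normalize_homography(homography_similarity(
        theta = stats::runif(1, -pi, pi), scale = stats::runif(1, 0.8, 1.2),
        tx = stats::runif(1, 0, max(spec$width - W, 1)) - spec$offset[1L],
        ty = stats::runif(1, 0, max(spec$height - H, 1)) - spec$offset[2L],
        center = frame_center(W, H)))
    }
  })
  chain
}

#' Write a quality report to disk
#'
#' Emits `quality.json` (aggregates) and `quality_trace.csv` (per-frame
#' SSIM_f / SSIM_p), and optionally a PNG plot of the traces.
#'
#' @param quality An `fm_quality`.
#' @param dir Output directory.
#' @param plot Whether to write a trace plot.
#' @export
write_quality_report <- function(quality, dir, plot = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(mean_ssim_f = quality$mean_ssim_f,
         mean_ssim_p = quality$mean_ssim_p,
         scene_integrity = quality$scene_integrity,
         match_threshold = quality$match_threshold,
         frames_evaluated = nrow(quality$trace)),
    file.path(dir, "quality.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(quality$trace, file.path(dir, "quality_trace.csv"),
                   row.names = FALSE)
  if (plot) {
    grDevices::png(file.path(dir, "quality_trace.png"), width = 900,
                   height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    tr <- quality$trace
    graphics::plot(tr$frame, tr$ssim_p, type = "l", col = "steelblue",
                   ylim = range(c(tr$ssim_f, tr$ssim_p, 1), na.rm = TRUE),
                   xlab = "frame", ylab = "SSIM",
                   main = "Per-frame mosaic quality")
    graphics::lines(tr$frame, tr$ssim_f, col = "tomato")
    graphics::legend("bottomleft", legend = c("SSIM_p", "SSIM_f"),
                     col = c("steelblue", "tomato"), lty = 1, bty = "n")
  }
  invisible(dir)
}
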