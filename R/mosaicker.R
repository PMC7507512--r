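# Mini-mosaic construction: frames within a shot are divided into groups,
# each frame registered directly to its group's reference frame (H_CR), each
# reference registered to the previous reference (H_RR); references chain to
# the shot's base frame (H_RB), every frame reaches base coordinates through
# H_CB = H_RB %*% H_CR. The canvas is the bounding box of all warped frame
# corners, and blending is pixel filling: a canvas pixel is written by the
# first frame that covers it and never overwritten.

frame_center <- function(width, height) c((width - 1) / 2, (height - 1) / 2)

#' Assign frames of a shot to groups
#'
#' Scans frames in order, registering each against the open group's
#' reference. A new group is started when the open group already holds
#' `max_group_size` members (the paper rule: more than 40 frames), or when
#' the frame-center displacement under the current-to-reference homography
#' exceeds `displacement_frac` of the frame width in x or of the frame
#' height in y. The frame that triggers a split becomes the new group's
#' reference, and the registration that was just computed against the old
#' reference is kept as the new group's reference-to-reference homography
#' (H_RR), which is thereby always estimated by direct registration.
#'
#' @param frame_indices Ordered (local) frame indices of the shot.
#' @param frame_size Frame `(width, height)` in pixels.
#' @param register_fn Function `(i, ref)` returning a registration with at
#'   least an `H` field mapping frame `i` coordinates to frame `ref`
#'   coordinates.
#' @param max_group_size Maximum members per group.
#' @param displacement_frac Fraction of frame width/height that triggers a
#'   split.
#' @return List of groups, each with `index`, `reference`, `members`,
#'   `h_cr` (per-member 3x3), `h_rr` (registration to the previous group's
#'   reference; `NULL` for the first group), `regs` (per-member
#'   registration records).
#' @export
assign_groups <- function(frame_indices, frame_size, register_fn,
                          max_group_size = 40L, displacement_frac = 1 / 3) {
  stopifnot(length(frame_indices) >= 1L)
  W <- frame_size[1L]; H <- frame_size[2L]
  ctr <- frame_center(W, H)
  new_group <- function(idx, ref, h_rr) {
    list(index = idx, reference = ref, members = ref,
         h_cr = list(homography_identity()), h_rr = h_rr, regs = list(NULL))
  }
  groups <- list()
  cur <- new_group(1L, frame_indices[1L], NULL)
  for (i in frame_indices[-1L]) {
    reg <- register_fn(i, cur$reference)
    disp <- abs(apply_homography(reg$H, ctr) - ctr)
    split <- length(cur$members) >= max_group_size ||
      disp[1L] > displacement_frac * W || disp[2L] > displacement_frac * H
    if (split) {
      groups[[length(groups) + 1L]] <- cur
      cur <- new_group(length(groups) + 1L, i, reg)
    } else {
      cur$members <- c(cur$members, i)
      cur$h_cr[[length(cur$h_cr) + 1L]] <- normalize_homography(reg$H)
      cur$regs[[length(cur$regs) + 1L]] <- reg
    }
  }
  groups[[length(groups) + 1L]] <- cur
  groups
}

#' Chain group homographies to the shot's base frame
#'
#' Computes the reference-to-base homography of each group recursively,
#' `H_RB(g) = H_RB(g-1) %*% H_RR(g)` with `H_RB(1) = I`, and every frame's
#' current-to-base homography `H_CB = H_RB %*% H_CR`. All outputs are
#' normalized so element (3,3) is 1; the base frame's H_CB is the identity.
#'
#' @param groups Result of [assign_groups()].
#' @param frame_size Frame `(width, height)` in pixels.
#' @return An object of class `fm_chain`: `frames`, `group_of`, `h_cr`,
#'   `h_cb` (per frame), `h_rr`, `h_rb` (per group), `frame_size`.
#' @export
chain_homographies <- function(groups, frame_size) {
  ng <- length(groups)
  h_rb <- vector("list", ng)
  h_rb[[1L]] <- homography_identity()
  if (ng > 1L) {
    for (g in 2:ng) {
      if (is.null(groups[[g]]$h_rr) || is.null(groups[[g]]$h_rr$H)) {
        fm_stop("fm_chain_break",
                "missing reference-to-reference transform for group %d", g)
      }
      h_rb[[g]] <- normalize_homography(h_rb[[g - 1L]] %*% groups[[g]]$h_rr$H)
    }
  }
  frames <- integer(0); group_of <- integer(0)
  h_cr <- list(); h_cb <- list()
  for (g in seq_len(ng)) {
    grp <- groups[[g]]
    for (k in seq_along(grp$members)) {
      frames <- c(frames, grp$members[k])
      group_of <- c(group_of, g)
      h_cr[[length(h_cr) + 1L]] <- grp$h_cr[[k]]
      h_cb[[length(h_cb) + 1L]] <-
        normalize_homography(h_rb[[g]] %*% grp$h_cr[[k]])
    }
  }
  ord <- order(frames)
  structure(list(
    frames = frames[ord], group_of = group_of[ord],
    h_cr = h_cr[ord], h_cb = h_cb[ord],
    h_rr = lapply(groups, function(g) if (is.null(g$h_rr)) NULL else
      normalize_homography(g$h_rr$H)),
    h_rb = h_rb, frame_size = as.numeric(frame_size)
  ), class = "fm_chain")
}

#' @export
print.fm_chain <- function(x, ...) {
  cat(sprintf("<fm_chain: %d frames in %d group(s)>\n",
              length(x$frames), length(x$h_rb)))
  invisible(x)
}

#' Build a homography chain directly from ground truth
#'
#' Converts per-frame frame-to-scene homographies into current-to-base
#' transforms (base = first frame), the ideal chain a perfect registration
#' would recover. Used for validation and quality probes.
#'
#' @param ground_truth An `fm_ground_truth`.
#' @return An `fm_chain` with `h_cb` filled (single pseudo-group).
#' @export
ground_truth_chain <- function(ground_truth) {
  hs <- ground_truth$homographies
  H1i <- solve(hs[[1L]])
  h_cb <- lapply(hs, function(Hm) normalize_homography(H1i %*% Hm))
  structure(list(
    frames = seq_along(hs), group_of = rep(1L, length(hs)),
    h_cr = h_cb, h_cb = h_cb,
    h_rr = list(NULL), h_rb = list(homography_identity()),
    frame_size = ground_truth$spec$frame_size
  ), class = "fm_chain")
}

#' Estimate the mosaic canvas
#'
#' Warps every frame's four corners by its current-to-base homography and
#' takes the axis-aligned bounding box of all warped corners; the origin
#' offset shifts base-frame coordinates into non-negative canvas indices.
#'
#' @param chain An `fm_chain`.
#' @param frame_size Frame `(width, height)`; defaults to the chain's.
#' @return List with `width`, `height`, `offset` (length-2, added to
#'   base-frame coordinates to get 0-based canvas coordinates).
#' @export
estimate_canvas <- function(chain, frame_size = chain$frame_size) {
  W <- frame_size[1L]; H <- frame_size[2L]
  pts <- lapply(seq_along(chain$h_cb), function(k) {
    fp <- footprint_polygon(chain$h_cb[[k]], W, H)
    if (any(!is.finite(fp))) {
      fm_stop("fm_degenerate_transform",
              "non-finite warped corner for frame %d", chain$frames[k])
    }
    fp
  })
  all_pts <- do.call(rbind, pts)
  xmin <- floor(min(all_pts[, 1L])); xmax <- ceiling(max(all_pts[, 1L]))
  ymin <- floor(min(all_pts[, 2L])); ymax <- ceiling(max(all_pts[, 2L]))
  list(width = as.integer(xmax - xmin + 1L),
       height = as.integer(ymax - ymin + 1L),
       offset = c(-xmin, -ymin))
}

#' Create an empty mosaic canvas
#'
#' @param spec Canvas geometry from [estimate_canvas()].
#' @param channels Number of image channels.
#' @return An object of class `fm_canvas` with `image`, `provenance`
#'   (integer matrix, 0 = unfilled), `offset`, `footprints`.
#' @export
new_canvas <- function(spec, channels = 3L) {
  structure(list(
    image = array(0, c(spec$height, spec$width, channels)),
    provenance = matrix(0L, spec$height, spec$width),
    offset = spec$offset,
    footprints = list()
  ), class = "fm_canvas")
}

#' @export
print.fm_canvas <- function(x, ...) {
  cat(sprintf("<fm_canvas: %d x %d px, %d frame(s), %.1f%% filled>\n",
              ncol(x$provenance), nrow(x$provenance), length(x$footprints),
              100 * mean(x$provenance > 0)))
  invisible(x)
}

#' Warp a frame into the canvas and blend by pixel filling
#'
#' Inverse-warps the frame into canvas coordinates (bilinear) within the
#' footprint's region of interest. Only previously unfilled canvas pixels
#' receive values, so every canvas pixel originates from exactly one frame;
#' re-blending a frame is a no-op. The provenance map records the supplying
#' frame index.
#'
#' @param canvas An `fm_canvas`.
#' @param frame The frame to blend.
#' @param H_CB Current-to-base homography of the frame.
#' @param frame_index Index recorded in the provenance map.
#' @param src_mask Optional logical matrix (frame-sized) marking valid
#'   source pixels (used when blending mini-mosaics, whose canvases contain
#'   unfilled regions).
#' @return The updated canvas.
#' @export
warp_and_blend <- function(canvas, frame, H_CB,
                           frame_index = if (inherits(frame, "fm_frame"))
                             frame$index else NA_integer_,
                           src_mask = NULL) {
  stopifnot(inherits(canvas, "fm_canvas"))
  img <- as_frame_image(frame)
  fh <- nrow(img); fw <- ncol(img)
  Wc <- ncol(canvas$provenance); Hc <- nrow(canvas$provenance)
  fp <- footprint_polygon(H_CB, fw, fh)
  fpc <- sweep(fp, 2L, canvas$offset, "+")
  tol <- 1e-6
  if (min(fpc[, 1L]) < -tol || max(fpc[, 1L]) > Wc - 1 + tol ||
      min(fpc[, 2L]) < -tol || max(fpc[, 2L]) > Hc - 1 + tol) {
    fm_stop("fm_canvas_overflow",
            "footprint of frame %s exceeds the canvas", frame_index)
  }
  c0 <- max(1L, floor(min(fpc[, 1L])) + 1L)
  c1 <- min(Wc, ceiling(max(fpc[, 1L])) + 1L)
  r0 <- max(1L, floor(min(fpc[, 2L])) + 1L)
  r1 <- min(Hc, ceiling(max(fpc[, 2L])) + 1L)
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  xs <- rep((c0:c1) - 1 - canvas$offset[1L], each = nr)
  ys <- rep((r0:r1) - 1 - canvas$offset[2L], nc)
  p <- apply_homography(solve(H_CB), cbind(xs, ys))
  inside <- p[, 1L] >= 0 & p[, 1L] <= fw - 1 &
    p[, 2L] >= 0 & p[, 2L] <= fh - 1
  if (!is.null(src_mask)) {
    rr <- pmin(pmax(round(p[, 2L]), 0), fh - 1) + 1L
    cc <- pmin(pmax(round(p[, 1L]), 0), fw - 1) + 1L
    inside <- inside & src_mask[cbind(rr, cc)]
  }
  prov_roi <- canvas$provenance[r0:r1, c0:c1]
  writable <- inside & (as.vector(prov_roi) == 0L)
  if (any(writable)) {
    vals <- sample_bilinear(img, p[writable, 1L], p[writable, 2L])
    C <- dim(canvas$image)[3L]
    roi_idx <- which(writable)
    roi_rows <- ((roi_idx - 1L) %% nr) + r0
    roi_cols <- ((roi_idx - 1L) %/% nr) + c0
    plane <- Hc * Wc
    flat_idx <- (roi_cols - 1L) * Hc + roi_rows
    for (ch in seq_len(min(C, ncol(vals)))) {
      canvas$image[flat_idx + (ch - 1L) * plane] <- vals[, ch]
    }
    if (C == 3L && ncol(vals) == 1L) {
      for (ch in 2:3) canvas$image[flat_idx + (ch - 1L) * plane] <- vals[, 1L]
    }
    prov_roi[roi_idx] <- as.integer(frame_index)
    canvas$provenance[r0:r1, c0:c1] <- prov_roi
  }
  canvas$footprints[[length(canvas$footprints) + 1L]] <-
    list(frame = frame_index, corners = fpc)
  canvas
}

#' Configuration for mini-mosaic construction
#'
#' @param policy A [register_policy()].
#' @param max_group_size Maximum frames per group.
#' @param displacement_frac Frame-center displacement fraction that opens a
#'   new group.
#' @export
mosaic_config <- function(policy = register_policy(),
                          max_group_size = 40L,
                          displacement_frac = 1 / 3) {
  structure(list(policy = policy,
                 max_group_size = as.integer(max_group_size),
                 displacement_frac = displacement_frac),
            class = "fm_mosaic_config")
}

#' Build a mini-mosaic from one shot
#'
#' Runs the full per-shot pipeline: adaptive registration of every frame
#' against its group reference (and of each reference against the previous
#' reference), grouping, homography chaining, canvas estimation, and
#' pixel-fill blending in frame order. A single-frame shot returns that
#' frame as its mini-mosaic.
#'
#' @param frames List of `fm_frame` objects (the shot, in temporal order).
#' @param config A [mosaic_config()].
#' @param register_fn Optional override passed to [adaptive_register()].
#' @return An object of class `fm_mosaic`: `canvas`, `chain`, `groups`,
#'   `log` (per-registration data frame).
#' @export
build_mini_mosaic <- function(frames, config = mosaic_config(),
                              register_fn = NULL) {
  stopifnot(length(frames) >= 1L)
  W <- frames[[1L]]$width; H <- frames[[1L]]$height
  log_rows <- list()
  reg_fn <- function(i, ref) {
    reg <- adaptive_register(frames[[i]], frames[[ref]],
                             policy = config$policy,
                             register_fn = register_fn)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      frame = frames[[i]]$index, reference = frames[[ref]]$index,
      descriptor = reg$descriptor,
      n_features = reg$n_features %||% NA_integer_,
      n_matches = reg$n_matches %||% NA_integer_,
      n_inliers = reg$n_inliers %||% NA_integer_,
      inlier_ratio = reg$inlier_ratio,
      rms = reg$rms %||% NA_real_,
      low_confidence = isTRUE(reg$low_confidence))
    reg
  }
  groups <- assign_groups(seq_along(frames), c(W, H), reg_fn,
                          max_group_size = config$max_group_size,
                          displacement_frac = config$displacement_frac)
  chain <- chain_homographies(groups, c(W, H))
  spec <- estimate_canvas(chain)
  canvas <- new_canvas(spec, channels = if (length(dim(frames[[1L]]$image)) ==
                                            3L) 3L else 1L)
  for (k in seq_along(chain$frames)) {
    local_i <- chain$frames[k]
    canvas <- warp_and_blend(canvas, frames[[local_i]], chain$h_cb[[k]],
                             frame_index = frames[[local_i]]$index)
  }
  # report chain in terms of the frames' own (global) indices
  chain$frames <- vapply(frames, function(f) f$index, integer(1))[chain$frames]
  structure(list(canvas = canvas, chain = chain, groups = groups,
                 log = if (length(log_rows)) do.call(rbind, log_rows) else
                   NULL),
            class = "fm_mosaic")
}

#' @export
print.fm_mosaic <- function(x, ...) {
  cat(sprintf("<fm_mosaic: %d frame(s), %d group(s), canvas %d x %d px>\n",
              length(x$chain$frames), length(x$h_rb %||% x$chain$h_rb),
              ncol(x$canvas$provenance), nrow(x$canvas$provenance)))
  invisible(x)
}

#' Merge mini-mosaics into a meta-mosaic
#'
#' Registers each mini-mosaic to the previous one with the adaptive ladder
#' (treating mini-mosaics as frames), chains the transforms to the first
#' shot's base coordinates, and blends by pixel filling. A single
#' mini-mosaic passes through unchanged. If adjacent mini-mosaics cannot be
#' registered (no scene overlap), an `fm_unmergeable_shots` error is raised
#' carrying the individual mosaics in its `mosaics` field.
#'
#' @param minis List of `fm_mosaic` objects in temporal order.
#' @param policy A [register_policy()] for mosaic-to-mosaic registration.
#' @return An `fm_mosaic` whose chain holds the mini-to-base transforms.
#' @export
meta_mosaic <- function(minis, policy = register_policy()) {
  stopifnot(length(minis) >= 1L)
  if (length(minis) == 1L) return(minis[[1L]])
  # unfilled canvas pixels would bias intensity-based refinement
  policy$refine <- FALSE
  n <- length(minis)
  imgs <- lapply(seq_len(n), function(k) {
    new_frame(minis[[k]]$canvas$image, k)
  })
  masks <- lapply(minis, function(m) m$canvas$provenance > 0L)
  trans <- vector("list", n)
  trans[[1L]] <- homography_identity()
  log_rows <- list()
  for (k in 2:n) {
    reg <- tryCatch(
      adaptive_register(imgs[[k]], imgs[[k - 1L]], policy = policy),
      fm_error = function(e) e)
    if (!inherits(reg, "fm_error") && isTRUE(reg$low_confidence)) {
      # a sub-threshold best guess between whole mosaics is evidence of
      # missing scene overlap, not of a hard registration fault
      reg <- structure(class = c("fm_registration_failure", "fm_error",
                                 "error", "condition"),
                       list(message = sprintf(
                         "best inlier ratio %.2f below threshold",
                         reg$inlier_ratio), call = NULL))
    }
    if (inherits(reg, "fm_error")) {
      stop(structure(
        class = c("fm_unmergeable_shots", "fm_error", "error", "condition"),
        list(message = sprintf(
          "mini-mosaics %d and %d share no usable overlap (%s)",
          k - 1L, k, conditionMessage(reg)),
          call = NULL, mosaics = minis)))
    }
    trans[[k]] <- normalize_homography(trans[[k - 1L]] %*% reg$H)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      frame = k, reference = k - 1L, descriptor = reg$descriptor,
      inlier_ratio = reg$inlier_ratio,
      low_confidence = isTRUE(reg$low_confidence))
  }
  corners <- lapply(seq_len(n), function(k) {
    footprint_polygon(trans[[k]], imgs[[k]]$width, imgs[[k]]$height)
  })
  all_pts <- do.call(rbind, corners)
  spec <- list(width = as.integer(ceiling(max(all_pts[, 1L])) -
                                  floor(min(all_pts[, 1L])) + 1L),
               height = as.integer(ceiling(max(all_pts[, 2L])) -
                                   floor(min(all_pts[, 2L])) + 1L),
               offset = c(-floor(min(all_pts[, 1L])),
                          -floor(min(all_pts[, 2L]))))
  canvas <- new_canvas(spec)
  for (k in seq_len(n)) {
    canvas <- warp_and_blend(canvas, imgs[[k]], trans[[k]], frame_index = k,
                             src_mask = masks[[k]])
  }
  chain <- structure(list(
    frames = seq_len(n), group_of = rep(1L, n), h_cr = trans, h_cb = trans,
    h_rr = list(NULL), h_rb = list(homography_identity()),
    frame_size = c(imgs[[1L]]$width, imgs[[1L]]$height)
  ), class = "fm_chain")
  structure(list(canvas = canvas, chain = chain, groups = NULL,
                 log = if (length(log_rows)) do.call(rbind, log_rows) else
                   NULL),
            class = "fm_mosaic")
}

#' Naive frame-to-frame homography chain
#'
#' Registers every consecutive frame pair and composes the transforms into a
#' full chain to the first frame. This is the baseline whose drift the
#' grouped chain is designed to reduce; it is provided for that comparison.
#'
#' @param frames List of `fm_frame` objects.
#' @param policy A [register_policy()].
#' @param register_fn Optional override passed to [adaptive_register()].
#' @return An `fm_chain` (one pseudo-group; `h_cb` holds the composed
#'   transforms).
#' @export
frame_to_frame_chain <- function(frames, policy = register_policy(),
                                 register_fn = NULL) {
  n <- length(frames)
  h_cb <- vector("list", n)
  h_cb[[1L]] <- homography_identity()
  if (n > 1L) {
    for (i in 2:n) {
      reg <- adaptive_register(frames[[i]], frames[[i - 1L]], policy = policy,
                               register_fn = register_fn)
      h_cb[[i]] <- normalize_homography(h_cb[[i - 1L]] %*% reg$H)
    }
  }
  structure(list(
    frames = vapply(frames, function(f) f$index, integer(1)),
    group_of = rep(1L, n), h_cr = h_cb, h_cb = h_cb,
    h_rr = list(NULL), h_rb = list(homography_identity()),
    frame_size = c(frames[[1L]]$width, frames[[1L]]$height)
  ), class = "fm_chain")
}

#' Write mosaic artifacts to disk
#'
#' Writes the mosaic PNG, the homography chain JSON (per frame: H_CR and
#' H_CB, row-major), footprint polygons in canvas coordinates as JSON, and
#' the provenance map as a 16-bit-equivalent two-channel PNG (low byte in
#' red, high byte in green).
#'
#' @param mosaic An `fm_mosaic`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @export
write_mosaic <- function(mosaic, dir, prefix = "mosaic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(mosaic$canvas$image, file.path(dir, paste0(prefix, ".png")))
  chain <- mosaic$chain
  jsonlite::write_json(
    list(frames = chain$frames,
         group_of = chain$group_of,
         h_cr = lapply(chain$h_cr, function(H) as.vector(t(H))),
         h_cb = lapply(chain$h_cb, function(H) as.vector(t(H)))),
    file.path(dir, paste0(prefix, "_chain.json")),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(mosaic$canvas$footprints, function(f) {
      list(frame = f$frame, corners = as.vector(t(f$corners)))
    }),
    file.path(dir, paste0(prefix, "_footprints.json")),
    auto_unbox = TRUE, digits = NA)
  prov <- mosaic$canvas$provenance
  prov_img <- array(0, c(nrow(prov), ncol(prov), 3L))
  prov_img[, , 1L] <- (prov %% 256L) / 255
  prov_img[, , 2L] <- (prov %/% 256L) / 255
  write_image(prov_img, file.path(dir, paste0(prefix, "_provenance.png")))
  invisible(dir)
}
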