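# Feature-based pairwise registration. Three descriptor rungs are provided
# behind one interface, ordered from fastest to most robust:
#   "st"            - structure-tensor (minimum-eigenvalue) corners selected
#                     one per micro-block, with raw normalized patch
#                     descriptors; fast, upright, for large-overlap pairs.
#   "fast_local"    - dense non-max-suppressed corners with larger
#                     illumination-normalized patch descriptors sampled at a
#                     coarser scale; upright.
#   "affine_robust" - as "fast_local" but each descriptor patch is rotated to
#                     the keypoint's dominant gradient orientation, giving
#                     in-plane-rotation robustness for abrupt viewpoint
#                     changes.
# The adaptive policy tries the rungs in order and escalates whenever the
# post-RANSAC inlier ratio falls below the acceptance threshold (default
# 40%).

# Shi-Tomasi style corner strength: minimum eigenvalue of the smoothed
# gradient structure tensor.
corner_response <- function(gray, sigma = 1.0) {
  g <- image_gradients(gray)
  sxx <- gaussian_smooth(g$gx * g$gx, sigma)
  syy <- gaussian_smooth(g$gy * g$gy, sigma)
  sxy <- gaussian_smooth(g$gx * g$gy, sigma)
  0.5 * ((sxx + syy) - sqrt((sxx - syy)^2 + 4 * sxy^2))
}

# 3x3 non-maximum suppression mask (strictly greater than 8-neighbours,
# ties broken toward the earlier pixel in column-major order by >=/>).
nonmax3 <- function(r) {
  H <- nrow(r); W <- ncol(r)
  shift <- function(dr, dc) {
    ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
    ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
    r[ri, ci, drop = FALSE]
  }
  ok <- r > shift(0, 1) & r >= shift(0, -1) &
    r > shift(1, 0) & r >= shift(-1, 0) &
    r > shift(1, 1) & r >= shift(-1, -1) &
    r > shift(1, -1) & r >= shift(-1, 1)
  ok
}

# One-dimensional quadratic sub-pixel refinement along both axes.
refine_subpixel <- function(r, rows, cols) {
  H <- nrow(r); W <- ncol(r)
  dx <- dy <- numeric(length(rows))
  okc <- cols > 1L & cols < W
  okr <- rows > 1L & rows < H
  c0 <- r[cbind(rows, cols)]
  if (any(okc)) {
    cm <- r[cbind(rows[okc], cols[okc] - 1L)]
    cp <- r[cbind(rows[okc], cols[okc] + 1L)]
    den <- cm - 2 * c0[okc] + cp
    d <- ifelse(abs(den) > 1e-12, 0.5 * (cm - cp) / den, 0)
    dx[okc] <- pmin(pmax(d, -0.5), 0.5)
  }
  if (any(okr)) {
    rm <- r[cbind(rows[okr] - 1L, cols[okr])]
    rp <- r[cbind(rows[okr] + 1L, cols[okr])]
    den <- rm - 2 * c0[okr] + rp
    d <- ifelse(abs(den) > 1e-12, 0.5 * (rm - rp) / den, 0)
    dy[okr] <- pmin(pmax(d, -0.5), 0.5)
  }
  cbind(dx, dy)
}

descriptor_params <- function(kind) {
  switch(kind,
    st = list(radius = 4L, spacing = 1, blur = 0, oriented = FALSE),
    fast_local = list(radius = 7L, spacing = 1.5, blur = 1, oriented = FALSE),
    affine_robust = list(radius = 7L, spacing = 1.5, blur = 1,
                         oriented = TRUE),
    fm_stop("fm_invalid_argument", "unknown descriptor kind '%s'", kind))
}

# Dominant gradient orientation per keypoint: magnitude-weighted 36-bin
# histogram over a Gaussian-weighted disc, circularly smoothed, with
# parabolic peak interpolation.
keypoint_orientations <- function(gray, pts, radius = 6L, sigma = 3) {
  g <- image_gradients(gaussian_smooth(gray, 1.5))
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  wgt <- exp(-(off$dx^2 + off$dy^2) / (2 * sigma^2))
  n <- nrow(pts); m <- nrow(off)
  px <- rep(pts[, 1L], each = m) + rep(off$dx, n)
  py <- rep(pts[, 2L], each = m) + rep(off$dy, n)
  gx <- sample_bilinear(g$gx, px, py)[, 1L]
  gy <- sample_bilinear(g$gy, px, py)[, 1L]
  mag <- sqrt(gx^2 + gy^2) * rep(wgt, n)
  ang <- atan2(gy, gx)
  bin <- (floor((ang + pi) / (2 * pi) * 36) %% 36) + 1L
  grp <- rep(seq_len(n), each = m)
  cell <- (grp - 1L) * 36L + bin
  acc <- rowsum(mag, cell)
  hist <- matrix(0, n, 36L)
  cells <- as.integer(rownames(acc))
  hist[cbind((cells - 1L) %/% 36L + 1L, (cells - 1L) %% 36L + 1L)] <- acc[, 1L]
  # circular smoothing
  sm <- hist
  for (s in c(-1L, 1L)) sm <- sm + hist[, ((seq_len(36L) - 1L + s) %% 36L) + 1L]
  sm <- sm / 3
  peak <- max.col(sm, ties.method = "first")
  left <- sm[cbind(seq_len(n), ((peak - 2L) %% 36L) + 1L)]
  mid <- sm[cbind(seq_len(n), peak)]
  right <- sm[cbind(seq_len(n), (peak %% 36L) + 1L)]
  den <- left - 2 * mid + right
  frac <- ifelse(abs(den) > 1e-12, 0.5 * (left - right) / den, 0)
  ((peak - 1 + pmin(pmax(frac, -0.5), 0.5)) / 36) * 2 * pi - pi
}

sample_patch_descriptors <- function(gray, pts, params, angles = NULL) {
  src <- if (params$blur > 0) gaussian_smooth(gray, params$blur) else gray
  r <- params$radius
  grid <- expand.grid(dx = (-r:r) * params$spacing,
                      dy = (-r:r) * params$spacing)
  m <- nrow(grid); n <- nrow(pts)
  if (is.null(angles)) {
    px <- rep(pts[, 1L], each = m) + rep(grid$dx, n)
    py <- rep(pts[, 2L], each = m) + rep(grid$dy, n)
  } else {
    ca <- rep(cos(angles), each = m); sa <- rep(sin(angles), each = m)
    gx <- rep(grid$dx, n); gy <- rep(grid$dy, n)
    px <- rep(pts[, 1L], each = m) + ca * gx - sa * gy
    py <- rep(pts[, 2L], each = m) + sa * gx + ca * gy
  }
  vals <- sample_bilinear(src, px, py)[, 1L]
  D <- matrix(vals, nrow = n, ncol = m, byrow = TRUE)
  D <- D - rowMeans(D)
  nrm <- sqrt(rowSums(D^2))
  D / pmax(nrm, 1e-12)
}

#' Detect features in a frame
#'
#' Detects corner keypoints with the requested descriptor family and keeps
#' at most `max_keep` of them, strongest first by detector response with a
#' deterministic `(y, x)` tie-break. The `"st"` kind returns at most one
#' keypoint per `block_size` x `block_size` micro-block.
#'
#' @param frame An `fm_frame` or image array.
#' @param kind `"st"`, `"fast_local"`, or `"affine_robust"`.
#' @param max_keep Maximum number of keypoints retained (>= 4).
#' @param block_size Micro-block size in pixels for the `"st"` kind.
#' @param response_threshold Minimum corner response for a candidate.
#' @return An object of class `fm_features` with `pts` (n x 2, sub-pixel
#'   x/y), `strength`, `desc` (n x d normalized descriptors), `kind`.
#' @export
detect_features <- function(frame, kind = c("st", "fast_local",
                                            "affine_robust"),
                            max_keep = 5000L, block_size = 8L,
                            response_threshold = 1e-9) {
  kind <- match.arg(kind)
  if (max_keep < 4L) fm_stop("fm_invalid_argument", "max_keep must be >= 4")
  img <- as_frame_image(frame)
  gray <- rgb_to_gray(img)
  H <- nrow(gray); W <- ncol(gray)
  params <- descriptor_params(kind)
  border <- ceiling(params$radius * params$spacing * 1.5) + 3L
  if (H <= 2L * border + 2L || W <= 2L * border + 2L) {
    fm_stop("fm_low_texture", "frame too small for feature detection")
  }
  r <- corner_response(gray)
  mask <- matrix(FALSE, H, W)
  mask[(border + 1L):(H - border), (border + 1L):(W - border)] <- TRUE
  if (kind == "st") {
    cand <- which(mask & r > response_threshold)
  } else {
    cand <- which(nonmax3(r) & mask & r > response_threshold)
  }
  if (length(cand) < 4L) {
    fm_stop("fm_low_texture",
            "only %d features found in frame (need >= 4)", length(cand))
  }
  rows <- ((cand - 1L) %% H) + 1L
  cols <- ((cand - 1L) %/% H) + 1L
  strength <- r[cand]
  if (kind == "st") {
    block <- ((rows - 1L) %/% block_size) * (W %/% block_size + 2L) +
      ((cols - 1L) %/% block_size)
    ord <- order(-strength, rows, cols)
    keep <- !duplicated(block[ord])
    sel <- ord[keep]
  } else {
    sel <- order(-strength, rows, cols)
  }
  sel <- sel[seq_len(min(length(sel), max_keep))]
  rows <- rows[sel]; cols <- cols[sel]; strength <- strength[sel]
  d <- refine_subpixel(r, rows, cols)
  pts <- cbind(x = cols - 1 + d[, 1L], y = rows - 1 + d[, 2L])
  angles <- if (params$oriented) keypoint_orientations(gray, pts) else NULL
  desc <- sample_patch_descriptors(gray, pts, params, angles)
  structure(list(
    frame_index = if (inherits(frame, "fm_frame")) frame$index else NA_integer_,
    kind = kind, pts = pts, strength = strength,
    angles = angles, desc = desc
  ), class = "fm_features")
}

#' @export
print.fm_features <- function(x, ...) {
  cat(sprintf("<fm_features: %d '%s' keypoints (frame %s)>\n",
              nrow(x$pts), x$kind, x$frame_index))
  invisible(x)
}

empty_matchset <- function(fa, fb) {
  structure(list(
    src_frame = fa$frame_index, dst_frame = fb$frame_index,
    kind = fa$kind,
    src_pts = matrix(numeric(0), 0L, 2L),
    dst_pts = matrix(numeric(0), 0L, 2L),
    score = numeric(0), inlier_mask = logical(0), inlier_ratio = NA_real_
  ), class = "fm_matches")
}

#' Match two feature sets
#'
#' Nearest-neighbour descriptor matching with a Lowe-style ratio test and
#' greedy one-to-one assignment (best matches claimed first). Descriptors
#' are unit-normalized, so distances are computed from correlations.
#'
#' @param fa,fb `fm_features` of the same kind.
#' @param ratio Ratio-test threshold on descriptor distances.
#' @return An object of class `fm_matches`; empty when nothing passes the
#'   ratio test.
#' @export
match_features <- function(fa, fb, ratio = 0.75) {
  stopifnot(inherits(fa, "fm_features"), inherits(fb, "fm_features"))
  if (fa$kind != fb$kind) {
    fm_stop("fm_invalid_argument",
            "cannot match descriptors of kinds '%s' and '%s'",
            fa$kind, fb$kind)
  }
  na <- nrow(fa$desc); nb <- nrow(fb$desc)
  if (na == 0L || nb == 0L) return(empty_matchset(fa, fb))
  best_j <- integer(na); best_d <- numeric(na); second_d <- numeric(na)
  chunk <- max(1L, floor(2e6 / max(nb, 1L)))
  for (s in seq(1L, na, by = chunk)) {
    e <- min(na, s + chunk - 1L)
    S <- fa$desc[s:e, , drop = FALSE] %*% t(fb$desc)
    D2 <- pmax(2 - 2 * S, 0)
    j1 <- max.col(-D2, ties.method = "first")
    d1 <- D2[cbind(seq_len(nrow(D2)), j1)]
    D2[cbind(seq_len(nrow(D2)), j1)] <- Inf
    d2 <- if (nb > 1L) apply(D2, 1L, min) else rep(Inf, nrow(D2))
    best_j[s:e] <- j1; best_d[s:e] <- d1; second_d[s:e] <- d2
  }
  pass <- which(best_d <= ratio^2 * second_d)
  if (length(pass) == 0L) return(empty_matchset(fa, fb))
  ord <- pass[order(best_d[pass], pass)]
  used <- logical(nb)
  keep <- integer(0)
  for (i in ord) {
    if (!used[best_j[i]]) {
      used[best_j[i]] <- TRUE
      keep <- c(keep, i)
    }
  }
  structure(list(
    src_frame = fa$frame_index, dst_frame = fb$frame_index,
    kind = fa$kind,
    src_pts = fa$pts[keep, , drop = FALSE],
    dst_pts = fb$pts[best_j[keep], , drop = FALSE],
    score = sqrt(best_d[keep]),
    inlier_mask = rep(NA, length(keep)), inlier_ratio = NA_real_
  ), class = "fm_matches")
}

#' @export
print.fm_matches <- function(x, ...) {
  cat(sprintf("<fm_matches: %d correspondences %s -> %s (inlier ratio %s)>\n",
              nrow(x$src_pts), x$src_frame, x$dst_frame,
              ifelse(is.na(x$inlier_ratio), "unset",
                     sprintf("%.2f", x$inlier_ratio))))
  invisible(x)
}

#' RANSAC homography estimation from putative matches
#'
#' Repeatedly fits projective transforms to random 4-point subsets by the
#' direct linear transformation, scores candidates by symmetric transfer
#' error, and refits on the final consensus set by least squares. Collinear
#' samples are rejected and iteration continues. Seeded and reproducible.
#'
#' @param matches An `fm_matches` with at least 4 correspondences.
#' @param reproj_tol Inlier threshold on the symmetric transfer error
#'   (pixels).
#' @param max_iters Maximum sampling iterations (adaptive early stop at
#'   `confidence`).
#' @param seed Optional RNG seed.
#' @param confidence Early-stop confidence for the adaptive iteration bound.
#' @return List with `matches` (inlier mask and ratio filled in) and
#'   `homography` (list: `H` mapping source to target points, `rms`
#'   reprojection error over inliers, `n_inliers`, frame indices).
#' @export
ransac_filter <- function(matches, reproj_tol = 2, max_iters = 2000L,
                          seed = NULL, confidence = 0.99) {
  stopifnot(inherits(matches, "fm_matches"))
  n <- nrow(matches$src_pts)
  if (n < 4L) {
    fm_stop("fm_degenerate_input",
            "RANSAC needs >= 4 correspondences (got %d) for pair %s -> %s",
            n, matches$src_frame, matches$dst_frame)
  }
  src <- matches$src_pts; dst <- matches$dst_pts
  run <- function() {
    best_inl <- logical(n); best_count <- 0L
    needed <- max_iters
    it <- 0L
    while (it < min(needed, max_iters)) {
      it <- it + 1L
      idx <- sample.int(n, 4L)
      s4 <- src[idx, , drop = FALSE]; d4 <- dst[idx, , drop = FALSE]
      if (points_degenerate(s4) || points_degenerate(d4)) next
      Hc <- tryCatch(fit_homography(s4, d4), fm_error = function(e) NULL,
                     error = function(e) NULL)
      if (is.null(Hc)) next
      err <- symmetric_transfer_error(Hc, src, dst)
      inl <- is.finite(err) & err <= reproj_tol
      cnt <- sum(inl)
      if (cnt > best_count) {
        best_count <- cnt; best_inl <- inl
        w <- cnt / n
        if (w > 0) {
          needed <- min(max_iters,
                        ceiling(log(1 - confidence) /
                                log(pmax(1 - w^4, 1e-12))))
        }
      }
    }
    list(inl = best_inl, count = best_count)
  }
  best <- if (n == 4L) {
    if (points_degenerate(src) || points_degenerate(dst)) {
      fm_stop("fm_registration_failure",
              "all four correspondences are degenerate for pair %s -> %s",
              matches$src_frame, matches$dst_frame)
    }
    list(inl = rep(TRUE, 4L), count = 4L)
  } else {
    with_seed(seed, run())
  }
  if (best$count < 4L) {
    fm_stop("fm_registration_failure",
            "no consensus model with >= 4 inliers for pair %s -> %s",
            matches$src_frame, matches$dst_frame)
  }
  H <- fit_homography(src[best$inl, , drop = FALSE],
                      dst[best$inl, , drop = FALSE])
  err <- symmetric_transfer_error(H, src, dst)
  inl <- is.finite(err) & err <= reproj_tol
  if (sum(inl) < 4L) inl <- best$inl
  matches$inlier_mask <- inl
  matches$inlier_ratio <- mean(inl)
  rms <- sqrt(mean(err[inl]^2))
  list(
    matches = matches,
    homography = list(H = H, src_frame = matches$src_frame,
                      dst_frame = matches$dst_frame, rms = rms,
                      n_inliers = sum(inl))
  )
}

#' Registration policy for the adaptive descriptor ladder
#'
#' @param ladder Descriptor kinds tried in order.
#' @param inlier_threshold Minimum post-RANSAC inlier ratio for acceptance.
#' @param ratio Ratio-test threshold for matching.
#' @param max_keep Strongest-K keypoint cap per frame.
#' @param block_size Micro-block size for the `"st"` rung.
#' @param ransac_tol,ransac_iters RANSAC reprojection tolerance (px) and
#'   iteration cap.
#' @param refine Photometrically refine accepted homographies (recommended;
#'   suppresses accumulation of detector-localization bias along chains).
#' @param seed Base seed for RANSAC sampling (per-pair seeds are derived
#'   from it and the frame indices).
#' @export
register_policy <- function(ladder = c("st", "fast_local", "affine_robust"),
                            inlier_threshold = 0.4, ratio = 0.75,
                            max_keep = 5000L, block_size = 8L,
                            ransac_tol = 2, ransac_iters = 2000L,
                            refine = TRUE, seed = 1L) {
  if (length(ladder) < 1L) {
    fm_stop("fm_invalid_argument", "descriptor ladder must be non-empty")
  }
  structure(list(ladder = ladder, inlier_threshold = inlier_threshold,
                 ratio = ratio, max_keep = as.integer(max_keep),
                 block_size = as.integer(block_size),
                 ransac_tol = ransac_tol,
                 ransac_iters = as.integer(ransac_iters),
                 refine = isTRUE(refine), seed = seed),
            class = "fm_register_policy")
}

pair_seed <- function(policy, a, b) {
  if (is.null(policy$seed)) return(NULL)
  a <- if (is.na(a)) 0L else as.integer(a)
  b <- if (is.na(b)) 0L else as.integer(b)
  (as.integer(policy$seed) * 7919L + a * 1009L + b * 271L) %% 2000000011L
}

# Photometric (Gauss-Newton) refinement of a homography: minimizes the sum
# of squared intensity differences between the reference and the warped
# current frame over a subsampled grid, with residual trimming. Removes the
# small detector-localization bias that feature-only estimates accumulate
# when chained over many frames.
refine_homography_photometric <- function(src_gray, dst_gray, H,
                                          max_iters = 25L, step_px = 3L,
                                          trim = 0.9) {
  Hs <- nrow(src_gray); Ws <- ncol(src_gray)
  Hd <- nrow(dst_gray); Wd <- ncol(dst_gray)
  gd <- image_gradients(dst_gray)
  xs <- seq(2, Ws - 3, by = step_px)
  ys <- seq(2, Hs - 3, by = step_px)
  gx0 <- rep(xs, each = length(ys))
  gy0 <- rep(ys, length(xs))
  Iv <- sample_bilinear(src_gray, gx0, gy0)[, 1L]
  H <- normalize_homography(H)
  for (it in seq_len(max_iters)) {
    P <- cbind(gx0, gy0, 1) %*% t(H)
    w <- P[, 3L]; u <- P[, 1L] / w; v <- P[, 2L] / w
    ok <- w > 1e-6 & u >= 1 & u <= Wd - 2 & v >= 1 & v <= Hd - 2
    if (sum(ok) < 50L) break
    x <- gx0[ok]; y <- gy0[ok]; wo <- w[ok]; uo <- u[ok]; vo <- v[ok]
    Id <- sample_bilinear(dst_gray, uo, vo)[, 1L]
    gxv <- sample_bilinear(gd$gx, uo, vo)[, 1L]
    gyv <- sample_bilinear(gd$gy, uo, vo)[, 1L]
    r <- Id - Iv[ok]
    keep <- abs(r) <= stats::quantile(abs(r), trim)
    x <- x[keep]; y <- y[keep]; wo <- wo[keep]; uo <- uo[keep]
    vo <- vo[keep]; gxv <- gxv[keep]; gyv <- gyv[keep]; r <- r[keep]
    iw <- 1 / wo
    J <- cbind(gxv * x * iw, gxv * y * iw, gxv * iw,
               gyv * x * iw, gyv * y * iw, gyv * iw,
               -(gxv * uo + gyv * vo) * x * iw,
               -(gxv * uo + gyv * vo) * y * iw)
    A <- crossprod(J) + diag(1e-8, 8L)
    delta <- tryCatch(solve(A, -crossprod(J, r)), error = function(e) NULL)
    if (is.null(delta)) break
    Hn <- H
    Hn[1L, ] <- Hn[1L, ] + delta[1:3]
    Hn[2L, ] <- Hn[2L, ] + delta[4:6]
    Hn[3L, 1:2] <- Hn[3L, 1:2] + delta[7:8]
    Hn <- normalize_homography(Hn)
    move <- corner_error(Hn, H, Ws, Hs)
    H <- Hn
    if (move < 1e-4) break
  }
  H
}

# Single-rung registration: detect in both frames, match, RANSAC.
register_once <- function(frame, reference, kind, policy) {
  fa <- detect_features(frame, kind, max_keep = policy$max_keep,
                        block_size = policy$block_size)
  fb <- detect_features(reference, kind, max_keep = policy$max_keep,
                        block_size = policy$block_size)
  m <- match_features(fa, fb, ratio = policy$ratio)
  if (nrow(m$src_pts) < 4L) {
    fm_stop("fm_registration_failure",
            "only %d putative matches for pair %s -> %s with '%s'",
            nrow(m$src_pts), m$src_frame, m$dst_frame, kind)
  }
  rr <- ransac_filter(m, reproj_tol = policy$ransac_tol,
                      max_iters = policy$ransac_iters,
                      seed = pair_seed(policy, fa$frame_index,
                                       fb$frame_index))
  Hbest <- rr$homography$H
  if (isTRUE(policy$refine)) {
    Hbest <- refine_homography_photometric(rgb_to_gray(frame),
                                           rgb_to_gray(reference), Hbest)
  }
  list(H = Hbest,
       inlier_ratio = rr$matches$inlier_ratio,
       n_features = nrow(fa$pts), n_features_ref = nrow(fb$pts),
       n_matches = nrow(m$src_pts), n_inliers = rr$homography$n_inliers,
       rms = rr$homography$rms, descriptor = kind)
}

#' Register a frame against a reference with adaptive descriptor escalation
#'
#' Tries the policy's descriptor ladder in order and accepts the first rung
#' whose post-RANSAC inlier ratio reaches the policy threshold. If every
#' rung falls short, the best-ratio result is returned flagged as low
#' confidence; if no rung produces any consensus model, a hard
#' registration-failure error naming the frame pair is raised.
#'
#' @param frame,reference `fm_frame` objects (or image arrays).
#' @param policy A [register_policy()].
#' @param register_fn Optional override with signature
#'   `(frame, reference, kind, policy)` returning the same fields as the
#'   built-in single-rung registration; used to inject precomputed or
#'   simulated registrations.
#' @return An object of class `fm_registration`: `H` (3x3, frame -> reference
#'   coordinates), `descriptor`, `inlier_ratio`, `low_confidence`, feature/
#'   match/inlier counts and `rms`.
#' @export
adaptive_register <- function(frame, reference, policy = register_policy(),
                              register_fn = NULL) {
  stopifnot(inherits(policy, "fm_register_policy"))
  best <- NULL
  errors <- character(0)
  for (kind in policy$ladder) {
    res <- tryCatch(
      if (is.null(register_fn)) register_once(frame, reference, kind, policy)
      else register_fn(frame, reference, kind, policy),
      fm_error = function(e) e)
    if (inherits(res, "fm_error")) {
      errors <- c(errors, sprintf("%s: %s", kind, conditionMessage(res)))
      next
    }
    res$H <- normalize_homography(res$H)
    if (res$inlier_ratio >= policy$inlier_threshold) {
      res$low_confidence <- FALSE
      return(structure(res, class = "fm_registration"))
    }
    if (is.null(best) || res$inlier_ratio > best$inlier_ratio) best <- res
  }
  if (is.null(best)) {
    fm_stop("fm_registration_failure",
            "registration failed at every descriptor rung for pair %s -> %s (%s)",
            if (inherits(frame, "fm_frame")) frame$index else "?",
            if (inherits(reference, "fm_frame")) reference$index else "?",
            paste(errors, collapse = "; "))
  }
  best$low_confidence <- TRUE
  structure(best, class = "fm_registration")
}

#' @export
print.fm_registration <- function(x, ...) {
  cat(sprintf(
    "<fm_registration: '%s', inlier ratio %.2f%s, rms %.3f px, %d inliers>\n",
    x$descriptor, x$inlier_ratio,
    if (isTRUE(x$low_confidence)) " (low confidence)" else "",
    x$rms, x$n_inliers))
  invisible(x)
}
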