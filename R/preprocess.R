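# Preprocessing: application of supplied lens-distortion coefficients
# (Brown-Conrady radial-tangential model) and area-based downsampling.
# Calibration itself is out of scope: coefficients are consumed from a
# config, never estimated.

#' Camera intrinsics and distortion coefficients
#'
#' @param fx,fy Focal lengths in pixels.
#' @param cx,cy Principal point in pixels (0-based pixel centers).
#' @param k1,k2,k3 Radial distortion coefficients.
#' @param p1,p2 Tangential distortion coefficients.
#' @return An object of class `fm_camera`.
#' @export
camera_model <- function(fx, fy, cx, cy, k1 = 0, k2 = 0, k3 = 0,
                         p1 = 0, p2 = 0) {
  if (!(is_scalar_num(fx) && is_scalar_num(fy) && fx > 0 && fy > 0)) {
    fm_stop("fm_invalid_argument", "focal lengths must be positive")
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2),
            class = "fm_camera")
}

#' Read a camera model from a YAML or JSON config block
#'
#' The file (or its `camera:` block) must provide `fx, fy, cx, cy` and may
#' provide `k1, k2, k3, p1, p2`.
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @export
read_camera_model <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$camera)) cfg <- cfg$camera
  do.call(camera_model, cfg[intersect(names(cfg),
    c("fx", "fy", "cx", "cy", "k1", "k2", "k3", "p1", "p2"))])
}

# Forward Brown-Conrady model: ideal (undistorted) normalized coordinates to
# distorted normalized coordinates.
distort_points_norm <- function(cam, xn, yn) {
  r2 <- xn^2 + yn^2
  radial <- 1 + cam$k1 * r2 + cam$k2 * r2^2 + cam$k3 * r2^3
  xd <- xn * radial + 2 * cam$p1 * xn * yn + cam$p2 * (r2 + 2 * xn^2)
  yd <- yn * radial + cam$p1 * (r2 + 2 * yn^2) + 2 * cam$p2 * xn * yn
  list(x = xd, y = yd)
}

#' Undistort a frame
#'
#' Inverts the radial-tangential lens model per pixel: each output pixel is
#' sampled from the input at its distorted location (bilinear). Output
#' dimensions are unchanged; with all coefficients zero the operation is the
#' identity. A `NULL` camera passes the frame through with a warning, since
#' undistortion is optional in the pipeline.
#'
#' @param frame An [new_frame()] object (or bare image array).
#' @param camera An [camera_model()], or `NULL`.
#' @return The undistorted frame.
#' @export
undistort <- function(frame, camera) {
  if (is.null(camera)) {
    fm_warn("no camera model supplied; skipping undistortion")
    return(frame)
  }
  stopifnot(inherits(camera, "fm_camera"))
  img <- as_frame_image(frame)
  H <- nrow(img); W <- ncol(img)
  x <- rep(0:(W - 1L), each = H)
  y <- rep(0:(H - 1L), W)
  xn <- (x - camera$cx) / camera$fx
  yn <- (y - camera$cy) / camera$fy
  d <- distort_points_norm(camera, xn, yn)
  xs <- d$x * camera$fx + camera$cx
  ys <- d$y * camera$fy + camera$cy
  sam <- sample_bilinear(img, xs, ys)
  out <- if (length(dim(img)) == 3L) array(sam, dim(img)) else
    matrix(sam[, 1L], H, W)
  if (inherits(frame, "fm_frame")) {
    new_frame(out, frame$index, frame$timestamp,
              c(frame$meta, list(undistorted = TRUE)))
  } else out
}

#' Apply lens distortion to a frame (simulation)
#'
#' Renders the distorted view of an ideal frame by numerically inverting the
#' Brown-Conrady mapping (fixed-point iteration). Intended for generating
#' synthetic test imagery for [undistort()].
#'
#' @inheritParams undistort
#' @param iterations Fixed-point iterations for the model inversion.
#' @export
distort_frame <- function(frame, camera, iterations = 10L) {
  stopifnot(inherits(camera, "fm_camera"))
  img <- as_frame_image(frame)
  H <- nrow(img); W <- ncol(img)
  x <- rep(0:(W - 1L), each = H)
  y <- rep(0:(H - 1L), W)
  xd <- (x - camera$cx) / camera$fx
  yd <- (y - camera$cy) / camera$fy
  xu <- xd; yu <- yd
  for (it in seq_len(iterations)) {
    d <- distort_points_norm(camera, xu, yu)
    xu <- xu - (d$x - xd)
    yu <- yu - (d$y - yd)
  }
  xs <- xu * camera$fx + camera$cx
  ys <- yu * camera$fy + camera$cy
  sam <- sample_bilinear(img, xs, ys)
  out <- if (length(dim(img)) == 3L) array(sam, dim(img)) else
    matrix(sam[, 1L], H, W)
  if (inherits(frame, "fm_frame")) {
    new_frame(out, frame$index, frame$timestamp,
              c(frame$meta, list(distorted = TRUE)))
  } else out
}

# Sparse 1-D area-resampling operator mapping `n_in` samples to `n_out`
# (n_out <= n_in): output pixel j averages the input interval it covers,
# weighted by overlap. Rows sum to 1.
area_resample_operator <- function(n_in, n_out) {
  s <- n_in / n_out
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (j in seq_len(n_out)) {
    lo <- (j - 1) * s; hi <- j * s
    first <- floor(lo) + 1
    last <- min(ceiling(hi), n_in)
    idx <- first:last
    w <- pmin(hi, idx) - pmax(lo, idx - 1)
    keep <- w > 1e-12
    ii <- c(ii, rep.int(j, sum(keep)))
    jj <- c(jj, idx[keep])
    ww <- c(ww, w[keep] / s)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n_out, n_in))
}

#' Downsample a frame by area averaging
#'
#' Each output pixel is the mean of the input area it covers (box filter),
#' which preserves mean intensity and avoids aliasing for integer factors.
#' If only one of the targets is given, the aspect ratio is preserved.
#' Upsampling requests are rejected.
#'
#' @param frame An `fm_frame` or image array.
#' @param target_width,target_height Output dimensions in pixels.
#' @export
downsample <- function(frame, target_width = NULL, target_height = NULL) {
  img <- as_frame_image(frame)
  H <- nrow(img); W <- ncol(img)
  if (is.null(target_width) && is.null(target_height)) {
    fm_stop("fm_invalid_argument", "a target dimension is required")
  }
  if (is.null(target_width)) {
    target_width <- round(W * target_height / H)
  }
  if (is.null(target_height)) {
    target_height <- round(H * target_width / W)
  }
  target_width <- as.integer(target_width)
  target_height <- as.integer(target_height)
  if (target_width > W || target_height > H) {
    fm_stop("fm_invalid_argument",
            "target %d x %d exceeds source %d x %d (upsampling not supported)",
            target_width, target_height, W, H)
  }
  if (target_width == W && target_height == H) return(frame)
  A <- area_resample_operator(H, target_height)
  B <- Matrix::t(area_resample_operator(W, target_width))
  C <- if (length(dim(img)) == 3L) dim(img)[3L] else 1L
  out <- array(0, c(target_height, target_width, C))
  for (ch in seq_len(C)) {
    plane <- if (length(dim(img)) == 3L) img[, , ch] else img
    out[, , ch] <- as.matrix(A %*% plane %*% B)
  }
  if (C == 1L) out <- out[, , 1L]
  if (inherits(frame, "fm_frame")) {
    new_frame(out, frame$index, frame$timestamp,
              c(frame$meta, list(downsampled_from = c(W, H))))
  } else out
}

#' Preprocess a frame sequence
#'
#' Applies (optionally) undistortion and downsampling to every frame. The
#' default order is undistort-then-downsample, since distortion coefficients
#' are defined for the native sensor geometry; the order is configurable.
#'
#' @param frames List of `fm_frame` objects.
#' @param camera Optional [camera_model()].
#' @param target_width,target_height Optional output dimensions.
#' @param order `"undistort_first"` or `"downsample_first"`.
#' @export
preprocess_frames <- function(frames, camera = NULL, target_width = NULL,
                              target_height = NULL,
                              order = c("undistort_first",
                                        "downsample_first")) {
  order <- match.arg(order)
  do_down <- !is.null(target_width) || !is.null(target_height)
  lapply(frames, function(f) {
    if (order == "undistort_first") {
      if (!is.null(camera)) f <- undistort(f, camera)
      if (do_down) f <- downsample(f, target_width, target_height)
    } else {
      if (do_down) f <- downsample(f, target_width, target_height)
      if (!is.null(camera)) f <- undistort(f, camera)
    }
    f
  })
}
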