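# Planar homographies: 3x3 projective transforms mapping 2-D points between
# coordinate systems. Convention used throughout the package:
#   * points are (x, y) with 0-based pixel centers (pixel [row 1, col 1] of an
#     image is the point (0, 0));
#   * a homography H maps source coordinates to target coordinates as
#     (u, v, w)' = H %*% (x, y, 1)', point = (u/w, v/w);
#   * matrices are normalized so that H[3, 3] == 1.

#' Identity homography
#' @return A 3x3 identity matrix.
#' @export
homography_identity <- function() diag(3)

#' Normalize a homography so its (3,3) element is 1
#'
#' @param H A 3x3 numeric matrix with nonzero (3,3) element.
#' @return The rescaled matrix.
#' @export
normalize_homography <- function(H) {
  stopifnot(is.matrix(H), all(dim(H) == c(3L, 3L)))
  if (!is.finite(H[3L, 3L]) || H[3L, 3L] == 0) {
    fm_stop("fm_degenerate_transform", "homography has zero (3,3) element")
  }
  H / H[3L, 3L]
}

#' Translation homography
#' @param dx,dy Translation in pixels.
#' @export
homography_translation <- function(dx, dy) {
  matrix(c(1, 0, dx, 0, 1, dy, 0, 0, 1), 3L, 3L, byrow = TRUE)
}

#' Similarity homography (rotation + isotropic scale + translation)
#'
#' @param theta Rotation angle in radians (counter-clockwise in x-right,
#'   y-down pixel coordinates).
#' @param scale Isotropic scale factor.
#' @param tx,ty Translation applied after rotation/scaling.
#' @param center Optional (x, y) point about which rotation/scaling pivots.
#' @export
homography_similarity <- function(theta = 0, scale = 1, tx = 0, ty = 0,
                                  center = c(0, 0)) {
  R <- scale * matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)),
                      2L, 2L, byrow = TRUE)
  t_part <- c(tx, ty) + center - R %*% center
  rbind(cbind(R, t_part), c(0, 0, 1))
}

#' Apply a homography to points
#'
#' @param H 3x3 homography.
#' @param pts An n x 2 matrix (or length-2 vector) of (x, y) coordinates.
#' @return An n x 2 matrix of transformed coordinates.
#' @export
apply_homography <- function(H, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  P <- cbind(pts, 1) %*% t(H)
  P[, 1:2, drop = FALSE] / P[, 3L]
}

#' Corner points of a w x h frame
#'
#' Corners are pixel centers of the four extreme pixels, in the order
#' top-left, top-right, bottom-right, bottom-left.
#' @param width,height Frame dimensions in pixels.
#' @export
frame_corners <- function(width, height) {
  matrix(c(0, 0,
           width - 1, 0,
           width - 1, height - 1,
           0, height - 1), ncol = 2L, byrow = TRUE)
}

#' Footprint polygon of a frame under a homography
#' @inheritParams frame_corners
#' @param H Homography mapping frame coordinates into the target system.
#' @return A 4 x 2 matrix of warped corner coordinates.
#' @export
footprint_polygon <- function(H, width, height) {
  apply_homography(H, frame_corners(width, height))
}

#' Signed polygon area (shoelace formula)
#' @param poly An n x 2 matrix of vertices.
#' @return Absolute enclosed area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Sutherland-Hodgman clipping of polygon `subject` by convex polygon `clip`.
# Returns an m x 2 matrix (possibly with 0 rows).
clip_polygon_convex <- function(subject, clip) {
  # orient clip counter-clockwise in the usual math sense of the coordinate
  # values (sign handled below)
  cc <- clip
  x <- cc[, 1L]; y <- cc[, 2L]; n <- nrow(cc)
  j <- c(2:n, 1L)
  signed <- sum(x * y[j] - x[j] * y) / 2
  if (signed < 0) cc <- cc[rev(seq_len(n)), , drop = FALSE]
  out <- subject
  nc <- nrow(cc)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- cc[i, ]; b <- cc[if (i == nc) 1L else i + 1L, ]
    # inside = left of edge a->b
    side <- function(p) (b[1L] - a[1L]) * (p[, 2L] - a[2L]) -
      (b[2L] - a[2L]) * (p[, 1L] - a[1L])
    s <- side(out)
    m <- nrow(out)
    res <- matrix(numeric(0), ncol = 2L)
    for (k in seq_len(m)) {
      p <- out[k, ]; q <- out[if (k == m) 1L else k + 1L, ]
      sp <- s[k]; sq <- s[if (k == m) 1L else k + 1L]
      if (sp >= 0) res <- rbind(res, p)
      if ((sp >= 0) != (sq >= 0)) {
        t <- sp / (sp - sq)
        res <- rbind(res, p + t * (q - p))
      }
    }
    out <- res
  }
  out
}

#' Intersection-over-union of two convex polygons
#'
#' @param a,b Convex polygons as n x 2 vertex matrices.
#' @return IoU in [0, 1].
#' @export
polygon_iou <- function(a, b) {
  inter <- clip_polygon_convex(a, b)
  ai <- if (nrow(inter) >= 3L) polygon_area(inter) else 0
  u <- polygon_area(a) + polygon_area(b) - ai
  if (u <= 0) return(0)
  ai / u
}

# Hartley-normalized direct linear transform. src, dst: n x 2, n >= 4.
# Returns the 3x3 homography mapping src -> dst (least squares for n > 4).
fit_homography <- function(src, dst) {
  n <- nrow(src)
  if (n < 4L || nrow(dst) != n) {
    fm_stop("fm_degenerate_input",
            "homography fit needs >= 4 point correspondences (got %d)", n)
  }
  norm_t <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2L, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    matrix(c(s, 0, -s * ctr[1L], 0, s, -s * ctr[2L], 0, 0, 1),
           3L, 3L, byrow = TRUE)
  }
  Ts <- norm_t(src); Td <- norm_t(dst)
  sn <- apply_homography(Ts, src)
  dn <- apply_homography(Td, dst)
  x <- sn[, 1L]; y <- sn[, 2L]; u <- dn[, 1L]; v <- dn[, 2L]
  zero <- numeric(n); one <- rep(1, n)
  A <- rbind(
    cbind(-x, -y, -one, zero, zero, zero, u * x, u * y, u),
    cbind(zero, zero, zero, -x, -y, -one, v * x, v * y, v)
  )
  h <- svd(A, nu = 0L, nv = 9L)$v[, 9L]
  Hn <- matrix(h, 3L, 3L, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  normalize_homography(H)
}

# TRUE when any three of the points are (nearly) collinear.
points_degenerate <- function(pts, tol = 1e-8) {
  n <- nrow(pts)
  scale2 <- max(apply(pts, 2L, function(z) diff(range(z)))^2, tol)
  idx <- utils::combn(n, 3L)
  for (k in seq_len(ncol(idx))) {
    p <- pts[idx[, k], , drop = FALSE]
    area2 <- abs((p[2L, 1L] - p[1L, 1L]) * (p[3L, 2L] - p[1L, 2L]) -
                 (p[3L, 1L] - p[1L, 1L]) * (p[2L, 2L] - p[1L, 2L]))
    if (area2 < tol * scale2) return(TRUE)
  }
  FALSE
}

# Symmetric transfer distance per correspondence (pixels).
symmetric_transfer_error <- function(H, src, dst) {
  Hi <- solve(H)
  f <- apply_homography(H, src) - dst
  b <- apply_homography(Hi, dst) - src
  sqrt((rowSums(f^2) + rowSums(b^2)) / 2)
}

# Maximum corner reprojection distance between two homographies acting on a
# w x h frame.
corner_error <- function(H_est, H_true, width, height) {
  d <- footprint_polygon(H_est, width, height) -
    footprint_polygon(H_true, width, height)
  max(sqrt(rowSums(d^2)))
}
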