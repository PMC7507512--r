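# Low-level raster helpers. Images are numeric arrays with values in [0, 1],
# dimensions [height, width] (grayscale) or [height, width, channels]. Pixel
# (row r, col c) has coordinates (x, y) = (c - 1, r - 1): 0-based centers.

#' Construct a video frame object
#'
#' @param image Numeric array in [0, 1], `[height, width]` or
#'   `[height, width, 3]`.
#' @param index 1-based frame index within its sequence.
#' @param timestamp Optional acquisition time in seconds.
#' @param meta Optional list of acquisition metadata.
#' @return An object of class `fm_frame`.
#' @export
new_frame <- function(image, index, timestamp = NULL, meta = list()) {
  stopifnot(is.numeric(image), length(dim(image)) %in% c(2L, 3L))
  structure(list(
    image = image,
    index = as.integer(index),
    width = ncol(image),
    height = nrow(image),
    timestamp = timestamp,
    meta = meta
  ), class = "fm_frame")
}

#' @export
print.fm_frame <- function(x, ...) {
  cat(sprintf("<fm_frame #%d: %d x %d px, %s>\n", x$index, x$width, x$height,
              if (length(dim(x$image)) == 3L) "RGB" else "gray"))
  invisible(x)
}

as_frame_image <- function(x) {
  if (inherits(x, "fm_frame")) x$image else x
}

#' Convert an RGB image to grayscale luminance
#'
#' Uses Rec. 601 weights (0.299, 0.587, 0.114). Grayscale input passes
#' through unchanged.
#' @param img Image array.
#' @export
rgb_to_gray <- function(img) {
  img <- as_frame_image(img)
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Bilinear sampling at 0-based coordinates (x, y); points outside the image
# get `fill`. Returns an n x channels matrix.
sample_bilinear <- function(img, x, y, fill = 0) {
  d <- dim(img)
  H <- d[1L]; W <- d[2L]
  C <- if (length(d) == 3L) d[3L] else 1L
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x >= 0 & x <= (W - 1) & y >= 0 & y <= (H - 1)
  x0 <- pmin(pmax(x0, 0), W - 1); y0 <- pmin(pmax(y0, 0), H - 1)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  plane <- H * W
  base00 <- x0 * H + y0 + 1
  base10 <- x1 * H + y0 + 1
  base01 <- x0 * H + y1 + 1
  base11 <- x1 * H + y1 + 1
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy; w11 <- fx * fy
  out <- matrix(fill, length(x), C)
  v <- as.vector(img)
  for (ch in seq_len(C)) {
    off <- (ch - 1L) * plane
    val <- v[base00 + off] * w00 + v[base10 + off] * w10 +
      v[base01 + off] * w01 + v[base11 + off] * w11
    val[!inside] <- fill
    out[, ch] <- val
  }
  out
}

# Normalized 1-D Gaussian kernel sampled at integers, radius = `radius`
# (defaults to the usual int(truncate * sigma + 0.5) with truncate = 3.5,
# giving the classic 11-tap kernel at sigma = 1.5).
gaussian_kernel1d <- function(sigma, radius = NULL) {
  if (is.null(radius)) radius <- as.integer(3.5 * sigma + 0.5)
  x <- (-radius):radius
  k <- exp(-0.5 * (x / sigma)^2)
  k / sum(k)
}

# Separable 'valid' convolution of a 2-D matrix with a symmetric 1-D kernel.
# Output is (H - n + 1) x (W - n + 1).
conv_valid_sep <- function(x, k) {
  n <- length(k)
  H <- nrow(x); W <- ncol(x)
  if (H < n || W < n) {
    fm_stop("fm_invalid_argument",
            "image (%d x %d) smaller than filter window (%d)", H, W, n)
  }
  A <- matrix(0, H - n + 1L, H)
  for (i in seq_len(n)) {
    A[cbind(seq_len(H - n + 1L), seq_len(H - n + 1L) + i - 1L)] <- k[i]
  }
  B <- matrix(0, W, W - n + 1L)
  for (i in seq_len(n)) {
    B[cbind(seq_len(W - n + 1L) + i - 1L, seq_len(W - n + 1L))] <- k[i]
  }
  A %*% x %*% B
}

pad_reflect <- function(x, r) {
  H <- nrow(x); W <- ncol(x)
  ridx <- c(rev(seq_len(min(r, H - 1L)) + 1L), seq_len(H),
            H - seq_len(min(r, H - 1L)))
  cidx <- c(rev(seq_len(min(r, W - 1L)) + 1L), seq_len(W),
            W - seq_len(min(r, W - 1L)))
  x[ridx, cidx, drop = FALSE]
}

# Same-size Gaussian smoothing with reflected borders.
gaussian_smooth <- function(x, sigma, radius = NULL) {
  k <- gaussian_kernel1d(sigma, radius)
  r <- (length(k) - 1L) %/% 2L
  conv_valid_sep(pad_reflect(x, r), k)
}

# Central-difference gradients with replicated borders; returns list(gx, gy).
image_gradients <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  cr <- c(2:W, W); cl <- c(1L, 1:(W - 1L))
  rd <- c(2:H, H); ru <- c(1L, 1:(H - 1L))
  list(
    gx = (gray[, cr, drop = FALSE] - gray[, cl, drop = FALSE]) / 2,
    gy = (gray[rd, , drop = FALSE] - gray[ru, , drop = FALSE]) / 2
  )
}

#' Read an image file (PNG)
#' @param path File path.
#' @return Numeric array in [0, 1] ([H, W] or [H, W, 3]; alpha dropped).
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  if (length(dim(img)) == 3L && dim(img)[3L] == 1L) img <- img[, , 1L]
  img
}

#' Write an image to a PNG file
#' @param img Numeric array in [0, 1].
#' @param path Destination path.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp01(img), target = path)
  invisible(path)
}

#' Read an ordered frame directory
#'
#' PNG files are read in lexicographic order and returned as a list of
#' [new_frame()] objects indexed 1..n.
#' @param dir Directory containing PNG frames.
#' @param stride Keep every `stride`-th frame (temporal subsampling).
#' @param exclude File names to skip (defaults to the ground-truth
#'   orthomosaic that [write_synthetic_dataset()] places next to frames).
#' @export
read_frame_dir <- function(dir, stride = 1L,
                           exclude = "orthomosaic.png") {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  files <- files[!(basename(files) %in% exclude)]
  if (length(files) == 0L) {
    fm_stop("fm_invalid_argument", "no PNG frames found in '%s'", dir)
  }
  files <- files[seq(1L, length(files), by = as.integer(stride))]
  lapply(seq_along(files), function(i) new_frame(read_image(files[i]), i))
}
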