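# Shot detection: segment the frame sequence into temporally contiguous,
# scene-consistent segments by clustering the cumulative-histogram difference
# energies of consecutive frame pairs into a low (within-shot) and a high
# (boundary) cluster.

#' Cumulative-histogram difference energy of a frame pair
#'
#' Per channel, computes a normalized `n_bins`-bin intensity histogram, forms
#' its cumulative distribution, and sums the absolute differences between the
#' two frames' cumulative histograms over bins and channels. The statistic is
#' non-negative, zero for identical frames, symmetric in its arguments, and
#' maximal (`channels * (n_bins - 1)`) for an all-black versus all-white
#' pair.
#'
#' @param frame_a,frame_b Frames of identical dimensions.
#' @param n_bins Histogram bins per channel.
#' @return Non-negative scalar energy.
#' @export
pair_energy <- function(frame_a, frame_b, n_bins = 64L) {
  a <- as_frame_image(frame_a); b <- as_frame_image(frame_b)
  if (!identical(dim(a), dim(b))) {
    fm_stop("fm_invalid_argument", "frames have mismatched dimensions")
  }
  C <- if (length(dim(a)) == 3L) dim(a)[3L] else 1L
  npx <- nrow(a) * ncol(a)
  total <- 0
  for (ch in seq_len(C)) {
    pa <- if (C > 1L) a[, , ch] else a
    pb <- if (C > 1L) b[, , ch] else b
    ha <- tabulate(pmin(floor(pa * n_bins), n_bins - 1L) + 1L, n_bins) / npx
    hb <- tabulate(pmin(floor(pb * n_bins), n_bins - 1L) + 1L, n_bins) / npx
    total <- total + sum(abs(cumsum(ha) - cumsum(hb)))
  }
  total
}

#' Pair energies of a frame sequence
#'
#' @param frames List of frames (n >= 2).
#' @param n_bins Histogram bins per channel.
#' @return Numeric vector of length `n - 1`; element `t` is the energy
#'   between frames `t` and `t + 1`.
#' @export
sequence_energies <- function(frames, n_bins = 64L) {
  n <- length(frames)
  if (n < 2L) return(numeric(0))
  vapply(seq_len(n - 1L), function(t) {
    pair_energy(frames[[t]], frames[[t + 1L]], n_bins)
  }, numeric(1))
}

# Exact 1-D two-means: tries every split of the sorted values and keeps the
# one minimizing within-cluster sum of squares. Deterministic.
two_means_1d <- function(x) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs); css <- cumsum(xs^2)
  best <- list(sse = Inf, k = n)
  for (k in seq_len(n - 1L)) {
    s1 <- cs[k]; s2 <- cs[n] - cs[k]
    q1 <- css[k]; q2 <- css[n] - css[k]
    sse <- (q1 - s1^2 / k) + (q2 - s2^2 / (n - k))
    if (sse < best$sse - 1e-15) best <- list(sse = sse, k = k)
  }
  k <- best$k
  thresh_idx <- ord[seq_len(k)]
  low <- logical(n); low[thresh_idx] <- TRUE
  list(low = low,
       mu_low = mean(x[low]),
       mu_high = if (k < n) mean(x[!low]) else mean(x[low]),
       sd_low = if (k > 1L) stats::sd(x[low]) else 0)
}

#' Detect shots from pair energies
#'
#' Splits the energies into two clusters by an exact 1-D two-means. Pair
#' indices in the high cluster become shot boundaries (the shot ends at the
#' pair's first frame); runs of consecutive boundary pairs are merged. When
#' the between-cluster separation is below `separation_factor` times the
#' standard deviation of the low cluster, the sequence is declared
#' boundary-free and a single shot is returned. Shots shorter than
#' `min_shot_len` frames are merged into the preceding shot (the first into
#' the following one). Boundaries are invariant to rescaling all energies by
#' a positive constant.
#'
#' @param energies Numeric vector from [sequence_energies()] (length
#'   `n_frames - 1`).
#' @param n_frames Number of frames (defaults to `length(energies) + 1`).
#' @param min_shot_len Minimum shot length in frames.
#' @param separation_factor Fallback sensitivity: boundaries require
#'   `mu_high - mu_low > separation_factor * sd_low`. Splitting a unimodal
#'   (boundary-free) energy distribution yields a separation of about 2.7
#'   low-cluster standard deviations, so the default of 4 declares such
#'   sequences boundary-free while real viewpoint jumps (an order of
#'   magnitude above within-shot energies) far exceed it.
#' @param boundary_gain Additional scale-invariant guard: a boundary pair's
#'   energy must exceed `boundary_gain` times the median energy of its
#'   temporal neighbourhood (+/- 5 pairs). Genuine viewpoint jumps are
#'   isolated discontinuities an order of magnitude above the local level,
#'   while smooth within-shot energy bursts elevate their whole
#'   neighbourhood and are rejected.
#' @param z_min Robust outlier threshold: a boundary's energy must lie
#'   `z_min` median absolute deviations above the sequence median.
#' @return A data frame with columns `shot`, `start`, `end`, `base` (the
#'   base frame, equal to `start`); shots partition `[1, n_frames]`.
#' @export
detect_shots <- function(energies, n_frames = length(energies) + 1L,
                         min_shot_len = 5L, separation_factor = 4,
                         boundary_gain = 5, z_min = 10) {
  n_frames <- as.integer(n_frames)
  if (length(energies) < 1L) {
    return(data.frame(shot = 1L, start = 1L, end = n_frames, base = 1L))
  }
  if (any(energies < 0)) {
    fm_stop("fm_invalid_argument", "energies must be non-negative")
  }
  boundaries <- integer(0)
  if (length(unique(energies)) > 1L) {
    cl <- two_means_1d(energies)
    if (cl$mu_high - cl$mu_low > separation_factor * cl$sd_low) {
      ne <- length(energies)
      # a boundary is an isolated discontinuity: its energy must dominate
      # the local energy level (median over a temporal neighbourhood), which
      # rejects smooth within-shot energy bursts, and must be a robust
      # outlier of the whole energy sequence
      local_med <- vapply(seq_len(ne), function(t) {
        w <- max(1L, t - 5L):min(ne, t + 5L)
        stats::median(energies[setdiff(w, t)])
      }, numeric(1))
      z <- (energies - stats::median(energies)) /
        max(stats::mad(energies), .Machine$double.eps)
      high <- which(energies > boundary_gain * pmax(local_med,
                                                    .Machine$double.eps) &
                    z > z_min)
      if (length(high)) {
        # merge runs of consecutive boundary pairs: keep the first of each run
        keep <- c(TRUE, diff(high) > 1L)
        boundaries <- high[keep]
      }
    }
  }
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n_frames)
  # enforce minimum shot length by merging short segments
  i <- 1L
  while (i <= length(starts)) {
    len <- ends[i] - starts[i] + 1L
    if (len >= min_shot_len || length(starts) == 1L) {
      i <- i + 1L
      next
    }
    if (i == 1L) {
      starts <- starts[-1L]
      starts[1L] <- 1L
      ends <- ends[-1L]
    } else {
      ends[i - 1L] <- ends[i]
      starts <- starts[-i]
      ends <- ends[-i]
    }
  }
  data.frame(shot = seq_along(starts), start = starts, end = ends,
             base = starts)
}

#' Write a shots manifest and energy trace
#'
#' Emits `shots.json` (shot index, start, end frame) and `energies.csv`
#' (pair index, energy) for diagnostics.
#' @param shots Data frame from [detect_shots()].
#' @param energies Vector from [sequence_energies()].
#' @param dir Output directory.
#' @export
write_shots_manifest <- function(shots, energies, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(shots, file.path(dir, "shots.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(pair = seq_along(energies), energy = energies),
    file.path(dir, "energies.csv"), row.names = FALSE)
  invisible(dir)
}
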