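# End-to-end pipeline: preprocess -> shot detection -> mini-mosaics ->
# meta-mosaic -> quality report; plus the synthetic-flight driver.

#' Pipeline configuration
#'
#' Defaults reproduce the published decision rules: 5000 strongest
#' keypoints, 40% inlier-ratio acceptance, at most 40 frames per group, and
#' a one-third-of-frame displacement threshold.
#'
#' @param input Frame directory (PNG sequence) or a list of `fm_frame`
#'   objects.
#' @param output_dir Directory for artifacts.
#' @param camera Optional [camera_model()] or path to a YAML/JSON camera
#'   config.
#' @param target_width,target_height Optional downsampling targets.
#' @param stride Frame sampling stride (1 = every frame).
#' @param n_bins Histogram bins per channel for shot detection.
#' @param min_shot_len Minimum shot length in frames.
#' @param ladder,inlier_threshold,ratio,max_keep,block_size Registration
#'   policy settings (see [register_policy()]).
#' @param ransac_tol,ransac_iters RANSAC settings.
#' @param max_group_size,displacement_frac Grouping rules.
#' @param match_threshold Scene-integrity SSIM threshold.
#' @param quality Compute the per-frame quality report.
#' @param seed Master seed for all randomized steps.
#' @export
pipeline_config <- function(input, output_dir,
                            camera = NULL,
                            target_width = NULL, target_height = NULL,
                            stride = 1L, n_bins = 64L, min_shot_len = 5L,
                            ladder = c("st", "fast_local", "affine_robust"),
                            inlier_threshold = 0.4, ratio = 0.75,
                            max_keep = 5000L, block_size = 8L,
                            ransac_tol = 2, ransac_iters = 2000L,
                            max_group_size = 40L, displacement_frac = 1 / 3,
                            match_threshold = 0.5, quality = TRUE,
                            seed = 1L) {
  if (stride < 1L || n_bins < 2L || max_group_size < 1L ||
      displacement_frac <= 0 || ransac_tol <= 0) {
    fm_stop("fm_invalid_argument", "invalid pipeline configuration")
  }
  if (is.character(camera)) camera <- read_camera_model(camera)
  policy <- register_policy(ladder = ladder,
                            inlier_threshold = inlier_threshold,
                            ratio = ratio, max_keep = max_keep,
                            block_size = block_size, ransac_tol = ransac_tol,
                            ransac_iters = ransac_iters, seed = seed)
  structure(list(input = input, output_dir = output_dir, camera = camera,
                 target_width = target_width, target_height = target_height,
                 stride = as.integer(stride), n_bins = as.integer(n_bins),
                 min_shot_len = as.integer(min_shot_len), policy = policy,
                 max_group_size = as.integer(max_group_size),
                 displacement_frac = displacement_frac,
                 match_threshold = match_threshold, quality = quality,
                 seed = seed),
            class = "fm_pipeline_config")
}

#' Run the full mosaicking pipeline
#'
#' Reads and preprocesses the frames, segments them into shots, builds one
#' mini-mosaic per shot, merges the mini-mosaics into a meta-mosaic, and
#' (optionally) computes the quality report. All artifacts are written under
#' `output_dir`: per-shot mosaics with chains and footprints, the
#' meta-mosaic, the shots manifest and energy trace, the registration log,
#' and the quality report. If adjacent mini-mosaics cannot be merged they
#' are still emitted individually and the result is flagged.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `shots`, `minis`, `meta` (or `NULL` when
#'   unmergeable), `quality` (per shot), `timings` (seconds per stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fm_pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  frames <- if (is.character(config$input)) {
    read_frame_dir(config$input, stride = config$stride)
  } else if (config$stride > 1L) {
    config$input[seq(1L, length(config$input), by = config$stride)]
  } else config$input
  if (length(frames) == 0L) {
    fm_stop("fm_invalid_argument", "no input frames")
  }
  frames <- preprocess_frames(frames, camera = config$camera,
                              target_width = config$target_width,
                              target_height = config$target_height)
  timings["preprocess"] <- tic() - t0
  t0 <- tic()
  energies <- sequence_energies(frames, n_bins = config$n_bins)
  shots <- detect_shots(energies, n_frames = length(frames),
                        min_shot_len = config$min_shot_len)
  write_shots_manifest(shots, energies, out)
  timings["shot_detection"] <- tic() - t0
  t0 <- tic()
  mcfg <- mosaic_config(policy = config$policy,
                        max_group_size = config$max_group_size,
                        displacement_frac = config$displacement_frac)
  minis <- vector("list", nrow(shots))
  logs <- list()
  for (s in seq_len(nrow(shots))) {
    shot_frames <- frames[shots$start[s]:shots$end[s]]
    minis[[s]] <- build_mini_mosaic(shot_frames, mcfg)
    write_mosaic(minis[[s]], out, prefix = sprintf("mosaic_shot_%02d", s))
    if (!is.null(minis[[s]]$log)) {
      logs[[length(logs) + 1L]] <- cbind(shot = s, minis[[s]]$log)
    }
  }
  if (length(logs)) {
    utils::write.csv(do.call(rbind, logs),
                     file.path(out, "registration_log.csv"),
                     row.names = FALSE)
  }
  timings["mini_mosaics"] <- tic() - t0
  t0 <- tic()
  meta <- tryCatch(meta_mosaic(minis, policy = config$policy),
                   fm_unmergeable_shots = function(e) {
                     fm_warn("meta-mosaicking skipped: %s",
                             conditionMessage(e))
                     NULL
                   })
  if (!is.null(meta)) write_mosaic(meta, out, prefix = "meta_mosaic")
  timings["meta_mosaic"] <- tic() - t0
  quality <- NULL
  if (isTRUE(config$quality)) {
    t0 <- tic()
    quality <- lapply(seq_len(nrow(shots)), function(s) {
      shot_frames <- frames[shots$start[s]:shots$end[s]]
      mosaic_quality(shot_frames, minis[[s]]$chain,
                     match_threshold = config$match_threshold)
    })
    agg <- list(
      mean_ssim_f = mean(vapply(quality, `[[`, numeric(1), "mean_ssim_f"),
                         na.rm = TRUE),
      mean_ssim_p = mean(unlist(lapply(quality, `[[`, "mean_ssim_p")),
                         na.rm = TRUE),
      scene_integrity = mean(vapply(quality, `[[`, numeric(1),
                                    "scene_integrity")),
      match_threshold = config$match_threshold,
      n_shots = nrow(shots))
    jsonlite::write_json(agg, file.path(out, "quality.json"),
                         auto_unbox = TRUE, digits = NA)
    trace <- do.call(rbind, lapply(seq_along(quality), function(s) {
      cbind(shot = s, quality[[s]]$trace)
    }))
    utils::write.csv(trace, file.path(out, "quality_trace.csv"),
                     row.names = FALSE)
    timings["quality"] <- tic() - t0
  }
  utils::write.csv(data.frame(stage = names(timings),
                              seconds = as.numeric(timings)),
                   file.path(out, "timings.csv"), row.names = FALSE)
  invisible(list(shots = shots, minis = minis, meta = meta,
                 quality = quality, timings = timings))
}

#' Generate a synthetic flight dataset on disk
#'
#' Drives the synthetic-flight simulator from a spec (a
#' [trajectory_spec()], a named list of its arguments, or a YAML/JSON file
#' holding them, plus optional `noise_sd`, `illum_drift`, `texture`
#' arguments) and writes frames, ground truth, and the true orthomosaic.
#' Deterministic for a fixed spec and seed.
#'
#' @param spec Spec object, list, or config-file path.
#' @param output_dir Destination directory.
#' @param seed Master seed.
#' @return Invisibly, the [simulate_flight()] result.
#' @export
run_simulate <- function(spec, output_dir, seed = 1L) {
  extra <- list(noise_sd = 0, illum_drift = 0, texture_args = list())
  if (is.character(spec)) {
    spec <- if (grepl("\\.json$", spec, ignore.case = TRUE)) {
      jsonlite::read_json(spec, simplifyVector = TRUE)
    } else yaml::read_yaml(spec)
  }
  if (!inherits(spec, "fm_trajectory_spec")) {
    if (!is.list(spec)) {
      fm_stop("fm_invalid_argument", "invalid simulation spec")
    }
    extra$noise_sd <- spec$noise_sd %||% 0
    extra$illum_drift <- spec$illum_drift %||% 0
    extra$texture_args <- spec$texture %||% list()
    spec <- do.call(trajectory_spec, spec[intersect(names(spec),
      c("kind", "n_frames", "frame_size", "overlap_target", "jitter",
        "shot_breaks"))])
  }
  flight <- simulate_flight(spec, seed = seed, noise_sd = extra$noise_sd,
                            illum_drift = extra$illum_drift,
                            texture_args = extra$texture_args)
  write_synthetic_dataset(flight, output_dir)
  invisible(flight)
}
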