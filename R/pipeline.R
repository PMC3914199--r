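#' Pipeline configuration
#'
#' Collects every stage's parameters with the package defaults. In phantom
#' mode the input sequence is generated by [render_phantom()] from
#' `phantom` / `vessels`; in frame-directory mode it is read from
#' `frames_dir`.
#'
#' @param input_mode `"phantom"` or `"frames"`.
#' @param frames_dir directory of `phase_*.png`/`.tif` frames (frames mode).
#' @param phantom a [phantom_config()] (phantom mode); `NULL` for defaults.
#' @param vessels list of [vessel_spec()] (phantom mode); `NULL` for a
#'   default arteriole/venule pair pulsating at cardiac points 2 and 6.
#' @param rng_seed global seed; fans out deterministically to the stages.
#' @param align_downsample registration downsampling factor.
#' @param sigma_px Hessian scale (px).
#' @param sigma_spatial_px,sigma_range bilateral filter parameters.
#' @param gabor_scales,gabor_step_deg segmentation feature parameters.
#' @param n_dilations mask cleanup dilations.
#' @param mask_per_frame build the mask per frame instead of once on the
#'   reference frame.
#' @param tracker list of tracker parameters (`radius_px`, `step_px`,
#'   `snap_radius`).
#' @param seeds list of [seed_spec()]; `NULL` derives them from phantom
#'   truth (phantom mode only).
#' @param calibration a [calibration_factor()]; `NULL` derives it from the
#'   optic-disk-to-macula distance in the phantom geometry.
#' @param playback a [playback_spec()].
#' @param write_playback write the playback PNG stack (one loop).
#' @param write_frames write the input frames as 16-bit TIFFs under
#'   `frames/` in the output directory.
#' @param stages character vector of stages to run (in pipeline order);
#'   later stages depend on earlier ones and are skipped if a dependency is
#'   disabled.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_mode = c("phantom", "frames"),
                            frames_dir = NULL,
                            phantom = NULL,
                            vessels = NULL,
                            rng_seed = 1L,
                            align_downsample = 2,
                            sigma_px = 2,
                            sigma_spatial_px = 3,
                            sigma_range = 0.1,
                            gabor_scales = c(2, 3, 4),
                            gabor_step_deg = 10,
                            n_dilations = 5,
                            mask_per_frame = FALSE,
                            tracker = list(radius_px = 4, step_px = 2,
                                           snap_radius = 5),
                            seeds = NULL,
                            calibration = NULL,
                            playback = playback_spec(),
                            write_playback = FALSE,
                            write_frames = FALSE,
                            stages = c("input", "align", "vesselness",
                                       "segmask", "caliper", "trends",
                                       "viz")) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "frames" &&
      (is.null(frames_dir) || !dir.exists(frames_dir))) {
    stop_invalid("`frames_dir` must exist in frames mode")
  }
  if (input_mode == "phantom" && is.null(rng_seed)) {
    stop_invalid("`rng_seed` must be set in phantom mode")
  }
  structure(
    list(input_mode = input_mode, frames_dir = frames_dir, phantom = phantom,
         vessels = vessels, rng_seed = as.integer(rng_seed),
         align_downsample = align_downsample, sigma_px = sigma_px,
         sigma_spatial_px = sigma_spatial_px, sigma_range = sigma_range,
         gabor_scales = gabor_scales, gabor_step_deg = gabor_step_deg,
         n_dilations = n_dilations, mask_per_frame = mask_per_frame,
         tracker = tracker, seeds = seeds, calibration = calibration,
         playback = playback, write_playback = write_playback,
         write_frames = write_frames, stages = stages),
    class = "pipeline_config"
  )
}

default_phantom_vessels <- function(config_shape, n_phases = 8) {
  h <- config_shape[1]
  w <- config_shape[2]
  x0 <- 0.12 * w
  x1 <- 0.88 * w
  list(
    vessel_spec(cbind(seq(x0, x1, length.out = 24),
                      0.32 * h + 14 * sin(seq(0, 2.4, length.out = 24))),
                baseline_width_px = 11.5, amplitude_px = 0.21,
                peak_phase = 2, vessel_class = "arteriole", contrast = 0.45),
    vessel_spec(cbind(seq(x0, x1, length.out = 24),
                      0.68 * h + 16 * sin(seq(0.8, 3.4, length.out = 24))),
                baseline_width_px = 14.2, amplitude_px = 0.42,
                peak_phase = 6, vessel_class = "venule", contrast = 0.55)
  )
}

#' Run the full pulsation pipeline
#'
#' Sequences the stages: phantom generation / frame loading, rigid
#' alignment, per-frame bilateral filtering and vesselness mapping, vessel
#' mask construction and masking, per-vessel edge tracking and caliber
#' measurement across the cardiac points, trend summarization with
#' repeated-measures ANOVA, and zone/playback artifacts. All stage outputs
#' plus a JSON run report (config echo, seed, per-class summaries, file
#' manifest) are written under `outdir`.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return Invisibly, the run report list (also written as
#'   `run_report.json`): `seed`, `trends` (per-vessel per-phase tibble),
#'   `summaries` (per-class [trend_summary()] glances), `transforms`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, outdir = tempfile("rp_run_")) {
  if (!inherits(config, "pipeline_config")) {
    stop_invalid("`config` must be a pipeline_config")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  stage <- function(name) name %in% config$stages
  note <- function(...) message(sprintf(...))

  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            class = "rp_stage_error", parent = e)
    })
    note("stage %-10s %6.1f s", name, proc.time()[["elapsed"]] - t0)
    res
  }

  # --- input ------------------------------------------------------------
  truth <- NULL
  inp <- run_stage("input", {
    if (config$input_mode == "phantom") {
      ph <- config$phantom %||% phantom_config(
        rng_seed = derive_seed(config$rng_seed, 1L),
        motions = random_motions(8, seed = derive_seed(config$rng_seed, 2L)))
      vs <- config$vessels %||% default_phantom_vessels(ph$image_shape,
                                                        ph$n_phases)
      render_phantom(ph, vs)
    } else {
      list(sequence = read_frames(config$frames_dir), truth = NULL)
    }
  })
  seq <- inp$sequence
  truth <- inp$truth
  if (!is.null(truth)) {
    p <- file.path(outdir, "phantom_truth.json")
    write_truth_json(truth, p)
    manifest <- c(manifest, p)
  }
  if (isTRUE(config$write_frames)) {
    paths <- write_frames(seq, file.path(outdir, "frames"))
    manifest <- c(manifest, paths)
  }

  # --- align ------------------------------------------------------------
  transforms <- NULL
  if (stage("align")) {
    al <- run_stage("align", {
      align_sequence(seq, downsample = config$align_downsample)
    })
    seq <- al$sequence
    transforms <- al$transforms
    p <- file.path(outdir, "transforms.csv")
    write_transforms_csv(transforms, p)
    manifest <- c(manifest, p)
  }

  # --- vesselness -------------------------------------------------------
  vmaps <- NULL
  filtered <- NULL
  if (stage("vesselness")) {
    vm <- run_stage("vesselness", {
      filtered <- lapply(seq$frames, function(f) {
        bilateral_filter(as_green_channel(f), config$sigma_spatial_px,
                         config$sigma_range)
      })
      vmaps <- lapply(filtered, function(f) {
        vesselness_map(orientation_map(hessian_field(f, config$sigma_px)))
      })
      list(filtered = filtered, vmaps = vmaps)
    })
    filtered <- vm$filtered
    vmaps <- vm$vmaps
  }

  # --- segmask ----------------------------------------------------------
  masked <- vmaps
  if (stage("segmask") && !is.null(vmaps)) {
    masked <- run_stage("segmask", {
      ref_img <- filtered[[1]]
      labels <- if (!is.null(truth)) {
        truth$vessel_mask
      } else {
        # unsupervised fallback: darkest quantile of the reference frame
        as.integer(ref_img < quantile(ref_img, 0.1)) |>
          matrix(nrow(ref_img), ncol(ref_img))
      }
      feats <- gabor_feature_stack(ref_img, scales = config$gabor_scales,
                                   step_deg = config$gabor_step_deg)
      model <- train_pixel_classifier(feats, labels,
                                      seed = derive_seed(config$rng_seed, 3L))
      p <- file.path(outdir, "classifier.json")
      write_classifier_json(model, p)
      manifest <- c(manifest, p)
      frames_for_mask <- if (config$mask_per_frame) filtered else filtered[1]
      masks <- lapply(frames_for_mask, function(f) {
        build_vessel_mask(f, model, scales = config$gabor_scales,
                          step_deg = config$gabor_step_deg,
                          n_dilations = config$n_dilations)
      })
      lapply(seq_along(vmaps), function(i) {
        m <- if (config$mask_per_frame) masks[[i]] else masks[[1]]
        mask_vesselness(vmaps[[i]], m)
      })
    })
    for (i in seq_along(masked)) {
      p <- file.path(outdir, sprintf("vesselness_%02d.tif", i))
      write_map(masked[[i]], path_tiff = p)
      manifest <- c(manifest, p)
    }
  }

  # --- caliper ----------------------------------------------------------
  trends <- NULL
  cal <- config$calibration
  if (stage("caliper") && !is.null(masked)) {
    trends <- run_stage("caliper", {
      if (is.null(cal)) {
        if (is.null(truth)) {
          stop_invalid("supply `calibration` in frames mode")
        }
        cal <- calibration_factor(
          sqrt(sum((truth$macula_center - truth$od_center)^2)))
      }
      seeds <- config$seeds %||% seeds_from_truth(truth)
      rows <- lapply(seeds, function(s) {
        m <- measure_vessel(masked, s, cal,
                            radius_px = config$tracker$radius_px,
                            step_px = config$tracker$step_px,
                            snap_radius = config$tracker$snap_radius)
        m$subject <- 1L
        m
      })
      dplyr::bind_rows(rows)
    })
    if (is.null(cal)) {
      cal <- calibration_factor(
        sqrt(sum((truth$macula_center - truth$od_center)^2)))
    }
    p <- file.path(outdir, "diameters.csv")
    write_trends_csv(trends, p)
    manifest <- c(manifest, p)
  }

  # --- trends -----------------------------------------------------------
  summaries <- NULL
  if (stage("trends") && !is.null(trends)) {
    summaries <- run_stage("trends", {
      per_class <- split(trends, trends$vessel_class)
      lapply(per_class, function(tr) {
        tr <- dplyr::rename(tr, diameter_um = "mean_um")
        avg <- average_trends(tr, use_dtw = length(unique(tr$vessel_id)) > 1)
        ts <- trend_summary(avg$summary$mean_um, avg$summary$sd_um,
                            subject_matrix = if (nrow(avg$aligned) >= 2) {
                              avg$aligned
                            } else {
                              NULL
                            },
                            n_phases = nrow(avg$summary))
        list(summary = ts, per_point = avg$summary)
      })
    })
    per_point <- dplyr::bind_rows(lapply(names(summaries), function(cl) {
      dplyr::mutate(summaries[[cl]]$per_point, vessel_class = cl)
    }))
    p <- file.path(outdir, "trend_points.csv")
    write.csv(per_point, p, row.names = FALSE)
    manifest <- c(manifest, p)
  }

  # --- viz --------------------------------------------------------------
  if (stage("viz") && !is.null(truth)) {
    run_stage("viz", {
      zm <- make_zone_map(truth$od_center, truth$od_diameter_px,
                          dim(as_green_channel(seq$frames[[1]])))
      if (config$write_playback && !is.null(masked)) {
        q <- quantile(unlist(lapply(masked, max)), 1)
        disp <- frame_sequence(lapply(masked, function(m) {
          clamp01(unclass(m) / max(q, 1e-9))
        }))
        res <- render_playback_frames(disp, file.path(outdir, "playback"),
                                      spec = config$playback, zone_map = zm)
        manifest <- c(manifest, res$paths)
      }
      invisible(zm)
    })
  }

  report <- list(
    seed = config$rng_seed,
    config = config_echo(config),
    summaries = if (!is.null(summaries)) {
      lapply(summaries, function(s) {
        g <- glance(s$summary)
        list(max_min_um = g$max_min_um, peak_point = g$peak_point,
             p_value = g$p.value)
      })
    },
    manifest = manifest
  )
  p <- file.path(outdir, "run_report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(c(report, list(trends = trends, transforms = transforms,
                           outdir = outdir)))
}

config_echo <- function(config) {
  keep <- c("input_mode", "rng_seed", "align_downsample", "sigma_px",
            "sigma_spatial_px", "sigma_range", "gabor_scales",
            "gabor_step_deg", "n_dilations", "mask_per_frame", "stages")
  config[keep]
}

#' Read a pipeline config from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; `phantom`
#' maps onto [phantom_config()] and `vessels` onto a list of
#' [vessel_spec()] entries (each with `centerline` as a list of `(x, y)`
#' pairs).
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (!is.null(y$phantom)) {
    ph <- y$phantom
    if (!is.null(ph$image_shape)) ph$image_shape <- as.integer(ph$image_shape)
    args$phantom <- do.call(phantom_config, ph)
  }
  if (!is.null(y$vessels)) {
    args$vessels <- lapply(y$vessels, function(v) {
      v$centerline <- do.call(rbind, lapply(v$centerline, as.numeric))
      do.call(vessel_spec, v)
    })
  }
  if (!is.null(y$playback)) args$playback <- do.call(playback_spec, y$playback)
  do.call(pipeline_config, args)
}
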