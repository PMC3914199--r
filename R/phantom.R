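#' ECG trigger schedule for gated acquisition
#'
#' The R-R interval is divided into `n_phases` identical subintervals and the
#' camera shutter fires at the start of each, the first trigger coinciding
#' with the R peak. Cardiac point `i` therefore lies at `(i-1)/n_phases` of
#' the R-R interval; a ninth trigger would coincide with the next R peak and
#' is redundant.
#'
#' @param rr_ms R-R interval in milliseconds.
#' @param n_phases number of cardiac points per cycle (default 8).
#' @return An object of class `trigger_schedule`: list with `rr_ms`,
#'   `n_phases` and `offsets_ms` (trigger delays from the R peak, first 0).
#' @examples
#' trigger_schedule(1000)$offsets_ms # 0, 125, ..., 875
#' @export
trigger_schedule <- function(rr_ms, n_phases = 8) {
  check_number(rr_ms, "rr_ms", positive = TRUE)
  check_number(n_phases, "n_phases", positive = TRUE, integer = TRUE)
  structure(
    list(rr_ms = rr_ms, n_phases = as.integer(n_phases),
         offsets_ms = (seq_len(n_phases) - 1) * rr_ms / n_phases),
    class = "trigger_schedule"
  )
}

#' R-R interval stability alarm
#'
#' During gated acquisition the monitor raises an alarm when the observed
#' R-R interval drifts by more than `tolerance` (default 10%) from the
#' baseline recorded at the start, since drifted triggers would land at the
#' wrong cardiac phases. The boundary is exclusive: a change of exactly
#' `tolerance` does not alarm.
#'
#' @param baseline_rr_ms baseline R-R interval (ms), > 0.
#' @param observed_rr_ms currently observed R-R interval (ms), > 0.
#' @param tolerance allowed fractional change (default 0.10).
#' @return `TRUE` if the alarm fires, else `FALSE`.
#' @export
check_rr_stability <- function(baseline_rr_ms, observed_rr_ms,
                               tolerance = 0.10) {
  check_number(baseline_rr_ms, "baseline_rr_ms", positive = TRUE)
  check_number(observed_rr_ms, "observed_rr_ms", positive = TRUE)
  check_number(tolerance, "tolerance", positive = TRUE)
  abs(observed_rr_ms - baseline_rr_ms) / baseline_rr_ms > tolerance
}

#' Specification of one synthetic vessel
#'
#' Describes a dark curvilinear vessel whose full width is modulated over the
#' cardiac cycle by a raised cosine peaking at `peak_phase`:
#' `width(p) = baseline_width_px + amplitude_px * cos(2*pi*(p - peak_phase)/n_phases)`.
#' Peak-to-trough width change is `2 * amplitude_px`.
#'
#' @param centerline n x 2 matrix of (x, y) control points in 0-based pixel
#'   coordinates; consecutive points are joined by straight segments.
#' @param baseline_width_px full vessel width at the waveform midpoint, > 0.
#' @param amplitude_px half the peak-to-trough width modulation, >= 0 and
#'   less than `baseline_width_px / 2`.
#' @param peak_phase 1-based cardiac point of maximum width.
#' @param vessel_class `"arteriole"` or `"venule"`.
#' @param contrast intensity depth of the vessel relative to the local
#'   background, in (0, 1].
#' @return A `vessel_spec` object.
#' @export
vessel_spec <- function(centerline, baseline_width_px, amplitude_px = 0,
                        peak_phase = 1, vessel_class = c("arteriole", "venule"),
                        contrast = 0.5) {
  vessel_class <- match.arg(vessel_class)
  if (!is.matrix(centerline) || ncol(centerline) != 2L ||
      nrow(centerline) < 2L) {
    stop_invalid("`centerline` must be an n x 2 matrix with n >= 2")
  }
  check_number(baseline_width_px, "baseline_width_px", positive = TRUE)
  check_number(amplitude_px, "amplitude_px")
  if (amplitude_px < 0 || amplitude_px >= baseline_width_px / 2) {
    stop_invalid("`amplitude_px` must satisfy 0 <= amplitude_px < baseline_width_px/2")
  }
  check_number(peak_phase, "peak_phase", positive = TRUE, integer = TRUE)
  check_number(contrast, "contrast", positive = TRUE)
  structure(
    list(centerline = centerline, baseline_width_px = baseline_width_px,
         amplitude_px = amplitude_px, peak_phase = as.integer(peak_phase),
         vessel_class = vessel_class, contrast = contrast),
    class = "vessel_spec"
  )
}

#' True vessel width at a cardiac point
#'
#' @param spec a [vessel_spec()].
#' @param phase 1-based cardiac point.
#' @param n_phases number of cardiac points per cycle.
#' @return Full width in pixels.
#' @export
width_at_phase <- function(spec, phase, n_phases = 8) {
  check_number(phase, "phase", positive = TRUE, integer = TRUE)
  check_number(n_phases, "n_phases", positive = TRUE, integer = TRUE)
  if (phase > n_phases) {
    stop_invalid(sprintf("`phase` (%d) out of range 1..%d", phase, n_phases))
  }
  if (spec$peak_phase > n_phases) {
    stop_invalid("`peak_phase` exceeds `n_phases`")
  }
  spec$baseline_width_px +
    spec$amplitude_px * cos(2 * pi * (phase - spec$peak_phase) / n_phases)
}

#' Phantom acquisition configuration
#'
#' Geometry, illumination, motion and noise settings for the synthetic
#' ECG-gated fundus sequence. Defaults emulate the acquisition conditions of
#' an optic-disk-centered crop at about 7.9 um/pixel: a 512 x 1024 frame, an
#' optic disk of 228 px diameter (about 1800 um), and a macula center 569 px
#' temporal to the optic disk center (about 4500 um).
#'
#' @param image_shape `c(rows, cols)` of each frame.
#' @param n_phases cardiac points per cycle (default 8).
#' @param rr_ms R-R interval in ms.
#' @param od_center optic disk center `(x, y)` in 0-based px; default image
#'   center.
#' @param od_diameter_px optic disk diameter in px.
#' @param macula_center macula center `(x, y)`; default 569 px to the right
#'   of the optic disk center.
#' @param illumination list of smooth multiplicative field parameters:
#'   `vignette_strength` (radial falloff at the image corner) and `tilt`
#'   (`c(tx, ty)` linear gradient across the field of view).
#' @param noise_sigma SD of additive Gaussian noise (intensity units).
#' @param motions list of length `n_phases` of per-frame rigid transforms
#'   ([rigid_transform()]), or `NULL` for no motion.
#' @param background_level background intensity before illumination.
#' @param od_brightness added intensity of the optic disk.
#' @param profile_blur_sigma Gaussian blur (px) applied to the rectangular
#'   vessel cross-profile; gives "true width" an exact half-depth meaning.
#' @param rng_seed integer seed controlling noise (and nothing else).
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(image_shape = c(512L, 1024L),
                           n_phases = 8,
                           rr_ms = 820,
                           od_center = NULL,
                           od_diameter_px = 228,
                           macula_center = NULL,
                           illumination = list(vignette_strength = 0.25,
                                               tilt = c(0.06, 0.03)),
                           noise_sigma = 0.01,
                           motions = NULL,
                           background_level = 0.85,
                           od_brightness = 0.12,
                           profile_blur_sigma = 1,
                           rng_seed = 1L) {
  if (length(image_shape) != 2L || any(image_shape <= 0)) {
    stop_invalid("`image_shape` must be two positive integers (rows, cols)")
  }
  check_number(n_phases, "n_phases", positive = TRUE, integer = TRUE)
  check_number(od_diameter_px, "od_diameter_px", positive = TRUE)
  check_number(noise_sigma, "noise_sigma")
  if (noise_sigma < 0) stop_invalid("`noise_sigma` must be >= 0")
  check_number(profile_blur_sigma, "profile_blur_sigma", positive = TRUE)
  if (is.null(od_center)) {
    od_center <- c((image_shape[2] - 1) / 2, (image_shape[1] - 1) / 2)
  }
  if (is.null(macula_center)) macula_center <- od_center + c(569, 0)
  if (is.null(motions)) {
    motions <- replicate(n_phases, rigid_identity(), simplify = FALSE)
  }
  if (length(motions) != n_phases) {
    stop_invalid("`motions` must have one rigid transform per cardiac phase")
  }
  structure(
    list(image_shape = as.integer(image_shape), n_phases = as.integer(n_phases),
         rr_ms = rr_ms, od_center = od_center,
         od_diameter_px = od_diameter_px, macula_center = macula_center,
         illumination = illumination, noise_sigma = noise_sigma,
         motions = motions, background_level = background_level,
         od_brightness = od_brightness,
         profile_blur_sigma = profile_blur_sigma,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_config"
  )
}

#' Random per-frame eye-drift transforms
#'
#' Draws small rigid motions of the magnitude seen as inter-frame eye drift
#' (a few pixels, fractions of a degree) -- comparable with the caliber
#' pulsation itself, which is why registration is required. The first frame
#' (the R peak, the registration reference) gets the identity.
#'
#' @param n_phases number of frames.
#' @param max_shift_px maximum |dx|, |dy| (uniform draw).
#' @param max_rot_deg maximum |rotation| in degrees.
#' @param seed RNG seed.
#' @return List of `n_phases` [rigid_transform()] objects.
#' @export
random_motions <- function(n_phases = 8, max_shift_px = 3, max_rot_deg = 0.5,
                           seed = 1L) {
  set.seed(seed)
  out <- vector("list", n_phases)
  out[[1]] <- rigid_identity()
  for (i in seq_len(n_phases)[-1]) {
    out[[i]] <- rigid_transform(runif(1, -max_shift_px, max_shift_px),
                                runif(1, -max_shift_px, max_shift_px),
                                runif(1, -max_rot_deg, max_rot_deg))
  }
  out
}

# Unsigned distance from every pixel to a polyline, computed only within
# `max_dist` of each segment's bounding box (Inf elsewhere).
polyline_distance_field <- function(centerline, shape, max_dist) {
  h <- shape[1]
  w <- shape[2]
  D <- matrix(Inf, h, w)
  n <- nrow(centerline)
  for (s in seq_len(n - 1)) {
    p <- centerline[s, ]
    q <- centerline[s + 1, ]
    x0 <- max(0, floor(min(p[1], q[1]) - max_dist))
    x1 <- min(w - 1, ceiling(max(p[1], q[1]) + max_dist))
    y0 <- max(0, floor(min(p[2], q[2]) - max_dist))
    y1 <- min(h - 1, ceiling(max(p[2], q[2]) + max_dist))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1
    ys <- y0:y1
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    Y <- matrix(ys, length(ys), length(xs))
    v <- q - p
    len2 <- sum(v^2)
    if (len2 == 0) {
      d <- sqrt((X - p[1])^2 + (Y - p[2])^2)
    } else {
      t <- pmin(pmax(((X - p[1]) * v[1] + (Y - p[2]) * v[2]) / len2, 0), 1)
      d <- sqrt((X - (p[1] + t * v[1]))^2 + (Y - (p[2] + t * v[2]))^2)
    }
    rows <- ys + 1
    cols <- xs + 1
    D[rows, cols] <- pmin(D[rows, cols], d)
  }
  D
}

# Soft tube profile: rectangular cross-section of full width `width`
# convolved with a Gaussian of SD `blur`, expressed through the signed
# distance to the centerline. Peaks at ~1 on the centerline and crosses 1/2
# at the true edge (distance = width/2) for width >> blur.
tube_profile <- function(D, width, blur) {
  P <- matrix(0, nrow(D), ncol(D))
  fin <- is.finite(D)
  d <- D[fin]
  P[fin] <- pnorm((width / 2 - d) / blur) - pnorm((-width / 2 - d) / blur)
  P
}

#' Render a synthetic ECG-gated fundus sequence with ground truth
#'
#' Renders one frame per cardiac point: dark vessels of phase-modulated
#' width (raised-cosine waveform, rectangular cross-profile convolved with a
#' small Gaussian) on a bright background with smooth uneven illumination
#' and a brighter optic disk; each frame is then rigidly moved by its
#' per-frame eye-drift transform and Gaussian noise is added. Identical
#' configs and seeds give bit-identical output.
#'
#' @param config a [phantom_config()].
#' @param specs list of [vessel_spec()] objects.
#' @return List with `sequence` (a `frame_sequence`) and `truth` (a
#'   `phantom_truth`: `widths_px` (vessel x phase matrix), `centerlines`,
#'   `motions`, `od_center`, `od_diameter_px`, `macula_center`,
#'   `vessel_mask` -- the true binary vessel map of the motion-free
#'   reference geometry at phase 1, and `vessel_classes`).
#' @export
render_phantom <- function(config, specs) {
  if (!inherits(config, "phantom_config")) {
    stop_invalid("`config` must be a phantom_config")
  }
  if (length(specs) < 1L) stop_invalid("at least one vessel_spec is required")
  h <- config$image_shape[1]
  w <- config$image_shape[2]
  n_phases <- config$n_phases

  widths <- matrix(NA_real_, length(specs), n_phases)
  dist_fields <- vector("list", length(specs))
  for (v in seq_along(specs)) {
    spec <- specs[[v]]
    cl <- spec$centerline
    if (any(cl[, 1] < 0) || any(cl[, 1] > w - 1) ||
        any(cl[, 2] < 0) || any(cl[, 2] > h - 1)) {
      stop_invalid(sprintf("vessel %d centerline extends outside the image", v))
    }
    widths[v, ] <- vapply(seq_len(n_phases), function(p) {
      width_at_phase(spec, p, n_phases)
    }, numeric(1))
    dist_fields[[v]] <- polyline_distance_field(
      cl, c(h, w), max(widths[v, ]) / 2 + 5 * config$profile_blur_sigma)
  }

  base <- config$background_level * illumination_field(config)
  base <- base + config$od_brightness * od_disk(config)

  set.seed(config$rng_seed)
  frames <- vector("list", n_phases)
  for (p in seq_len(n_phases)) {
    img <- base
    for (v in seq_along(specs)) {
      prof <- tube_profile(dist_fields[[v]], widths[v, p],
                           config$profile_blur_sigma)
      img <- img * (1 - specs[[v]]$contrast * prof)
    }
    mot <- config$motions[[p]]
    if (!is_identity_transform(mot)) {
      img <- apply_rigid(img, mot)
    }
    if (config$noise_sigma > 0) {
      img <- img + matrix(rnorm(h * w, 0, config$noise_sigma), h, w)
    }
    frames[[p]] <- clamp01(img)
  }

  mask <- matrix(0L, h, w)
  for (v in seq_along(specs)) {
    mask[dist_fields[[v]] <= widths[v, 1] / 2] <- 1L
  }

  seq <- frame_sequence(frames, rr_ms = config$rr_ms, channel = "green")
  truth <- structure(
    list(widths_px = widths,
         centerlines = lapply(specs, `[[`, "centerline"),
         motions = config$motions,
         od_center = config$od_center,
         od_diameter_px = config$od_diameter_px,
         macula_center = config$macula_center,
         vessel_mask = mask,
         vessel_classes = vapply(specs, `[[`, character(1), "vessel_class")),
    class = "phantom_truth"
  )
  list(sequence = seq, truth = truth)
}

illumination_field <- function(config) {
  h <- config$image_shape[1]
  w <- config$image_shape[2]
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  X <- matrix(0:(w - 1), h, w, byrow = TRUE)
  Y <- matrix(0:(h - 1), h, w)
  rmax2 <- cx^2 + cy^2
  s <- config$illumination$vignette_strength %||% 0
  tilt <- config$illumination$tilt %||% c(0, 0)
  (1 - s * ((X - cx)^2 + (Y - cy)^2) / rmax2) *
    (1 + tilt[1] * (X - cx) / w + tilt[2] * (Y - cy) / h)
}

od_disk <- function(config) {
  h <- config$image_shape[1]
  w <- config$image_shape[2]
  X <- matrix(0:(w - 1), h, w, byrow = TRUE)
  Y <- matrix(0:(h - 1), h, w)
  r <- sqrt((X - config$od_center[1])^2 + (Y - config$od_center[2])^2)
  # soft rim over ~3 px
  pnorm((config$od_diameter_px / 2 - r) / 3)
}

#' Ordered, phase-stamped frame sequence
#'
#' @param frames list of same-shape numeric matrices with values in `[0, 1]`.
#' @param phase_index 1-based cardiac point of each frame (default
#'   `1..length(frames)`).
#' @param rr_ms R-R interval of the acquisition (ms).
#' @param channel `"green"` or `"gray"`.
#' @return A `frame_sequence` object.
#' @export
frame_sequence <- function(frames, phase_index = seq_along(frames),
                           rr_ms = NA_real_, channel = c("green", "gray")) {
  channel <- match.arg(channel)
  if (!is.list(frames) || length(frames) < 1L) {
    stop_invalid("`frames` must be a non-empty list of matrices")
  }
  dims <- vapply(frames, function(f) dim(as_green_channel(f)), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_invalid("all frames must have the same shape")
  }
  if (length(phase_index) != length(frames)) {
    stop_invalid("`phase_index` must have one entry per frame")
  }
  structure(
    list(frames = frames, phase_index = as.integer(phase_index),
         rr_ms = rr_ms, channel = channel),
    class = "frame_sequence"
  )
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(as_green_channel(x$frames[[1]]))
  cat(sprintf("<frame_sequence> %d frames of %d x %d px (%s channel), R-R %s ms\n",
              length(x$frames), d[1], d[2], x$channel,
              format(x$rr_ms)))
  invisible(x)
}

#' Write a frame sequence to disk
#'
#' One 16-bit grayscale file per cardiac phase, named `phase_01` ...
#' `phase_NN`. TIFF files are written at 16 bits per sample; PNG files at 8
#' bits (preview quality).
#'
#' @param seq a [frame_sequence()].
#' @param dir output directory (created if needed).
#' @param format `"tiff"` (16-bit, default) or `"png"`.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(seq, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(seq$frames))
  for (i in seq_along(seq$frames)) {
    img <- clamp01(as_green_channel(seq$frames[[i]]))
    stem <- sprintf("phase_%02d", seq$phase_index[i])
    if (format == "tiff") {
      paths[i] <- file.path(dir, paste0(stem, ".tif"))
      tiff::writeTIFF(img, paths[i], bits.per.sample = 16)
    } else {
      paths[i] <- file.path(dir, paste0(stem, ".png"))
      png::writePNG(img, paths[i])
    }
  }
  invisible(paths)
}

#' Read an ordered frame sequence from a directory
#'
#' Loads `phase_*.png` / `phase_*.tif(f)` files in phase order. RGB images
#' are reduced to their green channel.
#'
#' @param dir directory containing the frame files.
#' @param rr_ms R-R interval to stamp on the sequence (ms).
#' @return A [frame_sequence()].
#' @export
read_frames <- function(dir, rr_ms = NA_real_) {
  files <- sort(list.files(dir, pattern = "^phase_[0-9]+\\.(png|tif|tiff)$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop_invalid(sprintf("no phase_*.png/tif frames found in %s", dir))
  }
  frames <- lapply(files, function(f) {
    img <- if (grepl("\\.png$", f)) png::readPNG(f) else tiff::readTIFF(f)
    as_green_channel(img)
  })
  phase <- as.integer(sub("^phase_([0-9]+)\\..*$", "\\1", basename(files)))
  frame_sequence(frames, phase_index = phase, rr_ms = rr_ms)
}

#' Write phantom ground truth / trigger schedule as JSON
#' @param x a `phantom_truth` or [trigger_schedule()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(x, path) {
  x <- unclass(x)
  if (!is.null(x$motions)) x$motions <- lapply(x$motions, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
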