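# Shared phantom builders for the tests. Geometry is kept small (the frames
# are a fraction of an OD-centered crop) and vessels run obliquely, as
# retinal vessels around the optic disk do.

`%||%` <- function(a, b) if (is.null(a)) b else a

# One oblique straight vessel; single phase unless n_phases > 1.
line_phantom <- function(width = 12, noise = 0.01, seed = 7, n_phases = 1,
                         amplitude = 0, peak_phase = 1,
                         vessel_class = "arteriole",
                         shape = c(140, 220), angle_slope = 0.17,
                         motions = NULL) {
  cfg <- phantom_config(
    image_shape = shape, n_phases = n_phases,
    od_center = c(24, 24), od_diameter_px = 26,
    macula_center = c(24 + 0.75 * shape[2], 30),
    noise_sigma = noise, rng_seed = seed,
    motions = motions %||% replicate(n_phases, rigid_identity(),
                                     simplify = FALSE)
  )
  ymid <- shape[1] * 0.52
  dx <- shape[2] - 40
  sp <- vessel_spec(
    cbind(c(20, shape[2] - 20),
          c(ymid - angle_slope * dx / 2, ymid + angle_slope * dx / 2)),
    baseline_width_px = width, amplitude_px = amplitude,
    peak_phase = peak_phase, vessel_class = vessel_class
  )
  render_phantom(cfg, list(sp))
}

# Two-vessel phantom with crossing slopes (arteriole peaking at point 2,
# venule at 6); the two orientations pin down both translation components
# during registration, as the radiating vessels of a real fundus do.
pulsating_phantom <- function(noise = 0.01, seed = 5, shape = c(200, 260),
                              art_amp = 0.21, ven_amp = 0.42,
                              motions = NULL, n_phases = 8) {
  cfg <- phantom_config(
    image_shape = shape, n_phases = n_phases,
    od_center = c(30, 30), od_diameter_px = 30,
    macula_center = c(30 + 0.73 * shape[2], 36),
    noise_sigma = noise, rng_seed = seed,
    motions = motions %||% replicate(n_phases, rigid_identity(),
                                     simplify = FALSE)
  )
  specs <- list(
    vessel_spec(cbind(c(25, shape[2] - 25), c(0.30, 0.46) * shape[1]),
                baseline_width_px = 11.5, amplitude_px = art_amp,
                peak_phase = min(2, n_phases), vessel_class = "arteriole",
                contrast = 0.45),
    vessel_spec(cbind(c(25, shape[2] - 25), c(0.78, 0.58) * shape[1]),
                baseline_width_px = 14, amplitude_px = ven_amp,
                peak_phase = min(6, n_phases), vessel_class = "venule",
                contrast = 0.55),
    # steep corner branches: they pin down the along-vessel translation
    # component during registration and do not cross the measured segments
    vessel_spec(cbind(c(0.76, 0.92) * shape[2], c(0.05, 0.22) * shape[1]),
                baseline_width_px = 8, vessel_class = "arteriole",
                contrast = 0.4),
    vessel_spec(cbind(c(0.08, 0.22) * shape[2], c(0.82, 0.97) * shape[1]),
                baseline_width_px = 9, vessel_class = "venule",
                contrast = 0.45)
  )
  render_phantom(cfg, specs)
}

# Frame -> masked vesselness maps via the full vesselness + segmask chain,
# training the pixel classifier on the phantom's ground-truth mask.
masked_vesselness_maps <- function(ph, sigma_px = 2) {
  filtered <- lapply(ph$sequence$frames, bilateral_filter)
  vmaps <- lapply(filtered, function(f) {
    vesselness_map(orientation_map(hessian_field(f, sigma_px)))
  })
  feats <- gabor_feature_stack(filtered[[1]])
  model <- train_pixel_classifier(feats, ph$truth$vessel_mask)
  mask <- clean_mask(classify_pixels(model, feats))
  lapply(vmaps, mask_vesselness, mask = mask)
}

# Render one seeded single-phase phantom of the given width, run the full
# vesselness + segmentation + tracking chain, and return the measured mean
# width in px.
measure_width_run <- function(width, seed, noise = 0.02) {
  ph <- line_phantom(width = width, noise = noise, seed = seed)
  maps <- masked_vesselness_maps(ph)
  seeds <- seeds_from_truth(ph$truth)[[1]]
  measure_vessel(maps, seeds, calibration_factor(569.1))$mean_px
}

# Distance from points to the true edge of a straight vessel defined by
# centerline endpoints p1 -> p2 and full width w (for tracker accuracy
# checks): distance from each point's offset-to-centerline to +/- w/2.
edge_distance_line <- function(pts, p1, p2, w) {
  v <- p2 - p1
  v <- v / sqrt(sum(v^2))
  nrm <- c(-v[2], v[1])
  off <- (pts[, 1] - p1[1]) * nrm[1] + (pts[, 2] - p1[2]) * nrm[2]
  abs(abs(off) - w / 2)
}
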