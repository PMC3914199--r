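#' Micrometer-per-pixel calibration factor
#'
#' Image scale is calibrated from a fixed anatomical length: the distance
#' between the optic disk center and the macula center, assumed to be
#' 4500 um (2.5 average optic-disk diameters). Dividing by the same
#' distance measured in pixels gives um per pixel.
#'
#' @param od_macula_distance_px optic-disk-center to macula-center distance
#'   in pixels, > 0.
#' @param reference_um assumed physical length of that distance (default
#'   4500 um).
#' @return A `calibration_factor`: list with `um_per_px`,
#'   `od_macula_distance_px`, `reference_um`.
#' @examples
#' calibration_factor(569.1)$um_per_px # ~7.9 um/px
#' @export
calibration_factor <- function(od_macula_distance_px, reference_um = 4500) {
  check_number(od_macula_distance_px, "od_macula_distance_px", positive = TRUE)
  check_number(reference_um, "reference_um", positive = TRUE)
  structure(
    list(um_per_px = reference_um / od_macula_distance_px,
         od_macula_distance_px = od_macula_distance_px,
         reference_um = reference_um),
    class = "calibration_factor"
  )
}

#' Seed specification for one vessel segment
#'
#' Mirrors the grader's clicks: one approximate point near each of the two
#' vessel boundaries, plus the start and end points of the segment to be
#' measured. All points are `(x, y)` in 0-based pixel coordinates on the
#' reference frame; the seed is held fixed across cardiac phases.
#'
#' @param edge1,edge2 approximate points on the two vessel boundaries.
#' @param start,end segment endpoints (on/near the vessel).
#' @param vessel_id,vessel_class optional identifiers carried into outputs.
#' @return A `seed_spec` object.
#' @export
seed_spec <- function(edge1, edge2, start, end, vessel_id = 1L,
                      vessel_class = "arteriole") {
  pts <- list(edge1 = edge1, edge2 = edge2, start = start, end = end)
  for (nm in names(pts)) {
    if (length(pts[[nm]]) != 2L || !all(is.finite(pts[[nm]]))) {
      stop_invalid(sprintf("`%s` must be a finite (x, y) point", nm))
    }
  }
  if (all(edge1 == edge2)) stop_invalid("the two boundary seeds must differ")
  if (all(start == end)) stop_invalid("`start` and `end` must differ")
  structure(c(pts, list(vessel_id = vessel_id, vessel_class = vessel_class)),
            class = "seed_spec")
}

# Highest-vesselness pixel within `snap_radius` of `pt`; errors if no ridge
# (response above `ridge_frac` of the map maximum) is nearby.
snap_to_ridge <- function(vmap, pt, snap_radius, ridge_frac = 0.2) {
  h <- nrow(vmap)
  w <- ncol(vmap)
  x0 <- max(0, floor(pt[1] - snap_radius))
  x1 <- min(w - 1, ceiling(pt[1] + snap_radius))
  y0 <- max(0, floor(pt[2] - snap_radius))
  y1 <- min(h - 1, ceiling(pt[2] + snap_radius))
  if (x1 < x0 || y1 < y0) {
    abort("seed lies outside the image", class = "rp_seed_error")
  }
  sub <- vmap[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  thr <- ridge_frac * max(vmap)
  if (max(sub) < thr || max(vmap) == 0) {
    abort(sprintf("no vesselness ridge within %g px of seed (%g, %g)",
                  snap_radius, pt[1], pt[2]),
          class = "rp_seed_error")
  }
  k <- which.max(sub)
  c(x0 + (k - 1) %/% nrow(sub), y0 + (k - 1) %% nrow(sub))
}

# Parabolic sub-pixel refinement of a ridge point across the local normal.
refine_across_normal <- function(vmap, pt, normal) {
  f <- bilinear_sample(vmap, pt[1] + c(-1, 0, 1) * normal[1],
                       pt[2] + c(-1, 0, 1) * normal[2], fill = 0)
  den <- f[1] - 2 * f[2] + f[3]
  if (!is.finite(den) || abs(den) < 1e-12) return(pt)
  d <- 0.5 * (f[1] - f[3]) / den
  d <- max(min(d, 1), -1)
  pt + d * normal
}

#' Track one vessel edge on a masked vesselness map
#'
#' Implements the moving-circle edge tracker: starting from the ridge point
#' nearest the seed, a probing circle of radius `radius_px` is centered on
#' the current point; the direction to the maximal-vesselness point on the
#' circle's forward arc (the back-pointing arc is excluded) is taken, and
#' the track advances `step_px` along it. Tracking stops when within
#' `step_px` of `end` or when the step budget is exhausted (an error).
#' Each tracked point is refined to sub-pixel precision by a 3-point
#' parabolic fit across the local ridge normal, since pulsation amplitudes
#' are sub-pixel at fundus resolutions.
#'
#' @param vmap masked `vesselness_map` (numeric matrix).
#' @param seed approximate `(x, y)` point on the target edge.
#' @param start,end segment endpoints `(x, y)`.
#' @param radius_px probing-circle radius (default 4).
#' @param step_px advance per step (default 2).
#' @param snap_radius maximum seed-to-ridge snap distance (default 5).
#' @param max_steps step budget (default 2000).
#' @param arc_half_deg half-width of the forward arc searched (default 60;
#'   the forward prior keeps the walk from straying onto the speckle ridges
#'   that the orientation gradient produces away from true edges).
#' @param smooth_sigma Gaussian smoothing (px) of the map used for tracking
#'   decisions; attenuates speckle while preserving the continuous edge
#'   ridge position (default 0.8).
#' @param recenter_px after each step the point is re-locked onto the local
#'   ridge maximum within this lateral range (default 2; keep below half
#'   the vessel width so the walk cannot hop onto the opposite edge).
#' @return A `boundary_track`: m x 2 matrix of ordered `(x, y)` edge points.
#' @export
track_edge <- function(vmap, seed, start, end, radius_px = 4, step_px = 2,
                       snap_radius = 5, max_steps = 2000, arc_half_deg = 60,
                       smooth_sigma = 0.8, recenter_px = 2) {
  check_matrix_image(vmap, "vmap")
  check_number(radius_px, "radius_px", positive = TRUE)
  check_number(step_px, "step_px", positive = TRUE)
  vmap <- unclass(vmap)
  sm <- if (smooth_sigma > 0) EBImage::gblur(vmap, sigma = smooth_sigma)
        else vmap

  # the seed disambiguates WHICH of the two parallel edge ridges to track;
  # the walk starts there and proceeds to each endpoint in turn
  p0 <- snap_to_ridge(sm, seed, snap_radius)
  p0 <- as.numeric(p0)

  arc <- seq(-arc_half_deg, arc_half_deg, by = 5) * pi / 180
  walk <- function(from, target) {
    u <- (target - from) / sqrt(sum((target - from)^2))
    goal <- sum((target - from) * u)
    dir <- u
    pts <- matrix(NA_real_, max_steps, 2)
    cur <- from
    n_pts <- 0L
    done <- function(p) {
      # reached: within step_px of the endpoint, or the track has advanced
      # past the endpoint's position along the segment axis (edge ridges
      # run parallel to, not through, the clicked endpoints)
      sqrt(sum((p - target)^2)) <= step_px ||
        sum((p - from) * u) >= goal - step_px
    }
    if (done(cur)) return(pts[0, , drop = FALSE])
    offsets <- seq(-recenter_px, recenter_px, by = 0.25)
    for (s in seq_len(max_steps)) {
      ang <- atan2(dir[2], dir[1]) + arc
      cx <- cur[1] + radius_px * cos(ang)
      cy <- cur[2] + radius_px * sin(ang)
      vals <- bilinear_sample(sm, cx, cy, fill = -Inf)
      k <- which.max(vals)
      new_dir <- c(cos(ang[k]), sin(ang[k]))
      cur <- cur + step_px * new_dir
      # lock back onto the local ridge maximum across the travel direction
      nrm <- c(-new_dir[2], new_dir[1])
      lv <- bilinear_sample(sm, cur[1] + offsets * nrm[1],
                            cur[2] + offsets * nrm[2], fill = -Inf)
      cur <- cur + offsets[which.max(lv)] * nrm
      dir <- new_dir
      n_pts <- n_pts + 1L
      pts[n_pts, ] <- cur
      if (done(cur)) return(pts[seq_len(n_pts), , drop = FALSE])
    }
    abort(sprintf("edge tracking failed to reach (%g, %g) within %d steps",
                  target[1], target[2], max_steps),
          class = "rp_tracking_error")
  }
  back <- walk(p0, start)
  fwd <- walk(p0, end)
  pts <- rbind(back[rev(seq_len(nrow(back))), , drop = FALSE],
               matrix(p0, 1, 2), fwd)

  # sub-pixel refinement across the local normal (on the smoothed map:
  # symmetric smoothing preserves the ridge peak position)
  for (i in seq_len(nrow(pts))) {
    i0 <- max(1, i - 1)
    i1 <- min(nrow(pts), i + 1)
    tang <- pts[i1, ] - pts[i0, ]
    nt <- sqrt(sum(tang^2))
    if (nt < 1e-9) next
    tang <- tang / nt
    pts[i, ] <- refine_across_normal(sm, pts[i, ], c(-tang[2], tang[1]))
  }
  structure(pts, class = c("boundary_track", "matrix"))
}

#' Pair points across two tracked edges by shortest Euclidean distance
#'
#' For each point on `edge1` the nearest point on `edge2` is selected (ties
#' broken toward the lower `edge2` index); one cross-section per `edge1`
#' point. With `mutual = TRUE`, only mutually nearest pairs are kept
#' (robust to skewed segment endpoints).
#'
#' @param edge1,edge2 `boundary_track` matrices (m x 2, n x 2).
#' @param mutual keep only mutual nearest neighbors (default `FALSE`).
#' @return A tibble with `x1, y1, x2, y2, length_px` -- one row per
#'   cross-section.
#' @export
pair_cross_sections <- function(edge1, edge2, mutual = FALSE) {
  e1 <- unclass(edge1)
  e2 <- unclass(edge2)
  if (is.null(dim(e1)) || nrow(e1) < 1L || is.null(dim(e2)) || nrow(e2) < 1L) {
    stop_invalid("both edge tracks must contain at least one point")
  }
  d2 <- outer(e1[, 1], e2[, 1], "-")^2 + outer(e1[, 2], e2[, 2], "-")^2
  j <- apply(d2, 1, which.min)
  if (mutual) {
    i_back <- apply(d2, 2, which.min)
    keep <- i_back[j] == seq_len(nrow(e1))
  } else {
    keep <- rep(TRUE, nrow(e1))
  }
  tibble::tibble(
    x1 = e1[keep, 1], y1 = e1[keep, 2],
    x2 = e2[j[keep], 1], y2 = e2[j[keep], 2],
    length_px = sqrt(d2[cbind(which(keep), j[keep])])
  )
}

#' Mean vessel diameter from a cross-section set
#'
#' The diameter of the segment is the arithmetic mean of the cross-section
#' lengths, reported in pixels and (through the calibration factor)
#' micrometers.
#'
#' @param pairs tibble from [pair_cross_sections()].
#' @param cal a [calibration_factor()].
#' @param phase cardiac point index to stamp on the result.
#' @param vessel_id vessel identifier to stamp on the result.
#' @return One-row tibble: `vessel_id`, `phase`, `mean_px`, `mean_um`,
#'   `n_cross_sections`.
#' @export
segment_diameter <- function(pairs, cal, phase = NA_integer_,
                             vessel_id = NA_integer_) {
  if (!inherits(cal, "calibration_factor")) {
    stop_invalid("`cal` must be a calibration_factor")
  }
  if (nrow(pairs) < 1L) stop_invalid("cross-section set is empty")
  mean_px <- mean(pairs$length_px)
  tibble::tibble(
    vessel_id = vessel_id, phase = as.integer(phase),
    mean_px = mean_px, mean_um = mean_px * cal$um_per_px,
    n_cross_sections = nrow(pairs)
  )
}

#' Measure one vessel across all cardiac phases
#'
#' Runs the edge tracker on each phase's masked vesselness map with the
#' same fixed seed points, pairs cross-sections, and returns the per-phase
#' mean caliber.
#'
#' @param vmaps list of masked vesselness maps, one per cardiac phase.
#' @param seeds a [seed_spec()].
#' @param cal a [calibration_factor()].
#' @param ... tracker parameters passed to [track_edge()].
#' @return Tibble: `vessel_id`, `vessel_class`, `phase`, `mean_px`,
#'   `mean_um`, `n_cross_sections`.
#' @export
measure_vessel <- function(vmaps, seeds, cal, ...) {
  if (!inherits(seeds, "seed_spec")) stop_invalid("`seeds` must be a seed_spec")
  out <- vector("list", length(vmaps))
  for (p in seq_along(vmaps)) {
    t1 <- track_edge(vmaps[[p]], seeds$edge1, seeds$start, seeds$end, ...)
    t2 <- track_edge(vmaps[[p]], seeds$edge2, seeds$start, seeds$end, ...)
    pairs <- pair_cross_sections(t1, t2)
    row <- segment_diameter(pairs, cal, phase = p,
                            vessel_id = seeds$vessel_id)
    row$vessel_class <- seeds$vessel_class
    out[[p]] <- row
  }
  dplyr::relocate(dplyr::bind_rows(out), "vessel_id", "vessel_class")
}

#' Derive seed specs from phantom ground truth
#'
#' Places the two boundary seeds on opposite sides of the vessel midpoint
#' (offset by half the baseline width along the local normal) and the
#' segment endpoints `inset` px in from the centerline ends -- the
#' information a grader would supply by clicking.
#'
#' @param truth `phantom_truth` from [render_phantom()].
#' @param inset distance (px) to pull the endpoints in from the centerline
#'   ends.
#' @return List of [seed_spec()], one per phantom vessel.
#' @export
seeds_from_truth <- function(truth, inset = 12) {
  lapply(seq_along(truth$centerlines), function(v) {
    cl <- truth$centerlines[[v]]
    half <- truth$widths_px[v, 1] / 2
    # arc-length parameterization along the polyline
    seg <- diff(cl)
    len <- sqrt(rowSums(seg^2))
    cum <- c(0, cumsum(len))
    total <- cum[length(cum)]
    point_at <- function(s) {
      s <- min(max(s, 0), total)
      i <- max(which(cum <= s + 1e-9))
      i <- min(i, nrow(seg))
      t <- (s - cum[i]) / len[i]
      list(p = cl[i, ] + t * seg[i, ], tang = seg[i, ] / len[i])
    }
    mid <- point_at(total / 2)
    nrm <- c(-mid$tang[2], mid$tang[1])
    seed_spec(
      edge1 = mid$p + half * nrm,
      edge2 = mid$p - half * nrm,
      start = point_at(inset)$p,
      end = point_at(total - inset)$p,
      vessel_id = v,
      vessel_class = truth$vessel_classes[v]
    )
  })
}

#' Read / write seed specs as JSON
#' @param seeds list of [seed_spec()] objects.
#' @param path JSON path.
#' @return `write_seeds_json` returns `path` invisibly; `read_seeds_json`
#'   returns a list of `seed_spec`.
#' @export
write_seeds_json <- function(seeds, path) {
  jsonlite::write_json(lapply(seeds, unclass), path, digits = NA)
  invisible(path)
}

#' @rdname write_seeds_json
#' @export
read_seeds_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) {
    seed_spec(edge1 = as.numeric(unlist(s$edge1)),
              edge2 = as.numeric(unlist(s$edge2)),
              start = as.numeric(unlist(s$start)),
              end = as.numeric(unlist(s$end)),
              vessel_id = unlist(s$vessel_id) %||% NA_integer_,
              vessel_class = unlist(s$vessel_class) %||% "arteriole")
  })
}
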