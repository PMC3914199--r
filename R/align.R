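#' Rigid (translation + rotation) image transform
#'
#' The transform moves image content by rotating `theta_deg`
#' counterclockwise (in the x-right, y-down pixel frame) about the image
#' center and then translating by `(dx_px, dy_px)`.
#'
#' @param dx_px,dy_px translation in pixels.
#' @param theta_deg rotation in degrees about the image center.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(dx_px = 0, dy_px = 0, theta_deg = 0) {
  check_number(dx_px, "dx_px")
  check_number(dy_px, "dy_px")
  check_number(theta_deg, "theta_deg")
  structure(list(dx_px = dx_px, dy_px = dy_px, theta_deg = theta_deg),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rigid_identity <- function() rigid_transform(0, 0, 0)

#' @rdname rigid_transform
#' @param t a `rigid_transform`.
#' @export
rigid_inverse <- function(t) {
  th <- -t$theta_deg * pi / 180
  rigid_transform(-(cos(th) * t$dx_px - sin(th) * t$dy_px),
                  -(sin(th) * t$dx_px + cos(th) * t$dy_px),
                  -t$theta_deg)
}

is_identity_transform <- function(t, tol = 0) {
  abs(t$dx_px) <= tol && abs(t$dy_px) <= tol && abs(t$theta_deg) <= tol
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dx=%.3f px, dy=%.3f px, theta=%.4f deg\n",
              x$dx_px, x$dy_px, x$theta_deg))
  invisible(x)
}

#' Apply a rigid transform to an image
#'
#' Resamples with bilinear interpolation; pixels pulled from outside the
#' frame are filled with the frame's median intensity (a neutral fundus
#' background value).
#'
#' @param img numeric matrix.
#' @param transform a [rigid_transform()].
#' @param fill fill value for out-of-frame pixels; default `median(img)`.
#' @return Transformed matrix of the same shape.
#' @export
apply_rigid <- function(img, transform, fill = NULL) {
  check_matrix_image(img)
  if (is.null(fill)) fill <- median(img)
  h <- nrow(img)
  w <- ncol(img)
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  th <- -transform$theta_deg * pi / 180 # inverse rotation for pull-resampling
  X <- matrix(0:(w - 1), h, w, byrow = TRUE) - cx - transform$dx_px
  Y <- matrix(0:(h - 1), h, w) - cy - transform$dy_px
  xs <- cos(th) * X - sin(th) * Y + cx
  ys <- sin(th) * X + cos(th) * Y + cy
  matrix(bilinear_sample(img, xs, ys, fill = fill), h, w)
}

# 2-D Hann window, used to suppress wrap-around edges in phase correlation.
hann2 <- function(h, w) {
  wy <- 0.5 - 0.5 * cos(2 * pi * seq(0, h - 1) / (h - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * seq(0, w - 1) / (w - 1))
  outer(wy, wx)
}

# Block-average downsampling by an integer factor (trailing rows/cols that
# do not fill a block are dropped).
downsample_mean <- function(img, factor) {
  if (factor <= 1) return(img)
  h <- (nrow(img) %/% factor) * factor
  w <- (ncol(img) %/% factor) * factor
  img <- img[seq_len(h), seq_len(w)]
  r1 <- colMeans(array(img, c(factor, h %/% factor, w)), dims = 1)
  r2 <- colMeans(array(t(r1), c(factor, w %/% factor, h %/% factor)), dims = 1)
  t(r2)
}

# Phase correlation: returns c(dx, dy, peak) such that moving the content of
# `moving` by (dx, dy) best matches `reference`, with parabolic sub-pixel
# refinement; `peak` is the normalized correlation peak height.
phase_correlate <- function(reference, moving) {
  h <- nrow(reference)
  w <- ncol(reference)
  win <- hann2(h, w)
  A <- fft((reference - mean(reference)) * win)
  B <- fft((moving - mean(moving)) * win)
  R <- A * Conj(B)
  R <- R / pmax(Mod(R), 1e-12)
  r <- Re(fft(R, inverse = TRUE)) / length(R)
  k <- which.max(r)
  iy <- (k - 1) %% h
  ix <- (k - 1) %/% h
  subpix <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (abs(den) < 1e-12) return(0)
    d <- 0.5 * (vm - vp) / den
    max(min(d, 0.5), -0.5)
  }
  ym <- r[(iy - 1) %% h + 1, ix + 1]
  yp <- r[(iy + 1) %% h + 1, ix + 1]
  xm <- r[iy + 1, (ix - 1) %% w + 1]
  xp <- r[iy + 1, (ix + 1) %% w + 1]
  v0 <- r[iy + 1, ix + 1]
  dy <- iy + subpix(ym, v0, yp)
  dx <- ix + subpix(xm, v0, xp)
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  c(dx = dx, dy = dy, peak = v0)
}

#' Estimate the rigid transform aligning one frame to another
#'
#' Translation is recovered by FFT phase correlation with sub-pixel
#' (parabolic) peak interpolation; rotation by a bounded golden-section
#' search that re-correlates the rotated moving frame at candidate angles.
#' Estimation runs on frames downsampled by `downsample` (block averaging);
#' the returned transform is expressed at full resolution, with the
#' translation refined by a final full-resolution correlation.
#'
#' @param reference,moving same-shape single-channel matrices.
#' @param downsample integer downsampling factor for estimation (default 2).
#' @param rotation_range_deg half-width of the rotation search interval
#'   (degrees); 0 disables rotation estimation.
#' @param min_peak minimum acceptable normalized correlation peak; below it
#'   a registration-failure error is raised.
#' @return A [rigid_transform()] such that `apply_rigid(moving, t)` matches
#'   `reference` (i.e. the inverse of the motion that displaced `moving`).
#' @export
estimate_rigid <- function(reference, moving, downsample = 2,
                           rotation_range_deg = 3.5, min_peak = 0.01) {
  check_matrix_image(reference, "reference")
  check_matrix_image(moving, "moving")
  if (!all(dim(reference) == dim(moving))) {
    stop_invalid("`reference` and `moving` must have the same shape")
  }
  ref_ds <- downsample_mean(reference, downsample)
  mov_ds <- downsample_mean(moving, downsample)

  # rotation objective: normalized cross-correlation of the central region
  # after aligning at the candidate angle (smooth and sharply peaked in
  # theta, unlike the raw phase-correlation peak height)
  ncc_at <- function(th) {
    pc <- phase_correlate(ref_ds, if (th != 0) {
      apply_rigid(mov_ds, rigid_transform(0, 0, th))
    } else {
      mov_ds
    })
    warped <- apply_rigid(mov_ds, rigid_transform(pc[["dx"]], pc[["dy"]], th))
    h <- nrow(ref_ds)
    w <- ncol(ref_ds)
    ri <- max(1, round(h * 0.15)):min(h, round(h * 0.85))
    ci <- max(1, round(w * 0.15)):min(w, round(w * 0.85))
    a <- ref_ds[ri, ci]
    b <- warped[ri, ci]
    sa <- sd(a)
    sb <- sd(b)
    if (sa < 1e-12 || sb < 1e-12) return(0)
    mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
  }

  theta <- 0
  if (rotation_range_deg > 0) {
    opt <- optimize(ncc_at, c(-rotation_range_deg, rotation_range_deg),
                    maximum = TRUE, tol = 2e-3)
    # prefer exactly zero when it is effectively as good
    theta <- if (ncc_at(0) >= opt$objective - 1e-7) 0 else opt$maximum
  }

  rot_full <- if (theta != 0) {
    apply_rigid(moving, rigid_transform(0, 0, theta))
  } else {
    moving
  }
  pc <- phase_correlate(reference, rot_full)
  if (pc[["peak"]] < min_peak) {
    abort(sprintf("registration failed: correlation peak %.4f below %.4f",
                  pc[["peak"]], min_peak),
          class = "rp_registration_failure")
  }

  # Nelder-Mead NCC polish: phase correlation whitens the spectrum, which
  # under-weights sparse structure and can bias the translation along a
  # dominant vessel direction; maximizing the central-region NCC over
  # (dx, dy, theta) removes that bias. Coarse polish on the downsampled
  # pair, then a short full-resolution polish.
  ncc_obj <- function(a, b) {
    h <- nrow(a)
    w <- ncol(a)
    ri <- max(1, round(h * 0.15)):min(h, round(h * 0.85))
    ci <- max(1, round(w * 0.15)):min(w, round(w * 0.85))
    function(par) {
      warped <- apply_rigid(b, rigid_transform(par[1], par[2], par[3]))
      x <- a[ri, ci]
      y <- warped[ri, ci]
      if (sd(x) < 1e-12 || sd(y) < 1e-12) return(0)
      -stats::cor(as.vector(x), as.vector(y))
    }
  }
  par <- c(pc[["dx"]], pc[["dy"]], theta)
  o_ds <- stats::optim(c(par[1] / downsample, par[2] / downsample, par[3]),
                       ncc_obj(ref_ds, mov_ds), method = "Nelder-Mead",
                       control = list(maxit = 200, reltol = 1e-10))
  par <- c(o_ds$par[1] * downsample, o_ds$par[2] * downsample, o_ds$par[3])
  if (downsample > 1) {
    o_full <- stats::optim(par, ncc_obj(reference, moving),
                           method = "Nelder-Mead",
                           control = list(maxit = 80, reltol = 1e-10))
    par <- o_full$par
  }
  rigid_transform(par[1], par[2], par[3])
}

#' Align a frame sequence to a reference frame
#'
#' Every frame is registered pairwise to the single reference frame (no
#' sequential chaining, so no drift accumulation) and resampled into its
#' coordinates. RGB frames are reduced to their green channel first.
#'
#' @param seq a [frame_sequence()] with at least 2 frames.
#' @param reference_index 1-based index of the reference frame (default 1,
#'   the R-peak frame).
#' @param ... passed to [estimate_rigid()].
#' @return List with `sequence` (aligned [frame_sequence()]) and
#'   `transforms` (tibble: `frame_index`, `dx_px`, `dy_px`, `theta_deg`).
#' @export
align_sequence <- function(seq, reference_index = 1, ...) {
  if (!inherits(seq, "frame_sequence")) {
    stop_invalid("`seq` must be a frame_sequence")
  }
  n <- length(seq$frames)
  if (n < 2L) stop_invalid("alignment needs at least 2 frames")
  check_number(reference_index, "reference_index", positive = TRUE,
               integer = TRUE)
  if (reference_index > n) stop_invalid("`reference_index` out of range")

  frames <- lapply(seq$frames, as_green_channel)
  ref <- frames[[reference_index]]
  aligned <- vector("list", n)
  tr <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == reference_index) {
      aligned[[i]] <- ref
      tr[[i]] <- rigid_identity()
      next
    }
    t_i <- tryCatch(
      estimate_rigid(ref, frames[[i]], ...),
      rp_registration_failure = function(e) {
        abort(sprintf("registration of frame %d to reference %d failed: %s",
                      i, reference_index, conditionMessage(e)),
              class = "rp_registration_failure")
      }
    )
    aligned[[i]] <- apply_rigid(frames[[i]], t_i)
    tr[[i]] <- t_i
  }
  out <- frame_sequence(aligned, phase_index = seq$phase_index,
                        rr_ms = seq$rr_ms, channel = seq$channel)
  transforms <- tibble::tibble(
    frame_index = seq_len(n),
    dx_px = vapply(tr, `[[`, numeric(1), "dx_px"),
    dy_px = vapply(tr, `[[`, numeric(1), "dy_px"),
    theta_deg = vapply(tr, `[[`, numeric(1), "theta_deg")
  )
  list(sequence = out, transforms = transforms)
}

#' Crop every frame of a sequence to a common window
#'
#' @param seq a [frame_sequence()].
#' @param center window center `(x, y)` in 0-based pixel coordinates.
#' @param size `c(rows, cols)` of the output window.
#' @return The cropped [frame_sequence()].
#' @export
crop_frames <- function(seq, center, size) {
  if (!inherits(seq, "frame_sequence")) {
    stop_invalid("`seq` must be a frame_sequence")
  }
  if (length(size) != 2L || any(size < 1)) {
    stop_invalid("`size` must be positive c(rows, cols)")
  }
  d <- dim(as_green_channel(seq$frames[[1]]))
  r0 <- round(center[2] - (size[1] - 1) / 2)
  c0 <- round(center[1] - (size[2] - 1) / 2)
  if (r0 < 0 || c0 < 0 || r0 + size[1] > d[1] || c0 + size[2] > d[2]) {
    stop_invalid("crop window exceeds frame bounds")
  }
  rows <- (r0 + 1):(r0 + size[1])
  cols <- (c0 + 1):(c0 + size[2])
  frames <- lapply(seq$frames, function(f) as_green_channel(f)[rows, cols])
  frame_sequence(frames, phase_index = seq$phase_index, rr_ms = seq$rr_ms,
                 channel = seq$channel)
}

#' Write estimated transforms as CSV
#' @param transforms tibble from [align_sequence()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_transforms_csv <- function(transforms, path) {
  write.csv(transforms, path, row.names = FALSE)
  invisible(path)
}
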