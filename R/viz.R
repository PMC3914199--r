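#' Concentric-zone map around the optic disk
#'
#' Pixels are labeled by radial distance `r` from the optic disk center
#' with half-open, lower-inclusive annuli each half an OD diameter wide:
#' OD (`r < d/2`), A (`d/2 <= r < d`), B (`d <= r < 3d/2`), C
#' (`3d/2 <= r < 2d`), and beyond (`r >= 2d`). The zones localize graded
#' pulsatile features (e.g. spontaneous venous pulsation within one OD
#' diameter; venous/arteriolar pulsation per zone).
#'
#' @param od_center optic disk center `(x, y)`, 0-based px.
#' @param od_diameter_px optic disk diameter in px, > 0.
#' @param shape `c(rows, cols)` of the image.
#' @return A `zone_map`: integer matrix with levels attribute
#'   `c("OD", "A", "B", "C", "beyond")`, plus `od_center`/`od_diameter_px`
#'   attributes.
#' @export
make_zone_map <- function(od_center, od_diameter_px, shape) {
  check_number(od_diameter_px, "od_diameter_px", positive = TRUE)
  if (length(shape) != 2L || any(shape < 1)) {
    stop_invalid("`shape` must be positive c(rows, cols)")
  }
  h <- shape[1]
  w <- shape[2]
  X <- matrix(0:(w - 1), h, w, byrow = TRUE)
  Y <- matrix(0:(h - 1), h, w)
  r <- sqrt((X - od_center[1])^2 + (Y - od_center[2])^2)
  z <- matrix(zone_of(r, od_diameter_px), h, w)
  structure(z, levels = c("OD", "A", "B", "C", "beyond"),
            od_center = od_center, od_diameter_px = od_diameter_px,
            class = c("zone_map", "matrix"))
}

#' @rdname make_zone_map
#' @param r radial distance(s) from the optic disk center (px).
#' @return `zone_of` returns integer codes 1..5 (OD, A, B, C, beyond).
#' @export
zone_of <- function(r, od_diameter_px) {
  d <- od_diameter_px
  findInterval(r, c(d / 2, d, 3 * d / 2, 2 * d)) + 1L
}

#' Playback timing specification
#'
#' Each of the gated frames is displayed for `frame_duration_ms` and the
#' loop is rendered at `fps` and repeated `loops` times -- the defaults
#' (125 ms, 30 fps, 50 loops) give an approximately one-minute playback of
#' an 8-point cycle (exactly 50 s).
#'
#' @param frame_duration_ms display duration of each source frame.
#' @param fps rendered frame rate.
#' @param loops number of cycle repetitions.
#' @return A `playback_spec` object.
#' @export
playback_spec <- function(frame_duration_ms = 125, fps = 30, loops = 50) {
  check_number(frame_duration_ms, "frame_duration_ms", positive = TRUE)
  check_number(fps, "fps", positive = TRUE)
  check_number(loops, "loops", positive = TRUE, integer = TRUE)
  structure(list(frame_duration_ms = frame_duration_ms, fps = fps,
                 loops = as.integer(loops)),
            class = "playback_spec")
}

#' Assemble the playback frame schedule
#'
#' Source frames are sampled at `1/fps` intervals by nearest source-frame
#' timestamp: per loop, `round(fps * n * frame_duration_ms / 1000)` rendered
#' frames, index `1 + floor(k * n / n_per_loop)`. At 125 ms and 30 fps this
#' yields the 4-4-4-3 repetition pattern (3.75 rendered frames per source
#' frame on average) with an exact long-run rate and no interpolation.
#'
#' @param seq a [frame_sequence()] (or anything with `$frames`).
#' @param spec a [playback_spec()].
#' @return List with `frame_indices` (source index of every rendered
#'   frame), `n_frames` (total rendered), `duration_s` (total playback
#'   seconds), `fps`.
#' @export
assemble_playback <- function(seq, spec = playback_spec()) {
  n <- length(seq$frames)
  if (n < 1L) stop_invalid("`seq` must contain at least one frame")
  if (spec$loops < 1L) stop_invalid("`loops` must be >= 1")
  n_per_loop <- round(spec$fps * n * spec$frame_duration_ms / 1000)
  idx <- 1L + floor((0:(n_per_loop - 1)) * n / n_per_loop)
  list(frame_indices = rep(idx, spec$loops),
       n_frames = n_per_loop * spec$loops,
       duration_s = n * spec$frame_duration_ms * spec$loops / 1000,
       fps = spec$fps)
}

# Zone overlay ring pixels: within half a line width of a zone boundary.
zone_overlay_mask <- function(zone_map, thickness = 1.5) {
  d <- attr(zone_map, "od_diameter_px")
  ctr <- attr(zone_map, "od_center")
  h <- nrow(zone_map)
  w <- ncol(zone_map)
  X <- matrix(0:(w - 1), h, w, byrow = TRUE)
  Y <- matrix(0:(h - 1), h, w)
  r <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2)
  on <- matrix(FALSE, h, w)
  for (b in c(d / 2, d, 3 * d / 2, 2 * d)) {
    on <- on | abs(r - b) <= thickness / 2
  }
  on
}

#' Render playback frames to a PNG stack
#'
#' Writes the scheduled frames as 8-bit PNGs (`frame_000001.png`, ...),
#' optionally with the concentric-zone overlay drawn in color on each
#' frame. A PNG stack keeps codecs out of the processing path; the stack
#' can be muxed to a video externally.
#'
#' @param seq a [frame_sequence()] of display-ready images in `[0, 1]`.
#' @param dir output directory.
#' @param spec a [playback_spec()].
#' @param zone_map optional [make_zone_map()] overlay.
#' @param overlay_color RGB triple in `[0, 1]` for the zone rings.
#' @param max_frames cap on written frames (default one loop's worth;
#'   `Inf` writes the full schedule).
#' @return Invisibly, list with the playback schedule and written paths.
#' @export
render_playback_frames <- function(seq, dir, spec = playback_spec(),
                                   zone_map = NULL,
                                   overlay_color = c(1, 0.85, 0.2),
                                   max_frames = NULL) {
  sched <- assemble_playback(seq, spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_write <- length(sched$frame_indices) / spec$loops
  if (!is.null(max_frames)) n_write <- min(max_frames, sched$n_frames)
  overlay <- if (!is.null(zone_map)) zone_overlay_mask(zone_map) else NULL
  paths <- character(n_write)
  cache <- list()
  for (k in seq_len(n_write)) {
    i <- sched$frame_indices[k]
    key <- as.character(i)
    if (is.null(cache[[key]])) {
      g <- clamp01(as_green_channel(seq$frames[[i]]))
      rgb <- array(g, c(nrow(g), ncol(g), 3))
      if (!is.null(overlay)) {
        for (ch in 1:3) {
          pl <- rgb[, , ch]
          pl[overlay] <- overlay_color[ch]
          rgb[, , ch] <- pl
        }
      }
      cache[[key]] <- rgb
    }
    paths[k] <- file.path(dir, sprintf("frame_%06d.png", k))
    png::writePNG(cache[[key]], paths[k])
  }
  invisible(list(schedule = sched, paths = paths))
}

#' Plot per-class diameter trends over the cardiac cycle
#'
#' @param summaries tibble with columns `vessel_class`, `phase`, `mean_um`,
#'   `sd_um` (e.g. bound from [average_trends()] results).
#' @return A ggplot object (mean +/- SD per cardiac point, one panel per
#'   vessel class).
#' @export
plot_diameter_trends <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$phase, y = .data$mean_um)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_um - .data$sd_um,
                                      ymax = .data$mean_um + .data$sd_um),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~vessel_class, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = seq_len(max(summaries$phase))) +
    ggplot2::labs(x = "cardiac point", y = "mean caliber (um)")
}

#' @rdname trend_summary
#' @param object a `trend_summary`.
#' @export
autoplot.trend_summary <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$mean_um)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = df$phase) +
    ggplot2::labs(x = "cardiac point", y = "mean caliber (um)")
}
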