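# Edge dynamics: ROI definitions, sub-pixel edge detection along ROI center
# lines, section classification by net edge velocity, montage construction,
# and per-section edge-band activity quantification.

#' Rectangular edge ROI
#'
#' A `width x length` rectangle (default 10 x 20 um) whose length axis is the
#' scan axis, oriented outward across the local cell edge.
#'
#' @param id label.
#' @param center (x, y) center in um.
#' @param orient_deg orientation of the outward scan axis, degrees
#'   (0 = +x, counterclockwise).
#' @param width,length um.
#' @param section optional edge-section id this ROI samples.
#' @return a `roi` object.
#' @export
roi_rect <- function(id, center, orient_deg, width = 10, length = 20,
                     section = NA_integer_) {
  structure(list(id = as.character(id), kind = "rectangle",
                 center = as.numeric(center), orient_deg = orient_deg,
                 width = width, length = length,
                 section = as.integer(section)), class = "roi")
}

#' Square trace ROI
#'
#' A square of the given area (default 4 um^2) used for activity-vs-time
#' traces, placed in the cell interior so edge motion cannot interfere.
#'
#' @param id label.
#' @param center (x, y) center in um.
#' @param area_um2 square area in um^2.
#' @return a `roi` object.
#' @export
roi_square <- function(id, center, area_um2 = 4) {
  side <- sqrt(area_um2)
  structure(list(id = as.character(id), kind = "square",
                 center = as.numeric(center), orient_deg = 0,
                 width = side, length = side, section = NA_integer_),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s [%s] center=(%.1f, %.1f) um, %g x %g um, %g deg\n",
              x$id, x$kind, x$center[1], x$center[2], x$width, x$length,
              x$orient_deg))
  invisible(x)
}

#' Write / read ROI tables
#'
#' ROIs travel as a plain CSV: `id, kind, cx_um, cy_um, orient_deg,
#' width_um, length_um, section`.
#'
#' @param rois list of `roi` objects.
#' @param path CSV path.
#' @return `path` / list of `roi`s.
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r) data.frame(
    id = r$id, kind = r$kind, cx_um = r$center[1], cy_um = r$center[2],
    orient_deg = r$orient_deg, width_um = r$width, length_um = r$length,
    section = r$section)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    if (df$kind[i] == "square") {
      roi_square(df$id[i], c(df$cx_um[i], df$cy_um[i]), df$width_um[i]^2)
    } else {
      roi_rect(df$id[i], c(df$cx_um[i], df$cy_um[i]), df$orient_deg[i],
               df$width_um[i], df$length_um[i], df$section[i])
    }
  })
}

# auto-generated ROIs for a scenario config: one outward-oriented rectangle
# per edge section (centered on the section's initial edge midpoint) plus the
# configured square trace ROIs
make_scenario_rois <- function(cfg) {
  rois <- list()
  if (isTRUE(cfg$rois$section_rects)) {
    ns <- cfg$cell$n_sections
    mid <- (seq_len(ns) - 0.5) * 2 * pi / ns
    for (s in seq_len(ns)) {
      ctr <- cfg$cell$center + cfg$cell$radius * c(cos(mid[s]), sin(mid[s]))
      rois[[length(rois) + 1L]] <- roi_rect(
        sprintf("sect%02d", s), ctr, mid[s] * 180 / pi,
        width = cfg$rois$rect_width, length = cfg$rois$rect_length,
        section = s)
    }
  }
  for (sq in cfg$rois$squares %||% list()) {
    rois[[length(rois) + 1L]] <-
      roi_square(sq$id, unlist(sq$center), sq$area_um2 %||% 4)
  }
  rois
}

#' Detect the cell edge along an ROI center line
#'
#' For each frame, scans the intensity used for masking (the corrected donor
#' carried by the ratio movie) along the ROI's central line and takes the
#' outermost above-to-below-threshold crossing as the edge, with linear
#' sub-pixel interpolation between the two bounding samples. Positions are
#' micrometers along the outward scan axis, relative to the ROI center.
#'
#' @param ratio a `ratio_movie` from [compute_ratio()].
#' @param roi a rectangle `roi` (outward orientation known).
#' @param max_missing error if more than this fraction of frames has no edge
#'   crossing on the scan line (default 0.2).
#' @param smooth_frames smoothing window (frames) for the velocity trace.
#' @return object of class `edge_trace`: data frame (`frame`, `time_s`,
#'   `position_um`, `displacement_um`, `velocity_um_s`), plus `roi` and
#'   metadata.
#' @export
detect_edge <- function(ratio, roi, max_missing = 0.2, smooth_frames = 5L) {
  stopifnot(inherits(ratio, "ratio_movie"))
  if (!identical(roi$kind, "rectangle"))
    stop("edge detection needs a rectangle ROI")
  px <- ratio$pixel_size
  d <- dim(ratio$ratio)
  Tn <- d[1]
  u <- c(cos(roi$orient_deg * pi / 180), sin(roi$orient_deg * pi / 180))
  step <- px / 4
  s_grid <- seq(-roi$length / 2, roi$length / 2, by = step)
  pts_x <- (roi$center[1] + s_grid * u[1]) / px
  pts_y <- (roi$center[2] + s_grid * u[2]) / px
  if (all(pts_x < 0 | pts_x > d[3] - 1 | pts_y < 0 | pts_y > d[2] - 1))
    stop("ROI ", roi$id, " does not intersect the image")
  vals <- bilinear_sample_stack(ratio$support, pts_x, pts_y)  # T x n

  pos <- rep(NA_real_, Tn)
  ns <- length(s_grid)
  for (t in seq_len(Tn)) {
    thr <- ratio$thresholds[t]
    if (is.na(thr)) next
    v <- vals[t, ]
    inside <- v >= thr
    # outermost inside->outside transition scanning from the outer end
    trans <- which(inside[-ns] & !inside[-1])
    if (!length(trans)) next
    i <- trans[length(trans)]
    f <- (v[i] - thr) / (v[i] - v[i + 1])
    pos[t] <- s_grid[i] + f * step
  }
  n_missing <- sum(is.na(pos))
  if (n_missing > max_missing * Tn)
    stop(sprintf(
      "no edge crossing on the scan line of ROI %s in %d/%d frames; consider re-placing the ROI",
      roi$id, n_missing, Tn))

  times <- (seq_len(Tn) - 1) * ratio$frame_interval
  sm <- moving_average(pos, smooth_frames, na.rm = TRUE)
  vel <- rep(NA_real_, Tn)
  if (Tn >= 3) {
    vel[2:(Tn - 1)] <- (sm[3:Tn] - sm[1:(Tn - 2)]) / (2 * ratio$frame_interval)
    vel[1] <- vel[2]
    vel[Tn] <- vel[Tn - 1]
  }
  df <- data.frame(frame = seq_len(Tn) - 1L, time_s = times,
                   position_um = pos,
                   displacement_um = pos - pos[which(!is.na(pos))[1]],
                   velocity_um_s = vel)
  structure(list(trace = df, roi = roi, pixel_size = px,
                 frame_interval = ratio$frame_interval),
            class = "edge_trace")
}

#' @export
print.edge_trace <- function(x, ...) {
  cat(sprintf("<edge_trace> ROI %s: %d frames, net displacement %.2f um\n",
              x$roi$id, nrow(x$trace),
              x$trace$displacement_um[nrow(x$trace)]))
  invisible(x)
}

# mean velocity over the trace = net displacement / time span (the mean of
# instantaneous velocities telescopes to the endpoints); endpoints are
# averaged over a few frames to suppress frame-level jitter
edge_mean_velocity <- function(trace, n_end = 5L) {
  df <- trace$trace
  ok <- which(!is.na(df$position_um))
  if (length(ok) < 2) return(NA_real_)
  head_i <- ok[seq_len(min(n_end, length(ok)))]
  tail_i <- ok[seq(max(1L, length(ok) - n_end + 1L), length(ok))]
  dt <- mean(df$time_s[tail_i]) - mean(df$time_s[head_i])
  if (dt <= 0) return(NA_real_)
  (mean(df$position_um[tail_i]) - mean(df$position_um[head_i])) / dt
}

#' Classify edge sections as stalling / protruding / retracting
#'
#' A section's mean edge velocity over its trace decides the label:
#' `|v| <= v0` stalling, `v > v0` protruding, `v < -v0` retracting. Traces
#' spanning less than `min_span_s` seconds are left unclassified.
#'
#' @param traces list of `edge_trace` objects.
#' @param v0 stalling threshold, um/s (default 0.005, about one pixel per
#'   100 s at 0.5 um/px).
#' @param min_span_s minimum trace span (default 60 s).
#' @return data frame: `id`, `section`, `mean_velocity_um_s`, `class`.
#' @export
classify_sections <- function(traces, v0 = 0.005, min_span_s = 60) {
  rows <- lapply(traces, function(tr) {
    df <- tr$trace
    span <- diff(range(df$time_s[!is.na(df$position_um)]))
    v <- edge_mean_velocity(tr)
    cls <- if (!is.finite(span) || span < min_span_s || is.na(v)) {
      "unclassified"
    } else if (v > v0) "protruding" else if (v < -v0) "retracting" else "stalling"
    data.frame(id = tr$roi$id, section = tr$roi$section,
               mean_velocity_um_s = v, class = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean ratio in the edge band of a section ROI
#'
#' Averages defined ratio pixels inside the ROI rectangle that lie within
#' `band_depth` um inward of the detected per-frame edge position along the
#' scan axis. A central strip (`strip_width`) narrower than the full
#' rectangle is used so adjacent sections do not cross-contaminate.
#'
#' @param ratio a `ratio_movie`.
#' @param trace the section's `edge_trace`.
#' @param band_depth band depth inward from the edge, um (default 5).
#' @param strip_width width of the central measurement strip, um
#'   (default 6).
#' @return list: `mean` (movie-wide mean of per-frame band means),
#'   `per_frame` vector.
#' @export
section_mean_ratio <- function(ratio, trace, band_depth = 5, strip_width = 6) {
  roi <- trace$roi
  px <- ratio$pixel_size
  d <- dim(ratio$ratio)
  u <- c(cos(roi$orient_deg * pi / 180), sin(roi$orient_deg * pi / 180))
  nvec <- c(-u[2], u[1])
  # candidate pixels: bounding box of the rectangle
  g <- coord_grids(d[2], d[3], px)
  relx <- g$X - roi$center[1]
  rely <- g$Y - roi$center[2]
  s_coord <- relx * u[1] + rely * u[2]
  p_coord <- relx * nvec[1] + rely * nvec[2]
  in_rect <- abs(s_coord) <= roi$length / 2 & abs(p_coord) <= strip_width / 2
  idx <- which(in_rect)
  s_in <- s_coord[idx]
  V <- gather_pixels(ratio$ratio, idx)              # T x n
  e <- trace$trace$position_um                       # T
  S <- matrix(s_in, nrow = d[1], ncol = length(idx), byrow = TRUE)
  inband <- S >= (e - band_depth) & S <= e           # recycles e per column
  V[!inband | is.na(inband)] <- NA
  counts <- rowSums(!is.na(V))
  per_frame <- rowMeans(V, na.rm = TRUE)
  per_frame[counts < 10] <- NA
  list(mean = mean(per_frame, na.rm = TRUE), per_frame = per_frame)
}

#' Build a montage of ROI crops over time
#'
#' Crops the ROI from the ratio movie at `t = 0, interval, 2*interval, ...`
#' and tiles the crops left-to-right on a shared intensity scale (no per-tile
#' rescaling). Undefined pixels stay NA and are rendered in a reserved color
#' by [plot_montage()].
#'
#' @param ratio a `ratio_movie`.
#' @param roi an `roi` (rectangle or square); the crop is the ROI's axis-
#'   aligned bounding box.
#' @param interval_s sampling interval, a multiple of the frame interval.
#' @return object of class `fret_montage`: `image` (H x (W*ntiles) matrix),
#'   `tiles` (list of crops), `times_s`, `range`.
#' @export
build_montage <- function(ratio, roi, interval_s = 60) {
  stopifnot(inherits(ratio, "ratio_movie"))
  dt <- ratio$frame_interval
  if (abs(interval_s / dt - round(interval_s / dt)) > 1e-9)
    stop("montage interval must be a multiple of the frame interval")
  d <- dim(ratio$ratio)
  px <- ratio$pixel_size
  total_s <- (d[1] - 1) * dt
  times <- seq(0, total_s, by = interval_s)
  frames <- as.integer(round(times / dt)) + 1L
  half_w <- max(roi$width, roi$length) / 2
  cx <- round(roi$center[1] / px); cy <- round(roi$center[2] / px)
  hw <- ceiling(half_w / px)
  rows <- clamp((cy - hw):(cy + hw), 0, d[2] - 1) + 1
  cols <- clamp((cx - hw):(cx + hw), 0, d[3] - 1) + 1
  rows <- unique(rows); cols <- unique(cols)
  tiles <- lapply(frames, function(f) ratio$ratio[f, rows, cols])
  img <- do.call(cbind, tiles)
  structure(list(image = img, tiles = tiles, times_s = times,
                 range = range(img, na.rm = TRUE),
                 pixel_size = px, roi_id = roi$id),
            class = "fret_montage")
}

#' Plot a montage to a PNG file
#'
#' @param montage a `fret_montage`.
#' @param path output PNG path.
#' @param na_color reserved color for undefined pixels.
#' @return `path`, invisibly.
#' @export
plot_montage <- function(montage, path, na_color = "gray20") {
  grDevices::png(path, width = 160 * length(montage$tiles), height = 400)
  on.exit(grDevices::dev.off())
  img <- montage$image
  graphics::par(mar = c(2, 2, 2, 1), bg = na_color)
  graphics::image(t(img)[, nrow(img):1, drop = FALSE],
                  col = grDevices::hcl.colors(64, "viridis"),
                  zlim = montage$range, axes = FALSE,
                  main = sprintf("ROI %s, every %g s", montage$roi_id,
                                 diff(montage$times_s[1:2])))
  invisible(path)
}
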