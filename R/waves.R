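# Activity traces and wave analytics: ROI mean-ratio traces, dF/F0
# normalization, smoothed-prominence maxima detection, maxima-interval
# period estimation, onset latency, and class-wise ratio summaries.

#' Mean-ratio activity trace of an ROI
#'
#' `F(t)` is the mean of defined ratio pixels inside the ROI per frame;
#' frames with fewer than `min_pixels` defined pixels are flagged missing.
#' Warns when the ROI touches undefined territory on more than 5% of frames
#' (edge interference): trace ROIs are meant to sit inside the mask so no
#' edge movement can interfere.
#'
#' @param ratio a `ratio_movie`.
#' @param roi an `roi` (typically a 4 um^2 square from [roi_square()]).
#' @param min_pixels minimum defined pixels per frame (default 10).
#' @return object of class `activity_trace`: data frame `trace`
#'   (`frame`, `time_s`, `F`), `roi`, metadata.
#' @export
roi_trace <- function(ratio, roi, min_pixels = 10L) {
  stopifnot(inherits(ratio, "ratio_movie"))
  px <- ratio$pixel_size
  d <- dim(ratio$ratio)
  half_w <- roi$width / 2
  half_l <- roi$length / 2
  u <- c(cos(roi$orient_deg * pi / 180), sin(roi$orient_deg * pi / 180))
  g <- coord_grids(d[2], d[3], px)
  relx <- g$X - roi$center[1]
  rely <- g$Y - roi$center[2]
  s_coord <- relx * u[1] + rely * u[2]
  p_coord <- -relx * u[2] + rely * u[1]
  idx <- which(abs(s_coord) <= half_l & abs(p_coord) <= half_w)
  if (!length(idx)) stop("ROI ", roi$id, " lies outside the image")
  Tn <- d[1]
  D <- gather_pixels(ratio$defined, idx) > 0         # T x n
  V <- gather_pixels(ratio$ratio, idx)
  V[!D] <- NA
  ndef <- rowSums(D)
  Fv <- rowMeans(V, na.rm = TRUE)
  Fv[ndef < min_pixels] <- NA
  interfered <- sum(ndef < length(idx))
  if (!any(ndef > 0)) stop("ROI ", roi$id, " lies fully outside the mask")
  if (interfered > 0.05 * Tn)
    warning(sprintf(
      "ROI %s touches undefined pixels in %d/%d frames: possible edge interference",
      roi$id, interfered, Tn))
  times <- (seq_len(Tn) - 1) * ratio$frame_interval
  structure(list(trace = data.frame(frame = seq_len(Tn) - 1L, time_s = times,
                                    F = Fv),
                 roi = roi, frame_interval = ratio$frame_interval),
            class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("<activity_trace> ROI %s: %d frames, F in [%.3f, %.3f]\n",
              x$roi$id, nrow(x$trace), min(x$trace$F, na.rm = TRUE),
              max(x$trace$F, na.rm = TRUE)))
  invisible(x)
}

#' Normalize a trace as dF/F0
#'
#' `dF/F0(t) = (F(t) - F0) / F0` with `F0` the mean of the first `m` frames
#' (default `m = 1`: the intensity at the first frame).
#'
#' @param trace an `activity_trace` (or numeric vector).
#' @param m number of initial frames averaged into `F0`.
#' @return numeric vector of the same length as the trace.
#' @export
delta_f_over_f <- function(trace, m = 1L) {
  Fv <- if (inherits(trace, "activity_trace")) trace$trace$F else as.numeric(trace)
  m <- as.integer(m)
  stopifnot(m >= 1, m <= length(Fv))
  F0 <- mean(Fv[seq_len(m)], na.rm = TRUE)
  if (!is.finite(F0) || F0 <= 0) stop("F0 must be positive")
  (Fv - F0) / F0
}

# split a series into contiguous segments at NA gaps longer than max_gap
# samples; shorter gaps are linearly interpolated
segment_series <- function(x, times, max_gap = 3L) {
  n <- length(x)
  isna <- is.na(x)
  if (!any(isna)) return(list(list(x = x, times = times, offset = 0L)))
  filled <- x
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long_gap <- logical(n)
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    a <- starts[i]; b <- ends[i]
    if (r$lengths[i] <= max_gap && a > 1 && b < n) {
      filled[a:b] <- x[a - 1] + (x[b + 1] - x[a - 1]) *
        (seq_len(r$lengths[i])) / (r$lengths[i] + 1)
    } else long_gap[a:b] <- TRUE
  }
  segs <- list()
  r2 <- rle(!long_gap)
  e2 <- cumsum(r2$lengths)
  s2 <- e2 - r2$lengths + 1L
  for (i in seq_along(r2$lengths)) {
    if (!r2$values[i]) next
    segs[[length(segs) + 1L]] <-
      list(x = filled[s2[i]:e2[i]], times = times[s2[i]:e2[i]],
           offset = s2[i] - 1L)
  }
  segs
}

# peak prominence: height above the higher of the two valley minima between
# the peak and the nearest higher peaks (or series ends)
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) min(x[(max(higher_l) + 1):(p - 1)])
    else min(left, h)
    right <- x[seq(p + 1, length(x))]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) min(x[(p + 1):(p + min(higher_r) - 1)])
    else min(right, h)
    h - max(lmin, rmin)
  }, 0)
}

#' Detect local maxima of a (smoothed) activity series
#'
#' Smooths the series with a centered moving average of `smoothing_window`
#' seconds and keeps local maxima whose prominence is at least
#' `min_prominence` standard deviations of the smoothed series. Times are
#' reported on the original sampling grid. NA gaps up to 3 s are linearly
#' interpolated; longer gaps split the series and maxima are detected per
#' segment.
#'
#' @param series numeric series (e.g. dF/F0).
#' @param times sampling times in seconds (default `0, dt, ...`).
#' @param dt sampling interval, used when `times` is NULL.
#' @param smoothing_window smoothing window, seconds (default 5).
#' @param min_prominence prominence threshold in units of the series SD
#'   (default 0.5).
#' @return numeric vector of maxima times (possibly empty).
#' @export
detect_maxima <- function(series, times = NULL, dt = 1,
                          smoothing_window = 5, min_prominence = 0.5) {
  if (length(series) < 3) stop("series needs >= 3 points")
  if (is.null(times)) times <- (seq_along(series) - 1) * dt
  dt <- times[2] - times[1]
  out <- numeric(0)
  for (seg in segment_series(series, times, max_gap = max(1L, round(3 / dt)))) {
    x <- moving_average(seg$x, round(smoothing_window / dt))
    n <- length(x)
    if (n < 3) next
    sdx <- stats::sd(x)
    if (!is.finite(sdx) || sdx == 0) next
    cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
    if (!length(cand)) next
    prom <- peak_prominences(x, cand)
    keep <- cand[prom >= min_prominence * sdx]
    out <- c(out, seg$times[keep])
  }
  sort(out)
}

#' Estimate the wave period from maxima times
#'
#' Intervals are successive differences of the maxima times; the period is
#' their arithmetic mean with the SEM computed over intervals. With
#' `n_intervals` set (e.g. 10, pooling ten consecutive periods), only the
#' first `n_intervals` intervals enter the estimate.
#'
#' @param maxima_times sorted maxima times, seconds.
#' @param n_intervals optional cap on the number of leading intervals used.
#' @return object of class `wave_estimate`: `maxima_times`, `intervals_s`,
#'   `period_s`, `sem_s`, `n_intervals`.
#' @export
estimate_period <- function(maxima_times, n_intervals = NULL) {
  if (length(maxima_times) < 2)
    stop("insufficient oscillations: need >= 2 maxima")
  iv <- diff(sort(maxima_times))
  if (!is.null(n_intervals)) iv <- iv[seq_len(min(n_intervals, length(iv)))]
  structure(list(maxima_times = sort(maxima_times), intervals_s = iv,
                 period_s = mean(iv),
                 sem_s = if (length(iv) > 1) stats::sd(iv) / sqrt(length(iv)) else 0,
                 n_intervals = length(iv)),
            class = "wave_estimate")
}

#' @export
print.wave_estimate <- function(x, ...) {
  cat(sprintf("<wave_estimate> period %.1f +/- %.1f s (SEM over %d intervals)\n",
              x$period_s, x$sem_s, x$n_intervals))
  invisible(x)
}

#' Detect activation onset after a stimulus
#'
#' Onset is the first post-stimulus time at which the series exceeds
#' (baseline mean + k * baseline SD) for at least `sustain_s` consecutive
#' seconds, with the baseline taken from the pre-stimulus record (at least
#' `min_baseline_s` seconds required).
#'
#' @param series numeric series (e.g. dF/F0).
#' @param times sampling times, seconds.
#' @param stimulus_time stimulus time, seconds (must lie inside the record).
#' @param k threshold in baseline SD multiples (default 3).
#' @param sustain_s required supra-threshold duration (default 5 s).
#' @param min_baseline_s minimum pre-stimulus baseline (default 30 s).
#' @return list: `onset_time_s`, `latency_s` (NA when never exceeded),
#'   `threshold`.
#' @export
detect_onset <- function(series, times, stimulus_time, k = 3, sustain_s = 5,
                         min_baseline_s = 30) {
  if (stimulus_time < min(times) || stimulus_time > max(times))
    stop("stimulus_time lies outside the record")
  pre <- times < stimulus_time
  if (diff(range(times[pre])) < min_baseline_s)
    stop("need at least ", min_baseline_s, " s of pre-stimulus baseline")
  base <- series[pre]
  mu <- mean(base, na.rm = TRUE)
  sdv <- stats::sd(base, na.rm = TRUE)
  thr <- mu + k * sdv
  dt <- times[2] - times[1]
  need <- max(1L, round(sustain_s / dt))
  post_idx <- which(times >= stimulus_time)
  above <- series[post_idx] > thr
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit))
    return(list(onset_time_s = NA_real_, latency_s = NA_real_, threshold = thr))
  onset <- times[post_idx[starts[hit[1]]]]
  list(onset_time_s = onset, latency_s = onset - stimulus_time, threshold = thr)
}

#' Class-wise normalized ratio summary
#'
#' Given per-section mean ratios and their stalling/protruding/retracting
#' labels, computes the per-class mean over section means, normalized by the
#' stalling-class mean (so the stalling mean is 1 by construction), with the
#' SEM over sections as dispersion.
#'
#' @param section_means numeric vector of per-section mean ratios.
#' @param labels character vector of section classes (same length).
#' @return object of class `class_ratio_summary`: data frame with `class`,
#'   `mean_ratio`, `normalized_mean`, `sem_normalized`, `n_sections`.
#' @export
summarize_classes <- function(section_means, labels) {
  stopifnot(length(section_means) == length(labels))
  keep <- labels %in% c("stalling", "protruding", "retracting") &
    is.finite(section_means)
  section_means <- section_means[keep]
  labels <- labels[keep]
  if (!any(labels == "stalling"))
    stop("no stalling section: stalling-normalization undefined")
  stall_mean <- mean(section_means[labels == "stalling"])
  classes <- intersect(c("stalling", "protruding", "retracting"),
                       unique(labels))
  df <- do.call(rbind, lapply(classes, function(cl) {
    v <- section_means[labels == cl]
    data.frame(class = cl, mean_ratio = mean(v),
               normalized_mean = mean(v) / stall_mean,
               sem_normalized = if (length(v) > 1)
                 stats::sd(v / stall_mean) / sqrt(length(v)) else 0,
               n_sections = length(v), stringsAsFactors = FALSE)
  }))
  structure(df, class = c("class_ratio_summary", "data.frame"))
}
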