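# Ratiometric correction chain: shading -> background -> (optional)
# photobleach -> bleedthrough -> masking -> ratio. The order is fixed and
# recorded in provenance; shading and background do not commute.

#' Otsu threshold of an intensity sample
#'
#' Between-class-variance maximizing threshold on a 256-bin histogram
#' (parameter-free; appropriate for the high-SNR donor channel used for
#' masking).
#'
#' @param v numeric vector of intensities.
#' @param nbins histogram bins.
#' @return threshold value, or `NA` for (near-)constant input.
#' @export
otsu_threshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) return(NA_real_)
  h <- tabulate(pmin(nbins, 1L + as.integer((v - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_tot <- mu[nbins]
  between <- (mu_tot * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  rng[1] + k / nbins * diff(rng)  # upper edge of the chosen bin
}

# binary dilation by r pixels (chessboard), used for the provisional mask
# when estimating background automatically
dilate_mask <- function(fg, r = 2L) {
  H <- nrow(fg); W <- ncol(fg)
  out <- fg
  for (i in seq_len(r)) {
    shifted <- out
    shifted[-1, ] <- shifted[-1, ] | out[-H, ]
    shifted[-H, ] <- shifted[-H, ] | out[-1, ]
    shifted[, -1] <- shifted[, -1] | out[, -W]
    shifted[, -W] <- shifted[, -W] | out[, -1]
    out <- shifted
  }
  out
}

#' Shading (flat-field) and background correction
#'
#' Applies `(input - background) / shading` per frame, clipped at zero.
#' With `background = "auto"` the background is estimated per frame as the
#' median intensity outside a dilated provisional (Otsu) mask.
#'
#' @param stack a [channel_stack()].
#' @param flatfield `H x W` shading field, strictly positive (unit mean by
#'   convention); `NULL` for no shading correction.
#' @param background numeric background level, or `"auto"`.
#' @return corrected `channel_stack`; attribute `"background"` holds the
#'   per-frame levels used.
#' @export
correct_shading_background <- function(stack, flatfield = NULL,
                                       background = "auto") {
  d <- dim(stack$data)
  if (!is.null(flatfield)) {
    stopifnot(identical(dim(flatfield), d[2:3]))
    if (min(flatfield) <= 0) stop("flatfield must be strictly positive")
  }
  out <- stack$data
  bgs <- numeric(d[1])
  for (t in seq_len(d[1])) {
    fr <- out[t, , ]
    if (identical(background, "auto")) {
      thr <- otsu_threshold(fr)
      outside <- if (is.na(thr)) rep(TRUE, length(fr)) else !dilate_mask(fr >= thr, 2L)
      bg <- stats::median(fr[outside])
    } else {
      if (background < 0) stop("background must be >= 0")
      bg <- background
    }
    bgs[t] <- bg
    fr <- fr - bg
    if (!is.null(flatfield)) fr <- fr / flatfield
    out[t, , ] <- pmax(fr, 0)
  }
  res <- restack(stack, out)
  attr(res, "background") <- bgs
  res
}

#' Photobleach correction by mono-exponential fit
#'
#' Fits the in-mask mean intensity to `I0 * exp(-k t)` by least squares on
#' the log-transformed means, and divides each frame by `exp(-k t)`. The
#' correction is optional: it is skipped (`k = 0`) unless the exponential
#' fit reduces the residual variance of the mean trace by more than
#' `min_improvement` relative to a constant fit.
#'
#' @param stack a background-corrected [channel_stack()] with `T >= 5`.
#' @param mask a `cell_mask` (see [compute_mask()]) or logical `T x H x W`.
#' @param min_improvement fractional variance-reduction threshold
#'   (default 0.05).
#' @param force apply the fitted decay regardless of significance.
#' @return list: `stack` (corrected), `k` (1/s, 0 when skipped), `applied`,
#'   `fit` (per-frame means and fitted curve).
#' @export
correct_photobleach <- function(stack, mask, min_improvement = 0.05,
                                force = FALSE) {
  m <- if (inherits(mask, "cell_mask")) mask$mask else mask
  d <- dim(stack$data)
  stopifnot(identical(dim(m), d))
  if (d[1] < 5) stop("photobleach fit needs T >= 5 frames")
  times <- times_of(stack)
  means <- vapply(seq_len(d[1]), function(t) {
    sel <- m[t, , ]
    if (!any(sel)) stop("photobleach correction: empty mask at frame ", t - 1L)
    mean(stack$data[t, , ][sel])
  }, 0)
  if (any(means <= 0)) stop("photobleach fit needs positive in-mask means")
  fit <- stats::lm.fit(cbind(1, times), log(means))
  k <- -fit$coefficients[2]
  fitted_curve <- exp(fit$coefficients[1]) * exp(-k * times)
  rss_fit <- sum((means - fitted_curve)^2)
  rss_const <- sum((means - mean(means))^2)
  improvement <- if (rss_const > 0) 1 - rss_fit / rss_const else 0
  applied <- isTRUE(force) || (is.finite(improvement) &&
                                 improvement > min_improvement && k > 0)
  if (!applied) k <- 0
  out <- stack$data
  if (applied && k != 0) {
    decay <- exp(-k * times)
    for (t in seq_len(d[1])) out[t, , ] <- out[t, , ] / decay[t]
  }
  list(stack = restack(stack, out), k = unname(k), applied = applied,
       fit = list(times = times, means = means, improvement = improvement))
}

#' Estimate spectral bleedthrough coefficients from single-fluorophore controls
#'
#' `alpha` (donor bleedthrough into the FRET channel) is the robust
#' through-origin slope of FRET-channel vs donor-channel intensity over
#' in-mask pixels of a donor-only control; `beta` (direct acceptor
#' excitation) likewise from an acceptor-only control against the direct
#' acceptor-excitation image. The robust slope is the through-origin
#' Theil-Sen estimator (median of pixelwise ratios) with a bootstrap
#' standard error; ordinary least squares on the same pixels is the test
#' oracle, not the production path.
#'
#' @param donor_only list with `donor` and `acceptor` [channel_stack()]s of
#'   a donor-only control, already shading/background-corrected.
#' @param acceptor_only optional list with `direct` (direct-excitation
#'   acceptor image stack) and `acceptor` (FRET-channel) stacks; omitted in
#'   the two-image acquisition protocol, in which case `beta = NA`.
#' @param min_pixels minimum usable in-mask pixels (default 100).
#' @param n_boot bootstrap replicates for the standard errors.
#' @param seed RNG seed for the bootstrap.
#' @return list: `alpha`, `alpha_se`, `beta`, `beta_se`, `n_pixels`.
#' @export
estimate_bleedthrough <- function(donor_only, acceptor_only = NULL,
                                  min_pixels = 100L, n_boot = 199L,
                                  seed = 1L) {
  slope_of <- function(xstack, ystack, what) {
    x <- as.vector(xstack$data)
    y <- as.vector(ystack$data)
    thr <- otsu_threshold(x)
    sel <- is.finite(x) & is.finite(y) & !is.na(thr) & x >= thr
    if (sum(sel) < min_pixels)
      stop("too few in-mask pixels above background for ", what,
           " estimation (", sum(sel), " < ", min_pixels, ")")
    x <- x[sel]; y <- y[sel]
    slope <- stats::median(y / x)
    se <- with_seed(derive_seed(seed, what), {
      n <- length(x)
      reps <- vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        stats::median(y[i] / x[i])
      }, 0)
      stats::sd(reps)
    })
    if (slope < 0) {
      warning("negative fitted ", what, " slope clipped to 0")
      slope <- 0
    }
    list(slope = slope, se = se, n = length(x))
  }
  a <- slope_of(donor_only$donor, donor_only$acceptor, "alpha")
  b <- if (!is.null(acceptor_only)) {
    slope_of(acceptor_only$direct, acceptor_only$acceptor, "beta")
  } else list(slope = NA_real_, se = NA_real_, n = 0L)
  list(alpha = a$slope, alpha_se = a$se, beta = b$slope, beta_se = b$se,
       n_pixels = c(alpha = a$n, beta = b$n))
}

#' Bleedthrough correction of the raw FRET channel
#'
#' `corrected = raw_acceptor - alpha * donor - beta * acceptor_direct`,
#' clipped at zero. In the two-image protocol there is no direct
#' acceptor-excitation image; the beta term is then omitted and recorded as
#' such in the returned provenance attribute.
#'
#' @param raw_acceptor,donor congruent [channel_stack()]s.
#' @param acceptor_direct optional direct-excitation stack.
#' @param alpha,beta bleedthrough coefficients, `>= 0`.
#' @return `corrected_fret` channel stack with a `"bleedthrough"` attribute.
#' @export
correct_fret <- function(raw_acceptor, donor, acceptor_direct = NULL,
                         alpha, beta = 0) {
  if (!stack_congruent(raw_acceptor, donor)) stop("stack shape mismatch")
  stopifnot(alpha >= 0, beta >= 0)
  if (alpha >= 1 || beta >= 1)
    warning("bleedthrough coefficient >= 1 is unexpected for this protocol")
  out <- raw_acceptor$data - alpha * donor$data
  beta_used <- FALSE
  if (!is.null(acceptor_direct) && beta > 0) {
    if (!stack_congruent(raw_acceptor, acceptor_direct))
      stop("stack shape mismatch (acceptor_direct)")
    out <- out - beta * acceptor_direct$data
    beta_used <- TRUE
  }
  res <- restack(raw_acceptor, pmax(out, 0), role = "corrected_fret")
  attr(res, "bleedthrough") <- list(alpha = alpha, beta = beta,
                                    beta_term_applied = beta_used)
  res
}

#' Segment the cell by thresholding the donor channel
#'
#' Per-frame automatic (Otsu) threshold on the corrected donor image --
#' the channel with the highest signal-to-noise ratio -- followed by
#' largest-connected-component selection and hole filling. Frames without
#' above-threshold pixels are flagged degenerate with an empty mask.
#'
#' @param donor shading/background-corrected donor [channel_stack()].
#' @param clean apply largest-component + hole filling (default TRUE).
#' @return object of class `cell_mask`: logical `T x H x W` `mask`,
#'   per-frame `thresholds`, `degenerate` flags, `method`.
#' @export
compute_mask <- function(donor, clean = TRUE) {
  d <- dim(donor$data)
  mask <- array(FALSE, dim = d)
  thresholds <- numeric(d[1])
  degenerate <- logical(d[1])
  for (t in seq_len(d[1])) {
    fr <- donor$data[t, , ]
    thr <- otsu_threshold(fr)
    if (is.na(thr) || !any(fr >= thr)) {
      degenerate[t] <- TRUE
      thresholds[t] <- NA_real_
      next
    }
    fg <- fr >= thr
    if (clean) fg <- fill_holes(largest_component(fg))
    mask[t, , ] <- fg
    thresholds[t] <- thr
  }
  structure(list(mask = mask, thresholds = thresholds,
                 degenerate = degenerate, method = "otsu"),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d frames, method=%s, %d degenerate\n",
              dim(x$mask)[1], x$method, sum(x$degenerate)))
  invisible(x)
}

#' Compute the activity ratio movie
#'
#' Ratio = corrected FRET / donor, defined only where the cell mask is true
#' and the donor exceeds `eps` times the in-mask donor median (the dim-rim
#' floor); all other pixels are flagged undefined (NA).
#'
#' @param corrected_fret,donor congruent [channel_stack()]s.
#' @param mask a `cell_mask`.
#' @param eps donor floor as a fraction of the in-mask donor median, in
#'   (0, 1).
#' @return object of class `ratio_movie`: `ratio` (`T x H x W`, NA where
#'   undefined), `defined`, the donor `support` and per-frame mask
#'   `thresholds` (used by edge detection), physical metadata, provenance.
#' @export
compute_ratio <- function(corrected_fret, donor, mask, eps = 0.05) {
  if (!stack_congruent(corrected_fret, donor)) stop("stack shape mismatch")
  if (eps <= 0 || eps >= 1) stop("eps must lie in (0, 1)")
  d <- dim(donor$data)
  m <- if (inherits(mask, "cell_mask")) mask$mask else mask
  stopifnot(identical(dim(m), d))
  ratio <- array(NA_real_, dim = d)
  defined <- array(FALSE, dim = d)
  floors <- numeric(d[1])
  for (t in seq_len(d[1])) {
    sel <- m[t, , ]
    if (!any(sel)) next
    dfr <- donor$data[t, , ]
    floors[t] <- eps * stats::median(dfr[sel])
    ok <- sel & dfr > floors[t] & corrected_fret$data[t, , ] > 0
    r <- corrected_fret$data[t, , ][ok] / dfr[ok]
    fr <- matrix(NA_real_, d[2], d[3])
    fr[ok] <- r
    ratio[t, , ] <- fr
    defined[t, , ] <- ok
  }
  structure(list(
    ratio = ratio, defined = defined, support = donor$data,
    thresholds = if (inherits(mask, "cell_mask")) mask$thresholds
    else rep(NA_real_, d[1]),
    donor_floors = floors,
    pixel_size = donor$pixel_size, frame_interval = donor$frame_interval,
    provenance = list(eps = eps)), class = "ratio_movie")
}

#' @export
print.ratio_movie <- function(x, ...) {
  d <- dim(x$ratio)
  cat(sprintf("<ratio_movie> %d frames x %d x %d px, %.1f%% defined\n",
              d[1], d[2], d[3], 100 * mean(x$defined)))
  if (any(x$defined))
    cat(sprintf("  defined ratio range [%.3f, %.3f]\n",
                min(x$ratio, na.rm = TRUE), max(x$ratio, na.rm = TRUE)))
  invisible(x)
}

#' Register the acceptor channel onto the donor channel
#'
#' Rigid integer translation estimated once by FFT cross-correlation of the
#' first frame (image-splitter geometry: a fixed offset) and applied to the
#' whole acceptor stack. Errors if the normalized correlation peak is below
#' `min_correlation`.
#'
#' @param donor,acceptor [channel_stack()]s.
#' @param min_correlation minimum acceptable normalized peak correlation.
#' @return list: shifted `acceptor` stack, `shift` (dy, dx in px: the
#'   translation applied to the acceptor to align it with the donor),
#'   `peak` correlation.
#' @export
register_channels <- function(donor, acceptor, min_correlation = 0.5) {
  a <- donor$data[1, , ]
  b <- acceptor$data[1, , ]
  a0 <- a - mean(a); b0 <- b - mean(b)
  H <- nrow(a); W <- ncol(a)
  cc <- Re(stats::fft(stats::fft(a0) * Conj(stats::fft(b0)), inverse = TRUE)) /
    length(a0)
  peak <- which.max(cc)
  pk <- cc[peak] / sqrt(sum(a0^2) * sum(b0^2))
  if (pk < min_correlation)
    stop(sprintf("channels appear unregistered: peak correlation %.2f < %.2f",
                 pk, min_correlation))
  dy <- (peak - 1) %% H
  dx <- (peak - 1) %/% H
  if (dy > H / 2) dy <- dy - H
  if (dx > W / 2) dx <- dx - W
  out <- acceptor$data
  if (dy != 0 || dx != 0) {
    # circular shift; image-splitter offsets are a few pixels so wrapped
    # border content sits in background
    ri <- ((seq_len(H) - 1 - dy) %% H) + 1
    ci <- ((seq_len(W) - 1 - dx) %% W) + 1
    for (t in seq_len(dim(out)[1])) out[t, , ] <- acceptor$data[t, ri, ci]
  }
  list(acceptor = restack(acceptor, out), shift = c(dy = dy, dx = dx),
       peak = unname(pk))
}

#' Run the full ratiometric correction chain
#'
#' Fixed order: registration -> shading -> background -> optional
#' photobleach (per channel) -> bleedthrough -> masking -> ratio. The order
#' and every estimated parameter are recorded in the returned provenance.
#'
#' @param donor,acceptor raw [channel_stack()]s.
#' @param flatfields list with `donor` and `acceptor` `H x W` shading
#'   fields (NULL elements skip shading correction).
#' @param controls optional donor-only control pair for
#'   [estimate_bleedthrough()]; when absent `alpha` must be supplied.
#' @param alpha,beta bleedthrough coefficients used if no controls given.
#' @param background per-channel background or `"auto"`.
#' @param photobleach logical, attempt photobleach correction.
#' @param eps donor floor for [compute_ratio()].
#' @param register logical, run [register_channels()].
#' @param seed seed for the bleedthrough bootstrap.
#' @return list: `ratio` (a `ratio_movie`), `mask`, `donor` / `fret`
#'   corrected stacks, `alpha`, `beta`, `k` (per channel), `provenance`.
#' @export
apply_correction_chain <- function(donor, acceptor, flatfields = NULL,
                                   controls = NULL, alpha = NULL, beta = 0,
                                   background = "auto", photobleach = TRUE,
                                   eps = 0.05, register = TRUE, seed = 1L) {
  prov <- list(chain = c("register", "shading", "background",
                         if (photobleach) "photobleach", "bleedthrough",
                         "mask", "ratio"))
  if (register) {
    reg <- register_channels(donor, acceptor)
    acceptor <- reg$acceptor
    prov$registration <- list(shift = as.list(reg$shift), peak = reg$peak)
  }
  donor_c <- correct_shading_background(donor, flatfields$donor, background)
  acc_c <- correct_shading_background(acceptor, flatfields$acceptor, background)
  prov$background <- list(donor = attr(donor_c, "background"),
                          acceptor = attr(acc_c, "background"))

  k <- c(donor = 0, acceptor = 0)
  if (photobleach && dim(donor_c$data)[1] >= 5) {
    # provisional (uncleaned) mask is enough for the in-mask mean trace
    mask0 <- compute_mask(donor_c, clean = FALSE)
    if (!any(mask0$degenerate)) {
      pb_d <- correct_photobleach(donor_c, mask0)
      pb_a <- correct_photobleach(acc_c, mask0)
      donor_c <- pb_d$stack
      acc_c <- pb_a$stack
      k <- c(donor = pb_d$k, acceptor = pb_a$k)
    }
  }
  # final mask from the fully corrected donor: its thresholds are the ones
  # edge detection compares against the same donor support
  mask <- compute_mask(donor_c)

  if (!is.null(controls)) {
    ctrl_d <- correct_shading_background(controls$donor, flatfields$donor,
                                         background)
    ctrl_a <- correct_shading_background(controls$acceptor,
                                         flatfields$acceptor, background)
    bt <- estimate_bleedthrough(list(donor = ctrl_d, acceptor = ctrl_a),
                                seed = seed)
    alpha <- bt$alpha
    prov$bleedthrough <- bt
  } else {
    if (is.null(alpha)) stop("alpha must be given when no control stacks exist")
    prov$bleedthrough <- list(alpha = alpha, beta = beta, source = "config")
  }
  fret <- correct_fret(acc_c, donor_c, alpha = alpha, beta = 0)
  ratio <- compute_ratio(fret, donor_c, mask, eps = eps)
  prov$alpha <- alpha
  prov$beta <- beta
  prov$k <- as.list(k)
  prov$thresholds <- mask$thresholds
  prov$eps <- eps
  ratio$provenance <- utils::modifyList(ratio$provenance, prov)
  list(ratio = ratio, mask = mask, donor = donor_c, fret = fret,
       alpha = alpha, beta = beta, k = k, provenance = prov)
}
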