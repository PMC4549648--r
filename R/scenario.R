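# ScenarioConfig: the complete stated world of a synthetic two-channel FRET
# movie -- geometry, edge-motion schedule, activity model (baseline, hotspots,
# traveling wave, per-section edge-band multipliers, stimulus ramp) and
# acquisition nuisances. A config plus a seed fixes the realization exactly.

#' Build a synthetic-scenario configuration
#'
#' The simulated cell is star-convex: a disk of radius `cell$radius` around
#' `cell$center` whose boundary radius per angular edge section is offset in
#' time by the velocity schedule. All lengths are micrometers, times seconds,
#' velocities micrometers per second.
#'
#' @param grid `c(height, width)` in pixels.
#' @param pixel_size micrometers per pixel (default 0.5, a 4x4-binned sCMOS
#'   at high magnification).
#' @param frame_interval seconds between frames (default 1, the modeled
#'   1 s exposure protocol).
#' @param n_frames number of frames.
#' @param seed integer seed fixing the whole realization.
#' @param cell list: `center` (x, y um), `radius` (um), `n_sections`
#'   (angular edge sections, equal wedges starting at angle 0).
#' @param edge_schedule data frame with columns `section`, `velocity` (um/s,
#'   positive outward), `start`, `stop` (s). Sections absent from the
#'   schedule are static.
#' @param activity list: `baseline` (dimensionless, 1 = resting), `hotspots`
#'   (list of lists with `center`, `radius`, `amplitude`, `t_on`, `t_off`),
#'   `wave` (`period` s, `wavelength` um, `amplitude`, `direction` unit
#'   vector of crest propagation, `start` s, `region` = list(`center`,
#'   `radius`) disk or NULL for the whole cell), `class_bands`
#'   (`depth` um and `factors` data frame `section`/`factor`: multiplicative
#'   activity level of the band hugging that section's edge).
#' @param stimulus NULL or list: `time` (s), `center`, `radius` (um),
#'   `ramp_rate` (activity units/s), `ramp_delay` (s after `time` at which
#'   the ramp starts), `ramp_max` (saturation, activity units).
#' @param nuisances list of acquisition nuisances; see
#'   [default_nuisances()].
#' @param noise logical; FALSE renders the analytic noise-free,
#'   unquantized movie (the oracle limit).
#' @param rois list: `squares` (list of `id`/`center` for 4 um^2 trace
#'   ROIs), `section_rects` (logical: one 10 x 20 um rectangle per section,
#'   outward-oriented), `rect_width`, `rect_length` (um).
#' @param name scenario name used in sidecars.
#' @return a validated object of class `scenario_config`.
#' @export
scenario_config <- function(grid = c(96L, 96L),
                            pixel_size = 0.5,
                            frame_interval = 1,
                            n_frames = 300L,
                            seed = 1L,
                            cell = list(center = c(24, 24), radius = 16,
                                        n_sections = 24L),
                            edge_schedule = NULL,
                            activity = list(baseline = 1),
                            stimulus = NULL,
                            nuisances = default_nuisances(),
                            noise = TRUE,
                            rois = list(squares = list(), section_rects = TRUE,
                                        rect_width = 10, rect_length = 20),
                            name = "custom") {
  cfg <- list(grid = as.integer(grid), pixel_size = pixel_size,
              frame_interval = frame_interval, n_frames = as.integer(n_frames),
              seed = as.integer(seed), cell = cell,
              edge_schedule = edge_schedule, activity = activity,
              stimulus = stimulus,
              nuisances = utils::modifyList(default_nuisances(), nuisances),
              noise = isTRUE(noise), rois = rois, name = name)
  cfg$cell$n_sections <- as.integer(cfg$cell$n_sections %||% 24L)
  cfg$activity$baseline <- cfg$activity$baseline %||% 1
  cfg$rois$section_rects <- isTRUE(cfg$rois$section_rects %||% TRUE)
  cfg$rois$rect_width <- cfg$rois$rect_width %||% 10
  cfg$rois$rect_length <- cfg$rois$rect_length %||% 20
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

#' Default acquisition nuisance parameters
#'
#' Shading is a smooth quadratic bowl (10% peak-to-edge, unit mean; the
#' acceptor-channel bowl is laterally offset so the two channels do not
#' cancel in the ratio). Noise is Poisson shot noise at `gain` electrons per
#' ADU-equivalent plus Gaussian read noise, on a 16-bit scale.
#'
#' @return named list of nuisance parameters: `shading` (type, per-channel
#'   `strength`, per-channel lateral `offset_frac`), `background` ADU,
#'   `alpha` (donor bleedthrough), `beta` (acceptor cross-excitation,
#'   default off: two-image protocol), `bleach` per-channel decay 1/s,
#'   `gain`, `read_noise`, `calibration` (FRET counts per sensor count per
#'   activity unit), `rho` (sensor-density intensity scale, ADU).
#' @export
default_nuisances <- function() {
  list(
    shading = list(type = "bowl",
                   strength = c(donor = 0.10, acceptor = 0.10),
                   offset_frac = c(donor = 0, acceptor = 0.1)),
    background = c(donor = 100, acceptor = 100),
    alpha = 0.6,
    beta = 0,
    bleach = c(donor = 2e-4, acceptor = 2e-4),
    gain = 0.5,
    read_noise = 2,
    calibration = 1,
    rho = 8000,
    x_acc = 0
  )
}

validate_scenario_config <- function(cfg) {
  with(cfg, {
    if (any(grid <= 0)) stop("grid dimensions must be positive")
    if (pixel_size <= 0) stop("pixel_size must be positive")
    if (frame_interval <= 0) stop("frame_interval must be positive")
    if (n_frames < 1) stop("n_frames must be >= 1")
    if (cell$radius <= 0) stop("cell radius must be positive")
    if (cell$n_sections < 1) stop("cell must have >= 1 edge sections")
  })
  wv <- cfg$activity$wave
  if (!is.null(wv)) {
    if (wv$period <= 2 * cfg$frame_interval)
      stop("wave period must exceed 2 * frame_interval (sampling limit)")
    if (wv$wavelength <= 2 * cfg$pixel_size)
      stop("wave wavelength <= 2 * pixel_size is unresolvable on this grid")
    if (wv$amplitude < 0) stop("wave amplitude must be >= 0")
  }
  for (h in cfg$activity$hotspots %||% list()) {
    if (h$amplitude < 0) stop("hotspot amplitudes must be >= 0")
    if (h$radius <= 0) stop("hotspot radius must be positive")
  }
  nuis <- cfg$nuisances
  num_nuis <- c(nuis$background, nuis$alpha, nuis$beta, nuis$bleach,
                nuis$gain, nuis$read_noise, nuis$calibration, nuis$rho,
                nuis$x_acc, nuis$shading$strength)
  if (any(num_nuis < 0))
    stop("negative nuisance parameter: all nuisance parameters must be >= 0")
  es <- cfg$edge_schedule
  if (!is.null(es)) {
    stopifnot(all(c("section", "velocity", "start", "stop") %in% names(es)))
    if (any(es$stop < es$start)) stop("edge schedule: stop must be >= start")
    if (any(es$section < 1 | es$section > cfg$cell$n_sections))
      stop("edge schedule refers to a section id outside 1..n_sections")
  }
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> '%s': %dx%d px, %d frames @ %gs, %g um/px\n",
              x$name, x$grid[1], x$grid[2], x$n_frames, x$frame_interval,
              x$pixel_size))
  cat(sprintf("  cell r=%g um, %d sections; wave period %s s; noise %s\n",
              x$cell$radius, x$cell$n_sections,
              if (is.null(x$activity$wave)) "-" else x$activity$wave$period,
              x$noise))
  invisible(x)
}

# plain-list round-trip for YAML sidecars
config_to_list <- function(cfg) {
  out <- unclass(cfg)
  # yaml::write_yaml writes named atomic vectors as plain sequences; convert
  # the named nuisance vectors to lists so they round-trip as maps
  for (f in c("background", "bleach"))
    out$nuisances[[f]] <- as.list(out$nuisances[[f]])
  out$nuisances$shading$strength <- as.list(out$nuisances$shading$strength)
  out$nuisances$shading$offset_frac <-
    as.list(out$nuisances$shading$offset_frac)
  if (!is.null(out$edge_schedule)) {
    out$edge_schedule <- lapply(seq_len(nrow(out$edge_schedule)), function(i)
      as.list(out$edge_schedule[i, , drop = FALSE]))
  }
  cb <- out$activity$class_bands
  if (!is.null(cb) && is.data.frame(cb$factors)) {
    out$activity$class_bands$factors <- lapply(
      seq_len(nrow(cb$factors)), function(i) as.list(cb$factors[i, , drop = FALSE]))
  }
  out
}

config_from_list <- function(lst) {
  if (!is.null(lst$edge_schedule) && !is.data.frame(lst$edge_schedule)) {
    lst$edge_schedule <- do.call(rbind, lapply(lst$edge_schedule, as.data.frame))
  }
  cb <- lst$activity$class_bands
  if (!is.null(cb) && !is.data.frame(cb$factors)) {
    lst$activity$class_bands$factors <-
      do.call(rbind, lapply(cb$factors, as.data.frame))
  }
  # yaml flattens named numeric vectors to lists; restore the ones we use
  fixvec <- function(v) if (is.list(v)) unlist(v) else v
  for (f in c("background", "bleach")) lst$nuisances[[f]] <- fixvec(lst$nuisances[[f]])
  lst$nuisances$shading$strength <- fixvec(lst$nuisances$shading$strength)
  lst$nuisances$shading$offset_frac <- fixvec(lst$nuisances$shading$offset_frac)
  lst$cell$center <- fixvec(lst$cell$center)
  do.call(scenario_config, lst[intersect(names(lst), names(formals(scenario_config)))])
}

#' Load a bundled scenario preset
#'
#' Presets encode the package's reference experiments: `spontaneous_rhoa`,
#' `spontaneous_cdc42`, `sema3a_vesicle_rhoa`, `sema3a_vesicle_cdc42` and
#' `cdc42_beads`. Seeded ground truth (wave periods 70 / 110 / 155 s,
#' retracting/protruding activity ratios, stimulus-ramp onset) matches the
#' reference experimental conditions each preset emulates.
#'
#' @param name preset name.
#' @param seed optional seed override.
#' @param n_frames optional frame-count override (scaled-down test runs).
#' @return a `scenario_config`.
#' @export
preset_config <- function(name, seed = NULL, n_frames = NULL) {
  path <- system.file("presets", paste0(name, ".yaml"), package = "fretwave")
  if (path == "") stop("unknown preset: ", name)
  lst <- yaml::read_yaml(path)
  if (!is.null(seed)) lst$seed <- as.integer(seed)
  if (!is.null(n_frames)) lst$n_frames <- as.integer(n_frames)
  config_from_list(lst)
}

#' List bundled scenario presets
#' @return character vector of preset names.
#' @export
list_presets <- function() {
  sub("\\.yaml$", "", dir(system.file("presets", package = "fretwave"),
                          pattern = "\\.yaml$"))
}
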