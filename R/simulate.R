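# Forward simulator: star-convex cell geometry with scheduled edge motion,
# dimensionless activity field (baseline + hotspots + traveling wave +
# edge-band class multipliers + stimulus ramp), and two-channel rendering
# with acquisition nuisances. The seeded parameters are the ground truth
# against which the analysis chain is validated by parameter recovery.

# piecewise-linear integral of the velocity schedule: offset (um) of each
# section's boundary at time t
schedule_offsets <- function(cfg, t) {
  off <- numeric(cfg$cell$n_sections)
  es <- cfg$edge_schedule
  if (is.null(es) || !nrow(es)) return(off)
  for (i in seq_len(nrow(es))) {
    dt <- max(0, min(t, es$stop[i]) - es$start[i])
    off[es$section[i]] <- off[es$section[i]] + es$velocity[i] * dt
  }
  off
}

section_of_angle <- function(theta, n_sections) {
  th <- theta %% (2 * pi)
  pmin(1L + as.integer(floor(th / (2 * pi / n_sections))), n_sections)
}

#' Simulate per-frame cell geometry
#'
#' Realizes the configured cell as a star-convex region whose boundary radius
#' per angular edge section follows the velocity schedule exactly (radial
#' offsetting of the section's boundary arc, i.e. normal offsetting for a
#' locally circular edge). Sub-pixel boundary positions are kept in the
#' ground truth; the rendered occupancy has a one-pixel anti-aliased rim and
#' the boolean mask thresholds it at 0.5.
#'
#' @param config a [scenario_config()].
#' @return object of class `scenario_geometry`: `coverage` (`T x H x W`
#'   occupancy in \[0, 1\]), `edge_um` (`n_sections x T` true boundary radius,
#'   um), grids (`sec_grid`, `r_grid`, `theta_grid`), the section mid-angles,
#'   and the config.
#' @export
simulate_geometry <- function(config) {
  cfg <- config
  H <- cfg$grid[1]; W <- cfg$grid[2]
  px <- cfg$pixel_size
  ctr <- cfg$cell$center
  g <- coord_grids(H, W, px)
  r_grid <- sqrt((g$X - ctr[1])^2 + (g$Y - ctr[2])^2)
  theta_grid <- atan2(g$Y - ctr[2], g$X - ctr[1])
  ns <- cfg$cell$n_sections
  sec_grid <- matrix(section_of_angle(theta_grid, ns), H, W)

  max_r <- min(ctr[1], ctr[2], (W - 1) * px - ctr[1], (H - 1) * px - ctr[2]) - px
  Tn <- cfg$n_frames
  times <- (seq_len(Tn) - 1) * cfg$frame_interval
  coverage <- array(0, dim = c(Tn, H, W))
  edge_um <- matrix(0, ns, Tn)
  for (t in seq_len(Tn)) {
    off <- schedule_offsets(cfg, times[t])
    R_s <- cfg$cell$radius + off
    bad <- which(R_s > max_r | R_s < 2 * px)
    if (length(bad)) {
      stop(sprintf(
        "edge schedule moves section %d outside the grid at frame %d (radius %.2f um, allowed [%.2f, %.2f])",
        bad[1], t - 1L, R_s[bad[1]], 2 * px, max_r))
    }
    edge_um[, t] <- R_s
    Rmap <- matrix(R_s[sec_grid], H, W)
    coverage[t, , ] <- clamp((Rmap - r_grid) / px + 0.5, 0, 1)
  }
  mid_angles <- (seq_len(ns) - 0.5) * 2 * pi / ns
  structure(list(coverage = coverage, edge_um = edge_um, sec_grid = sec_grid,
                 r_grid = r_grid, theta_grid = theta_grid,
                 mid_angles = mid_angles, config = cfg),
            class = "scenario_geometry")
}

#' Boolean cell mask stack of a simulated geometry
#' @param geometry a `scenario_geometry`.
#' @return logical `T x H x W` array (occupancy >= 0.5).
#' @export
geometry_mask <- function(geometry) geometry$coverage >= 0.5

#' Simulate the dimensionless activity field
#'
#' Builds the true GTPase-activity field: baseline, Gaussian hotspots within
#' their on-windows, a traveling cosine wave
#' `A * cos(2*pi*(t/T - x/lambda))` restricted to its region and to
#' `t >= start` (with `x` the projection onto the propagation direction),
#' per-section multiplicative bands hugging the moving edge, and a clipped
#' linear ramp after the stimulus. The field is floored at a small positive
#' value so it is strictly positive inside the cell.
#'
#' @param config a [scenario_config()].
#' @param geometry matching [simulate_geometry()] output.
#' @return numeric `T x H x W` activity array (1 = baseline).
#' @export
simulate_activity_field <- function(config, geometry) {
  cfg <- config
  act_cfg <- cfg$activity
  H <- cfg$grid[1]; W <- cfg$grid[2]
  Tn <- cfg$n_frames
  times <- (seq_len(Tn) - 1) * cfg$frame_interval
  g <- coord_grids(H, W, cfg$pixel_size)

  wv <- act_cfg$wave
  if (!is.null(wv)) {
    dirv <- wv$direction %||% c(-1, 0)
    dirv <- unlist(dirv); dirv <- dirv / sqrt(sum(dirv^2))
    xproj <- (g$X - cfg$cell$center[1]) * dirv[1] +
      (g$Y - cfg$cell$center[2]) * dirv[2]
    wreg <- if (is.null(wv$region)) {
      matrix(TRUE, H, W)
    } else {
      rc <- unlist(wv$region$center %||% cfg$cell$center)
      sqrt((g$X - rc[1])^2 + (g$Y - rc[2])^2) <= wv$region$radius
    }
    wstart <- wv$start %||% 0
    widx <- which(wreg)
    wphase <- 2 * pi * xproj[widx] / wv$wavelength
  }

  hs <- act_cfg$hotspots %||% list()
  hs_fields <- lapply(hs, function(h) {
    ctr <- unlist(h$center)
    d2 <- (g$X - ctr[1])^2 + (g$Y - ctr[2])^2
    h$amplitude * exp(-d2 / h$radius^2)
  })

  cb <- act_cfg$class_bands
  if (!is.null(cb) && nrow(cb$factors)) {
    # per-section pixel caches: the band test then touches only own-section
    # pixels instead of the full grid
    sec_idx <- lapply(cb$factors$section,
                      function(s) which(geometry$sec_grid == s))
    sec_r <- lapply(sec_idx, function(ix) geometry$r_grid[ix])
  }
  stim <- cfg$stimulus
  if (!is.null(stim)) {
    sc <- unlist(stim$center)
    sreg <- sqrt((g$X - sc[1])^2 + (g$Y - sc[2])^2) <= stim$radius
    ramp_start <- stim$time + (stim$ramp_delay %||% 10)
    ramp_max <- stim$ramp_max %||% 1
  }

  base <- act_cfg$baseline
  field <- array(0, dim = c(Tn, H, W))
  for (t in seq_len(Tn)) {
    fr <- matrix(base, H, W)
    if (length(hs_fields)) {
      for (i in seq_along(hs_fields)) {
        h <- hs[[i]]
        if (times[t] >= (h$t_on %||% 0) && times[t] < (h$t_off %||% Inf))
          fr <- fr + hs_fields[[i]]
      }
    }
    if (!is.null(wv) && times[t] >= wstart) {
      fr[widx] <- fr[widx] +
        wv$amplitude * cos(2 * pi * times[t] / wv$period - wphase)
    }
    if (!is.null(cb) && nrow(cb$factors)) {
      depth <- cb$depth %||% 5
      for (i in seq_len(nrow(cb$factors))) {
        f <- cb$factors$factor[i]
        if (f == 1) next
        Rs <- geometry$edge_um[cb$factors$section[i], t]
        sel <- sec_idx[[i]][sec_r[[i]] >= (Rs - depth) & sec_r[[i]] <= Rs]
        fr[sel] <- fr[sel] + base * (f - 1)
      }
    }
    if (!is.null(stim) && times[t] >= ramp_start) {
      fr[sreg] <- fr[sreg] +
        min(ramp_max, stim$ramp_rate * (times[t] - ramp_start))
    }
    field[t, , ] <- pmax(fr, 1e-6)
  }
  field
}

# smooth quadratic-bowl shading field, unit mean, strictly positive
shading_field <- function(H, W, pixel_size, strength, offset_frac = 0) {
  g <- coord_grids(H, W, pixel_size)
  cx <- (W - 1) * pixel_size * (0.5 + offset_frac)
  cy <- (H - 1) * pixel_size * 0.5
  b <- (g$X - cx)^2 + (g$Y - cy)^2
  b <- b / max(b)
  s <- 1 - strength * b
  s / mean(s)
}

#' Render the two acquisition channels from activity and geometry
#'
#' Forward model per pixel x and frame time t (sensor density
#' `rho(x) = rho * occupancy`):
#' \deqn{D = S_d(x) B_d(t) \rho(x) + bg_d + noise}
#' \deqn{A_{raw} = S_a(x) B_a(t) (c\,\rho(x)\,act(x,t) + \alpha\,\rho(x) +
#'   \beta X_{acc}) + bg_a + noise}
#' with shading fields S (unit mean), photobleach factors
#' `B(t) = exp(-k t)`, calibration c, donor bleedthrough alpha and direct
#' acceptor excitation beta (off by default). Noise, when enabled, is
#' `Poisson(gain * signal) / gain + N(0, read_noise)` followed by 16-bit
#' quantization; with `noise = FALSE` the analytic unquantized movie is
#' returned.
#'
#' @param activity `T x H x W` activity array.
#' @param geometry matching `scenario_geometry`.
#' @param nuisances nuisance list (see [default_nuisances()]); any negative
#'   parameter is an error.
#' @param seed integer seed for the noise realization.
#' @param noise logical, add noise + quantization.
#' @return list with `donor` and `acceptor` [channel_stack()]s and the
#'   `shading` fields used (`donor`, `acceptor` matrices).
#' @export
render_channels <- function(activity, geometry, nuisances = default_nuisances(),
                            seed = 1L, noise = TRUE) {
  cfg <- geometry$config
  nuis <- utils::modifyList(default_nuisances(), nuisances)
  if (any(c(nuis$background, nuis$alpha, nuis$beta, nuis$bleach, nuis$gain,
            nuis$read_noise, nuis$calibration, nuis$rho, nuis$x_acc,
            nuis$shading$strength) < 0))
    stop("negative nuisance parameter")
  d <- dim(activity)
  Tn <- d[1]; H <- d[2]; W <- d[3]
  stopifnot(identical(dim(geometry$coverage), d))
  times <- (seq_len(Tn) - 1) * cfg$frame_interval
  S_d <- shading_field(H, W, cfg$pixel_size, nuis$shading$strength[["donor"]],
                       (nuis$shading$offset_frac %||% c(donor = 0))[["donor"]])
  S_a <- shading_field(H, W, cfg$pixel_size, nuis$shading$strength[["acceptor"]],
                       (nuis$shading$offset_frac %||% c(acceptor = 0))[["acceptor"]])
  Bd <- exp(-nuis$bleach[["donor"]] * times)
  Ba <- exp(-nuis$bleach[["acceptor"]] * times)

  donor <- array(0, dim = d)
  acc <- array(0, dim = d)
  add_noise <- function(x) {
    x <- rpois(length(x), nuis$gain * x) / nuis$gain +
      rnorm(length(x), 0, nuis$read_noise)
    clamp(round(x), 0, 65535)
  }
  with_seed(seed, {
    for (t in seq_len(Tn)) {
      rho_t <- nuis$rho * geometry$coverage[t, , ]
      dfr <- S_d * (Bd[t] * rho_t) + nuis$background[["donor"]]
      afr <- S_a * (Ba[t] * (nuis$calibration * rho_t * activity[t, , ] +
                               nuis$alpha * rho_t + nuis$beta * nuis$x_acc)) +
        nuis$background[["acceptor"]]
      if (noise) {
        dfr <- add_noise(dfr)
        afr <- add_noise(afr)
      }
      donor[t, , ] <- dfr
      acc[t, , ] <- afr
    }
  })
  list(
    donor = channel_stack(donor, "donor", cfg$pixel_size, cfg$frame_interval),
    acceptor = channel_stack(acc, "raw_acceptor", cfg$pixel_size,
                             cfg$frame_interval),
    shading = list(donor = S_d, acceptor = S_a)
  )
}

# render a short single-fluorophore control scenario on the same geometry
# frame; donor-only cells have no acceptor fluorophore (FRET = 0, only
# bleedthrough in the acceptor channel)
render_donor_only_control <- function(geometry, nuisances, seed,
                                      n_frames = 5L, noise = TRUE) {
  cfg <- geometry$config
  nuis <- utils::modifyList(default_nuisances(), nuisances)
  sub <- geometry
  sub$coverage <- geometry$coverage[rep(1L, n_frames), , , drop = FALSE]
  act <- array(0, dim = dim(sub$coverage))
  nuis0 <- nuis
  nuis0$calibration <- 0  # no acceptor -> no sensitized emission
  nuis0$bleach <- c(donor = 0, acceptor = 0)
  ch <- render_channels(act, sub, nuis0, seed = seed, noise = noise)
  ch$donor$role <- "control_donor_only"
  ch
}

#' Simulate a complete scenario
#'
#' Runs geometry, activity and rendering for a config and assembles the
#' ground-truth record (seeded wave period, per-section net edge velocities
#' and class labels, class activity ratios, nuisance set, seed).
#'
#' @param config a [scenario_config()].
#' @param controls render a short donor-only control pair for bleedthrough
#'   estimation.
#' @return object of class `fret_scenario`.
#' @export
simulate_scenario <- function(config, controls = TRUE) {
  cfg <- config
  geom <- simulate_geometry(cfg)
  act <- simulate_activity_field(cfg, geom)
  ch <- render_channels(act, geom, cfg$nuisances,
                        seed = derive_seed(cfg$seed, "render"),
                        noise = cfg$noise)
  ctrl <- if (controls) {
    render_donor_only_control(geom, cfg$nuisances,
                              seed = derive_seed(cfg$seed, "control"),
                              noise = cfg$noise)
  }

  ns <- cfg$cell$n_sections
  duration <- (cfg$n_frames - 1) * cfg$frame_interval
  net_v <- (geom$edge_um[, cfg$n_frames] - geom$edge_um[, 1]) / max(duration, 1)
  labels <- ifelse(net_v > 1e-9, "protruding",
                   ifelse(net_v < -1e-9, "retracting", "stalling"))
  cb <- cfg$activity$class_bands
  class_ratios <- NULL
  if (!is.null(cb) && nrow(cb$factors)) {
    fac <- rep(1, ns)
    fac[cb$factors$section] <- cb$factors$factor
    stal <- mean(fac[labels == "stalling"])
    class_ratios <- list(
      stalling = 1,
      protruding = if (any(labels == "protruding"))
        mean(fac[labels == "protruding"]) / stal else NULL,
      retracting = if (any(labels == "retracting"))
        mean(fac[labels == "retracting"]) / stal else NULL)
  }
  truth <- list(
    name = cfg$name,
    seed = cfg$seed,
    wave_period_s = cfg$activity$wave$period %||% NULL,
    wave_wavelength_um = cfg$activity$wave$wavelength %||% NULL,
    class_ratios = class_ratios,
    section_labels = as.list(stats::setNames(labels, paste0("s", seq_len(ns)))),
    section_velocity_um_s = as.list(stats::setNames(net_v, paste0("s", seq_len(ns)))),
    stimulus_time_s = cfg$stimulus$time %||% NULL,
    ramp_start_s = if (!is.null(cfg$stimulus))
      cfg$stimulus$time + (cfg$stimulus$ramp_delay %||% 10) else NULL,
    nuisances = cfg$nuisances,
    noise = cfg$noise
  )
  structure(list(config = cfg, geometry = geom, activity = act,
                 donor = ch$donor, acceptor = ch$acceptor,
                 shading = ch$shading, controls = ctrl, truth = truth),
            class = "fret_scenario")
}

#' @export
print.fret_scenario <- function(x, ...) {
  cat(sprintf("<fret_scenario> '%s', %d frames, seed %d\n", x$config$name,
              x$config$n_frames, x$config$seed))
  invisible(x)
}

#' Write a simulated scenario to disk
#'
#' Emits `donor.tif` / `acceptor.tif` (16-bit multi-page TIFF with pixel size
#' and frame interval metadata), per-channel flat-field references
#' (`flatfield_donor.tif`, `flatfield_acceptor.tif`, float32), an optional
#' donor-only control pair, the ground-truth sidecar `truth.json`, the config
#' copy `scenario.yaml` and the ROI table `rois.csv`. Re-reading reproduces
#' the stacks bit-exactly.
#'
#' @param scenario a `fret_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  scn <- scenario
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create scenario directory: ", dir)
  cfg <- scn$config
  wr <- function(stack, name, dtype = "uint16") {
    write_tiff_stack(stack$data, file.path(dir, name), dtype = dtype,
                     pixel_size = cfg$pixel_size,
                     frame_interval = cfg$frame_interval,
                     extra_description = list(role = stack$role,
                                              scenario = cfg$name))
  }
  wr(scn$donor, "donor.tif")
  wr(scn$acceptor, "acceptor.tif")
  write_tiff_stack(scn$shading$donor, file.path(dir, "flatfield_donor.tif"),
                   dtype = "float32", pixel_size = cfg$pixel_size,
                   frame_interval = cfg$frame_interval)
  write_tiff_stack(scn$shading$acceptor, file.path(dir, "flatfield_acceptor.tif"),
                   dtype = "float32", pixel_size = cfg$pixel_size,
                   frame_interval = cfg$frame_interval)
  if (!is.null(scn$controls)) {
    wr(scn$controls$donor, "control_donor_only_donor.tif")
    wr(scn$controls$acceptor, "control_donor_only_acceptor.tif")
  }
  write_json_file(scn$truth, file.path(dir, "truth.json"))
  yaml::write_yaml(config_to_list(cfg), file.path(dir, "scenario.yaml"))
  write_rois(make_scenario_rois(cfg), file.path(dir, "rois.csv"))
  invisible(dir)
}

#' Read a scenario directory written by [write_scenario()]
#'
#' @param dir scenario directory.
#' @return list with `donor`, `acceptor` channel stacks, `flatfields`,
#'   `controls` (or NULL), `config`, `truth` and `rois`.
#' @export
read_scenario <- function(dir) {
  cfg <- config_from_list(yaml::read_yaml(file.path(dir, "scenario.yaml")))
  out <- list(
    donor = read_channel_stack(file.path(dir, "donor.tif"), "donor"),
    acceptor = read_channel_stack(file.path(dir, "acceptor.tif"), "raw_acceptor"),
    flatfields = list(
      donor = read_tiff_stack(file.path(dir, "flatfield_donor.tif"))$data[1, , ],
      acceptor = read_tiff_stack(file.path(dir, "flatfield_acceptor.tif"))$data[1, , ]
    ),
    config = cfg,
    truth = read_json_file(file.path(dir, "truth.json")),
    rois = read_rois(file.path(dir, "rois.csv"))
  )
  cd <- file.path(dir, "control_donor_only_donor.tif")
  if (file.exists(cd)) {
    out$controls <- list(
      donor = read_channel_stack(cd, "donor"),
      acceptor = read_channel_stack(
        file.path(dir, "control_donor_only_acceptor.tif"), "raw_acceptor"))
    out$controls$donor$role <- "control_donor_only"
  }
  out
}
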