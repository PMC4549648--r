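# End-to-end orchestration: simulate a scenario to disk, analyze a scenario
# directory through the full correction + analytics chain, and score recovery
# against the ground-truth sidecar.

fw_log <- function(level, ..., min_level = getOption("fretwave.log_level", "INFO")) {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)
  if (levels[[level]] >= levels[[min_level]])
    message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                    paste0(..., collapse = "")))
}

#' Simulate a scenario and write it to disk
#'
#' @param config a [scenario_config()], or a preset name.
#' @param out_dir output directory.
#' @param seed optional seed override.
#' @return the scenario directory, invisibly.
#' @export
fw_simulate <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- preset_config(config, seed = seed)
  else if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    validate_scenario_config(config)
  }
  fw_log("INFO", "simulating scenario '", config$name, "' (",
         config$n_frames, " frames, seed ", config$seed, ")")
  scn <- simulate_scenario(config)
  write_scenario(scn, out_dir)
  fw_log("INFO", "scenario written to ", out_dir)
  invisible(out_dir)
}

#' Analyze a scenario directory
#'
#' Runs the correction chain (registration, shading, background, optional
#' photobleach, bleedthrough from the bundled control pair, masking, ratio),
#' edge detection + classification on every rectangle ROI, class-wise
#' stalling-normalized ratio summaries, dF/F0 traces + wave-period estimates
#' on every square ROI, and onset latency when the scenario has a stimulus.
#' Writes `report.json`, `provenance.json`, `edges.csv`, `traces.csv`,
#' `class_summary.csv`, `mask.tif`, optionally `ratio.tif` and a montage
#' PNG, all under `out_dir`. Outputs are removed again if the run fails
#' partway.
#'
#' @param in_dir scenario directory (from [fw_simulate()] or equivalent).
#' @param out_dir report directory.
#' @param photobleach run the optional photobleach stage.
#' @param eps donor floor for the ratio.
#' @param v0 stalling threshold um/s; default from the scenario config
#'   (`rois$v0`) or 0.005.
#' @param m frames averaged into F0.
#' @param smoothing_window,min_prominence maxima-detection parameters.
#' @param onset_k onset threshold in baseline SD multiples.
#' @param n_intervals intervals pooled into the period estimate
#'   (default 10).
#' @param band_depth edge-band depth for class quantification, um.
#' @param do_sections run edge detection / classification / class summary on
#'   the rectangle ROIs (disable for trace-only runs).
#' @param write_ratio_tiff write the (large) float32 ratio movie.
#' @return the parsed report, invisibly.
#' @export
fw_analyze <- function(in_dir, out_dir, photobleach = TRUE, eps = 0.05,
                       v0 = NULL, m = 1L, smoothing_window = 5,
                       min_prominence = 0.5, onset_k = 3, n_intervals = 10L,
                       band_depth = 5, do_sections = TRUE,
                       write_ratio_tiff = FALSE) {
  scn <- read_scenario(in_dir)
  cfg <- scn$config
  v0 <- v0 %||% cfg$rois$v0 %||% 0.005
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE))

  fw_log("INFO", "correction chain on '", cfg$name, "'")
  chain <- apply_correction_chain(
    scn$donor, scn$acceptor, flatfields = scn$flatfields,
    controls = scn$controls, alpha = cfg$nuisances$alpha,
    photobleach = photobleach, eps = eps, seed = cfg$seed)
  scn$donor <- NULL; scn$acceptor <- NULL; gc(FALSE)
  ratio <- chain$ratio

  rect_rois <- if (do_sections)
    Filter(function(r) r$kind == "rectangle", scn$rois) else list()
  sq_rois <- Filter(function(r) r$kind == "square", scn$rois)

  fw_log("INFO", "edge detection on ", length(rect_rois), " section ROIs")
  traces <- lapply(rect_rois, function(r) detect_edge(ratio, r))
  cls <- if (length(traces)) classify_sections(traces, v0 = v0) else NULL
  summary_df <- NULL
  if (!is.null(cls) && any(cls$class == "stalling")) {
    means <- vapply(traces, function(tr)
      section_mean_ratio(ratio, tr, band_depth = band_depth)$mean, 0)
    summary_df <- summarize_classes(means, cls$class)
  }

  fw_log("INFO", "activity traces on ", length(sq_rois), " square ROIs")
  wave_results <- list()
  onset_results <- list()
  for (r in sq_rois) {
    tr <- roi_trace(ratio, r)
    dff <- delta_f_over_f(tr, m = m)
    tms <- tr$trace$time_s
    mx <- detect_maxima(dff, tms, smoothing_window = smoothing_window,
                        min_prominence = min_prominence)
    wave_results[[r$id]] <- if (length(mx) >= 2) {
      we <- estimate_period(mx, n_intervals = n_intervals)
      list(period_s = we$period_s, sem_s = we$sem_s,
           n_intervals = we$n_intervals, n_maxima = length(mx),
           maxima_times_s = we$maxima_times)
    } else list(period_s = NULL, n_maxima = length(mx))
    if (!is.null(cfg$stimulus)) {
      on <- detect_onset(dff, tms, cfg$stimulus$time, k = onset_k)
      onset_results[[r$id]] <- list(latency_s = on$latency_s,
                                    onset_time_s = on$onset_time_s,
                                    threshold = on$threshold)
    }
    utils::write.csv(
      data.frame(frame = tr$trace$frame, time_s = tms, F = tr$trace$F,
                 dff = dff),
      file.path(out_dir, sprintf("trace_%s.csv", r$id)), row.names = FALSE)
  }

  if (length(traces)) {
    edges_df <- do.call(rbind, lapply(traces, function(tr)
      cbind(id = tr$roi$id, section = tr$roi$section, tr$trace)))
    utils::write.csv(edges_df, file.path(out_dir, "edges.csv"),
                     row.names = FALSE)
  }
  if (!is.null(summary_df))
    utils::write.csv(as.data.frame(summary_df),
                     file.path(out_dir, "class_summary.csv"),
                     row.names = FALSE)
  write_tiff_stack(chain$mask$mask + 0, file.path(out_dir, "mask.tif"),
                   dtype = "uint8", pixel_size = cfg$pixel_size,
                   frame_interval = cfg$frame_interval)
  if (write_ratio_tiff) {
    rr <- ratio$ratio
    rr[is.na(rr)] <- NaN  # undefined-value sentinel
    write_tiff_stack(rr, file.path(out_dir, "ratio.tif"), dtype = "float32",
                     pixel_size = cfg$pixel_size,
                     frame_interval = cfg$frame_interval)
  }
  if (length(rect_rois))
    tryCatch(plot_montage(build_montage(ratio, rect_rois[[1]],
                                        interval_s = 60),
                          file.path(out_dir, "montage.png")),
             error = function(e) fw_log("WARN", "montage skipped: ",
                                        conditionMessage(e)))

  report <- list(
    scenario = cfg$name,
    seed = cfg$seed,
    parameters = list(eps = eps, v0 = v0, m = m,
                      smoothing_window = smoothing_window,
                      min_prominence = min_prominence, onset_k = onset_k,
                      n_intervals = n_intervals, band_depth = band_depth,
                      photobleach = photobleach),
    alpha = chain$alpha,
    k = as.list(chain$k),
    registration = chain$provenance$registration,
    sections = if (!is.null(cls)) lapply(seq_len(nrow(cls)), function(i)
      as.list(cls[i, ])) else NULL,
    class_summary = if (!is.null(summary_df))
      lapply(seq_len(nrow(summary_df)), function(i)
        as.list(as.data.frame(summary_df)[i, ])) else NULL,
    waves = wave_results,
    onsets = if (length(onset_results)) onset_results else NULL,
    version = as.character(utils::packageVersion("fretwave"))
  )
  write_json_file(report, file.path(out_dir, "report.json"))
  prov <- chain$provenance
  prov$software_version <- report$version
  prov$seed <- cfg$seed
  write_json_file(prov, file.path(out_dir, "provenance.json"))
  ok <- TRUE
  fw_log("INFO", "report written to ", out_dir)
  invisible(report)
}

#' Default recovery tolerances
#'
#' @return named list of scorecard tolerances: fractional period error,
#'   fractional class-ratio error, onset latency bound (s), fractional
#'   edge-velocity error for moving sections, minimum mask Jaccard.
#' @export
default_tolerances <- function() {
  list(period_frac = 0.10, class_frac = 0.03, onset_max_s = 30,
       velocity_frac = 0.10, jaccard_min = 0.95)
}

#' Score an analysis report against the ground truth
#'
#' Compares `report.json` to the scenario's `truth.json` (and regenerates
#' the true geometry from the config to score the mask): period error,
#' class-ratio errors, onset latency, per-section edge-velocity errors and
#' mask Jaccard, each checked against its tolerance. Writes
#' `scorecard.json` into the analysis directory.
#'
#' @param scenario_dir directory with `truth.json` + `scenario.yaml`.
#' @param analysis_dir directory with `report.json` + `mask.tif`.
#' @param tolerances see [default_tolerances()].
#' @return the scorecard list, invisibly.
#' @export
fw_recover <- function(scenario_dir, analysis_dir,
                       tolerances = default_tolerances()) {
  tpath <- file.path(scenario_dir, "truth.json")
  if (!file.exists(tpath)) stop("missing ground-truth sidecar: ", tpath)
  truth <- read_json_file(tpath)
  report <- read_json_file(file.path(analysis_dir, "report.json"))
  tol <- utils::modifyList(default_tolerances(), tolerances)
  checks <- list()

  if (!is.null(truth$wave_period_s) && length(report$waves)) {
    periods <- unlist(lapply(report$waves, function(w) w$period_s))
    if (length(periods)) {
      err <- abs(periods[1] - truth$wave_period_s)
      checks$period <- list(
        truth_s = truth$wave_period_s, recovered_s = unname(periods[1]),
        abs_error_s = unname(err),
        pass = unname(err <= tol$period_frac * truth$wave_period_s))
    }
  }

  # re-read JSON arrives simplified into data.frames; in-memory reports are
  # lists of rows -- normalize both to data.frames
  as_df <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) x else do.call(rbind, lapply(x, as.data.frame))
  }
  report$sections <- as_df(report$sections)
  report$class_summary <- as_df(report$class_summary)

  if (!is.null(truth$class_ratios) && !is.null(report$class_summary)) {
    rec <- stats::setNames(report$class_summary$normalized_mean,
                           report$class_summary$class)
    for (cl in setdiff(names(truth$class_ratios), "stalling")) {
      tv <- truth$class_ratios[[cl]]
      if (is.null(tv) || !cl %in% names(rec)) next
      err <- abs(rec[[cl]] - tv) / tv
      checks[[paste0("class_", cl)]] <- list(
        truth = tv, recovered = rec[[cl]], rel_error = err,
        pass = err <= tol$class_frac)
    }
  }

  if (!is.null(truth$stimulus_time_s) && length(report$onsets)) {
    lat <- unlist(lapply(report$onsets, function(o) o$latency_s))
    if (length(lat)) {
      true_lat <- truth$ramp_start_s - truth$stimulus_time_s
      checks$onset <- list(
        true_ramp_latency_s = true_lat, detected_latency_s = unname(lat[1]),
        pass = is.finite(lat[1]) && lat[1] <= tol$onset_max_s)
    }
  }

  if (!is.null(report$sections)) {
    sec_v <- report$sections$mean_velocity_um_s
    sec_id <- report$sections$section
    verr <- c()
    for (i in seq_along(sec_id)) {
      tv <- truth$section_velocity_um_s[[paste0("s", sec_id[i])]]
      if (is.null(tv) || abs(tv) < 1e-9) next
      verr <- c(verr, abs(sec_v[i] - tv) / abs(tv))
    }
    if (length(verr)) {
      checks$edge_velocity <- list(
        mean_rel_error = mean(verr), n_moving_sections = length(verr),
        pass = mean(verr) <= tol$velocity_frac)
    }
    tlab <- unlist(truth$section_labels[paste0("s", sec_id)])
    rlab <- report$sections$class
    agree <- mean(rlab == tlab)
    checks$classification <- list(agreement = agree, pass = agree >= 0.9)
  }

  mask_path <- file.path(analysis_dir, "mask.tif")
  if (file.exists(mask_path)) {
    cfg <- config_from_list(yaml::read_yaml(file.path(scenario_dir,
                                                      "scenario.yaml")))
    geom <- simulate_geometry(cfg)
    true_mask <- geometry_mask(geom)
    rec_mask <- read_tiff_stack(mask_path)$data > 0
    jac <- vapply(seq_len(dim(true_mask)[1]), function(t) {
      a <- true_mask[t, , ]; b <- rec_mask[t, , ]
      sum(a & b) / sum(a | b)
    }, 0)
    checks$mask <- list(jaccard_mean = mean(jac), jaccard_min = min(jac),
                        pass = mean(jac) >= tol$jaccard_min)
  }

  scorecard <- list(scenario = truth$name, seed = truth$seed,
                    tolerances = tol, checks = checks,
                    pass = all(vapply(checks, function(c)
                      isTRUE(c$pass), TRUE)))
  write_json_file(scorecard, file.path(analysis_dir, "scorecard.json"))
  invisible(scorecard)
}

#' Command-line entry point
#'
#' Verbs: `simulate`, `analyze`, `recover`, `report`. See the package
#' README; an executable wrapper ships in `inst/exec/fretwave`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
fretwave_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fretwave <verb> [options]",
    "  simulate --preset NAME | --config FILE.yaml  --out DIR  [--seed N]",
    "  analyze  --in DIR --out DIR  [--skip-photobleach] [--seed N]",
    "  recover  --scenario DIR --analysis DIR",
    "  report   --analysis DIR",
    "common: --log-level DEBUG|INFO|WARN", sep = "\n")
  if (!length(args)) {
    cat(usage, "\n")
    return(invisible(1L))
  }
  verb <- args[1]
  opt <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (key %in% c("skip-photobleach")) {
      opt[[key]] <- TRUE
      i <- i + 1L
    } else {
      opt[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  if (!is.null(opt[["log-level"]]))
    options(fretwave.log_level = opt[["log-level"]])
  switch(verb,
    simulate = {
      cfg <- if (!is.null(opt$preset)) {
        preset_config(opt$preset, seed = opt$seed)
      } else {
        c2 <- config_from_list(yaml::read_yaml(opt$config))
        if (!is.null(opt$seed)) c2$seed <- as.integer(opt$seed)
        c2
      }
      fw_simulate(cfg, opt$out)
    },
    analyze = fw_analyze(opt[["in"]], opt$out,
                         photobleach = !isTRUE(opt[["skip-photobleach"]])),
    recover = print(jsonlite::toJSON(
      fw_recover(opt$scenario, opt$analysis), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)),
    report = cat(readLines(file.path(opt$analysis, "report.json")),
                 sep = "\n"),
    stop("unknown verb: ", verb, "\n", usage)
  )
  invisible(0L)
}
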