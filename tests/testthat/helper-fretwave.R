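# Shared fixtures: everything is generated in code at test time.

options(fretwave.log_level = "WARN")

# A small, fast scenario: 48 x 48 px (24 um) cell of radius 8 um with 8 edge
# sections. Override any scenario_config() argument via ...
tiny_config <- function(..., noise = FALSE, n_frames = 30L, seed = 42L) {
  args <- utils::modifyList(
    list(grid = c(48L, 48L), pixel_size = 0.5, frame_interval = 1,
         n_frames = n_frames, seed = seed,
         cell = list(center = c(12, 12), radius = 8, n_sections = 8L),
         noise = noise, name = "tiny"),
    list(...))
  do.call(scenario_config, args)
}

# Nuisance set with every nuisance switched off (identity acquisition).
no_nuisances <- function(...) {
  utils::modifyList(
    list(shading = list(type = "bowl",
                        strength = c(donor = 0, acceptor = 0),
                        offset_frac = c(donor = 0, acceptor = 0)),
         background = c(donor = 0, acceptor = 0),
         alpha = 0, beta = 0, bleach = c(donor = 0, acceptor = 0),
         gain = 0.5, read_noise = 0, calibration = 1, rho = 1, x_acc = 0),
    list(...))
}

# Hand-built ratio movie for unit tests of edge/wave operations that do not
# need the full correction chain. `support` defaults to a two-level image
# tracking defined-ness (1000 inside, 0 outside) with thresholds at 500.
fake_ratio_movie <- function(ratio, defined = NULL, support = NULL,
                             thresholds = NULL, pixel_size = 0.5,
                             frame_interval = 1) {
  if (is.null(defined)) defined <- !is.na(ratio)
  if (is.null(support)) support <- ifelse(defined, 1000, 0)
  if (is.null(thresholds)) thresholds <- rep(500, dim(ratio)[1])
  structure(list(ratio = ratio, defined = defined, support = support,
                 thresholds = thresholds,
                 donor_floors = rep(0, dim(ratio)[1]),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 provenance = list()), class = "ratio_movie")
}

# Memoized full preset runs shared between acceptance tests (simulate +
# analyze once per preset in the test session).
.preset_cache <- new.env(parent = emptyenv())
preset_run <- function(name, seed) {
  key <- paste0(name, "_", seed)
  if (!is.null(.preset_cache[[key]])) return(.preset_cache[[key]])
  scn_dir <- file.path(tempdir(), paste0("scn_", key))
  out_dir <- file.path(tempdir(), paste0("out_", key))
  fw_simulate(name, scn_dir, seed = seed)
  report <- fw_analyze(scn_dir, out_dir)
  scorecard <- fw_recover(scn_dir, out_dir)
  res <- list(scn_dir = scn_dir, out_dir = out_dir, report = report,
              scorecard = scorecard)
  .preset_cache[[key]] <- res
  res
}

# normalized class means from an in-memory report as a named vector
report_class_means <- function(report) {
  df <- do.call(rbind, lapply(report$class_summary, as.data.frame))
  stats::setNames(df$normalized_mean, df$class)
}

# independent autocorrelation-peak period oracle: lag of the first local
# maximum of the sample ACF beyond lag zero
acf_period_oracle <- function(x, dt = 1) {
  n <- length(x)
  a <- stats::acf(x, lag.max = n - 2, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  cand <- which(diff(sign(diff(a))) < 0) + 1L  # local maxima (1-based lag+1)
  cand <- cand[cand > 2]
  if (!length(cand)) return(NA_real_)
  (cand[1] - 1) * dt
}

# ordinary-least-squares through-origin slope: the bleedthrough test oracle
ols_origin_slope <- function(x, y) sum(x * y) / sum(x * x)
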