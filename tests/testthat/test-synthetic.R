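# Forward simulator: geometry, activity field, rendering, scenario I/O.

test_that("static schedule gives an identical mask every frame", {
  cfg <- tiny_config(n_frames = 6L)
  geom <- simulate_geometry(cfg)
  m <- geometry_mask(geom)
  for (t in 2:6) expect_identical(m[t, , ], m[1, , ])
  expect_true(all(geom$edge_um == cfg$cell$radius))
})

test_that("scheduled edge motion matches the integral of the velocity schedule", {
  # +0.1 um/s at 0.5 um/px for 100 s -> 20 px displacement at the last frame
  cfg <- tiny_config(
    grid = c(96L, 96L), n_frames = 101L,
    cell = list(center = c(24, 24), radius = 10, n_sections = 8L),
    edge_schedule = data.frame(section = 1, velocity = 0.1,
                               start = 0, stop = 1000))
  geom <- simulate_geometry(cfg)
  disp_px <- (geom$edge_um[1, 101] - geom$edge_um[1, 1]) / cfg$pixel_size
  expect_equal(disp_px, 20)
  expect_true(all(geom$edge_um[2:8, ] == 10))

  # retraction at -0.05 um/s for 300 s: monotone decrease totalling -15 um
  cfg2 <- tiny_config(
    grid = c(96L, 96L), n_frames = 301L,
    cell = list(center = c(24, 24), radius = 20, n_sections = 8L),
    edge_schedule = data.frame(section = 3, velocity = -0.05,
                               start = 0, stop = 300))
  geom2 <- simulate_geometry(cfg2)
  trace <- geom2$edge_um[3, ]
  expect_true(all(diff(trace) < 0))
  expect_equal(trace[301] - trace[1], -15)
})

test_that("a schedule that exits the grid errors naming section and frame", {
  cfg <- tiny_config(
    n_frames = 200L,
    edge_schedule = data.frame(section = 2, velocity = 0.1,
                               start = 0, stop = 500))
  expect_error(simulate_geometry(cfg), "section 2")
  expect_error(simulate_geometry(cfg), "frame")
})

test_that("null wave and hotspots give a pure-baseline field; wave is periodic", {
  cfg <- tiny_config(n_frames = 25L,
                     activity = list(baseline = 1.3,
                                     wave = list(period = 8, wavelength = 4,
                                                 amplitude = 0,
                                                 direction = c(1, 0))))
  geom <- simulate_geometry(cfg)
  act <- simulate_activity_field(cfg, geom)
  expect_true(all(act == 1.3))

  cfg2 <- tiny_config(n_frames = 25L,
                      activity = list(baseline = 1,
                                      wave = list(period = 8, wavelength = 4,
                                                  amplitude = 0.25,
                                                  direction = c(1, 0))))
  act2 <- simulate_activity_field(cfg2, simulate_geometry(cfg2))
  # static geometry, no ramp: t and t + T frames are identical
  expect_equal(act2[1, , ], act2[9, , ], tolerance = 1e-12)
  expect_equal(act2[5, , ], act2[13, , ], tolerance = 1e-12)
})

test_that("the wave crest advances wavelength * dt / period per frame", {
  lam <- 6; Tper <- 30
  cfg <- tiny_config(
    grid = c(96L, 96L), n_frames = 21L,
    cell = list(center = c(24, 24), radius = 20, n_sections = 4L),
    activity = list(baseline = 1,
                    wave = list(period = Tper, wavelength = lam,
                                amplitude = 0.3, direction = c(1, 0))))
  geom <- simulate_geometry(cfg)
  act <- simulate_activity_field(cfg, geom)
  row <- round(24 / cfg$pixel_size) + 1  # scan along the center row
  xs <- (seq_len(96) - 1) * cfg$pixel_size
  near <- which(abs(xs - 24) <= lam / 2)  # one wavelength window
  crest_x <- vapply(seq_len(21), function(t)
    xs[near][which.max(act[t, row, near])], 0)
  # over 15 frames the crest advances 15 * lam / Tper; within the finite
  # window the crest position wraps modulo the wavelength, so compare the
  # circular distance, within one pixel
  adv <- (crest_x[16] - crest_x[1]) - 15 * lam / Tper
  circ <- abs(((adv + lam / 2) %% lam) - lam / 2)
  expect_lt(circ, cfg$pixel_size + 1e-9)
})

test_that("unresolvable wavelength and negative nuisances are rejected", {
  expect_error(tiny_config(activity = list(
    baseline = 1, wave = list(period = 10, wavelength = 0.9, amplitude = 0.1,
                              direction = c(1, 0)))), "unresolvable")
  expect_error(tiny_config(nuisances = list(alpha = -0.2)), "negative nuisance")
  cfg <- tiny_config(n_frames = 5L)
  geom <- simulate_geometry(cfg)
  act <- simulate_activity_field(cfg, geom)
  expect_error(render_channels(act, geom, no_nuisances(rho = -5), noise = FALSE),
               "negative nuisance")
})

test_that("identity configuration renders acceptor equal to donor", {
  cfg <- tiny_config(n_frames = 4L)
  geom <- simulate_geometry(cfg)
  act <- simulate_activity_field(cfg, geom)  # baseline 1
  ch <- render_channels(act, geom, no_nuisances(), seed = 1, noise = FALSE)
  expect_equal(ch$acceptor$data, ch$donor$data, tolerance = 1e-14)
})

test_that("alpha bleedthrough adds exactly alpha * donor to the raw acceptor", {
  cfg <- tiny_config(n_frames = 3L,
                     activity = list(baseline = 1.4))
  geom <- simulate_geometry(cfg)
  act <- simulate_activity_field(cfg, geom)
  nuis <- no_nuisances(alpha = 0.6, rho = 100)
  ch <- render_channels(act, geom, nuis, seed = 1, noise = FALSE)
  true_fret <- 100 * geom$coverage * act
  expect_equal(ch$acceptor$data, true_fret + 0.6 * ch$donor$data,
               tolerance = 1e-12)
})

test_that("noise-free donor conserves exp(-k t) decay to 1e-6 relative", {
  k <- 0.002
  cfg <- tiny_config(n_frames = 40L,
                     nuisances = no_nuisances(bleach = c(donor = k,
                                                         acceptor = 0),
                                              rho = 5000))
  geom <- simulate_geometry(cfg)
  act <- simulate_activity_field(cfg, geom)
  ch <- render_channels(act, geom, cfg$nuisances, seed = 1, noise = FALSE)
  m <- geometry_mask(geom)
  totals <- vapply(seq_len(40), function(t) sum(ch$donor$data[t, , ][m[t, , ]]), 0)
  expected <- totals[1] * exp(-k * (seq_len(40) - 1))
  expect_lt(max(abs(totals - expected) / expected), 1e-6)
})

test_that("true activity trace in a wave ROI is periodic at lag T", {
  Tper <- 20
  cfg <- tiny_config(
    grid = c(96L, 96L), n_frames = 200L,
    cell = list(center = c(24, 24), radius = 20, n_sections = 4L),
    activity = list(baseline = 1,
                    wave = list(period = Tper, wavelength = 5,
                                amplitude = 0.2, direction = c(-1, 0))))
  geom <- simulate_geometry(cfg)
  act <- simulate_activity_field(cfg, geom)
  # ROI-mean true activity at a point inside the wave region
  rows <- 47:50; cols <- 58:61
  trace <- vapply(seq_len(200), function(t) mean(act[t, rows, cols]), 0)
  lag <- acf_period_oracle(trace, dt = cfg$frame_interval)
  expect_lte(abs(lag - Tper), cfg$frame_interval)
})

test_that("identical config + seed reproduces the realization bit-exactly", {
  cfg <- tiny_config(noise = TRUE, n_frames = 5L, seed = 99L)
  s1 <- simulate_scenario(cfg, controls = FALSE)
  s2 <- simulate_scenario(cfg, controls = FALSE)
  expect_identical(s1$donor$data, s2$donor$data)
  expect_identical(s1$acceptor$data, s2$acceptor$data)

  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_scenario(s1, d1)
  write_scenario(s2, d2)
  for (f in c("donor.tif", "acceptor.tif")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
})

test_that("scenario write/read round-trips stacks and sidecars", {
  cfg <- tiny_config(noise = TRUE, n_frames = 4L, seed = 5L,
                     activity = list(baseline = 1,
                                     wave = list(period = 9, wavelength = 4,
                                                 amplitude = 0.1,
                                                 direction = c(1, 0))))
  scn <- simulate_scenario(cfg)
  dir <- file.path(tempdir(), "rt_scn")
  write_scenario(scn, dir)
  back <- read_scenario(dir)
  expect_identical(back$donor$data, scn$donor$data)
  expect_identical(back$acceptor$data, scn$acceptor$data)
  expect_equal(back$donor$pixel_size, cfg$pixel_size)
  # sidecar bookkeeping: the truth period equals the configured wave period
  expect_equal(back$truth$wave_period_s, 9)
  expect_equal(back$config$activity$wave$period, 9)
  expect_gt(length(back$rois), 0)
})

test_that("full-chain round-trip recovers the seeded activity field", {
  mk <- function(noise, seed = 42L) {
    cfg <- tiny_config(
      grid = c(96L, 96L), n_frames = 30L, noise = noise, seed = seed,
      cell = list(center = c(24, 24), radius = 16, n_sections = 8L),
      activity = list(baseline = 1,
                      hotspots = list(list(center = c(28, 24), radius = 3,
                                           amplitude = 0.4, t_on = 0)),
                      wave = list(period = 10, wavelength = 5, amplitude = 0.2,
                                  direction = c(-1, 0),
                                  region = list(center = c(24, 24), radius = 10))))
    scn <- simulate_scenario(cfg)
    chain <- apply_correction_chain(
      scn$donor, scn$acceptor,
      flatfields = scn$shading, controls = scn$controls, seed = 1)
    def <- chain$ratio$defined
    err <- abs(chain$ratio$ratio[def] - scn$activity[def]) / scn$activity[def]
    mean(err)
  }
  expect_lt(mk(noise = FALSE), 0.02)  # noise-free: < 2 %
  expect_lt(mk(noise = TRUE), 0.05)   # default noise: < 5 %
})
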