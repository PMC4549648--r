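# Ratiometric correction chain: shading/background, photobleach,
# bleedthrough, masking, ratio, and chain-level invariants.

test_that("shading/background correction inverts the forward model exactly", {
  H <- 20L; W <- 24L
  stack <- channel_stack(array(50, c(3, H, W)), "donor", 0.5, 1)
  # uniform flatfield = 1, background 0 -> identity
  out <- correct_shading_background(stack, matrix(1, H, W), background = 0)
  expect_equal(out$data, stack$data)

  # input = shading * c + bg with known bg -> uniform image c
  set.seed(3)
  shade <- matrix(exp(0.1 * rnorm(H * W)), H, W)
  shade <- shade / mean(shade)
  cval <- 700
  raw <- array(NA_real_, c(2, H, W))
  for (t in 1:2) raw[t, , ] <- shade * cval + 40
  stack2 <- channel_stack(raw, "donor", 0.5, 1)
  out2 <- correct_shading_background(stack2, shade, background = 40)
  expect_equal(max(abs(out2$data - cval)), 0, tolerance = 1e-9)

  expect_error(correct_shading_background(stack2, shade * 0, background = 0),
               "strictly positive")
})

test_that("bowl shading on a uniform scene corrects to CV < 1 % (noise-free)", {
  # the bowl is offset so the cell sits on its slope
  cfg <- tiny_config(n_frames = 3L,
                     nuisances = no_nuisances(
                       shading = list(type = "bowl",
                                      strength = c(donor = 0.2, acceptor = 0.2),
                                      offset_frac = c(donor = 0.5,
                                                      acceptor = 0.5)),
                       rho = 4000))
  geom <- simulate_geometry(cfg)
  act <- simulate_activity_field(cfg, geom)
  ch <- render_channels(act, geom, cfg$nuisances, seed = 1, noise = FALSE)
  corr <- correct_shading_background(ch$donor, ch$shading$donor, background = 0)
  inside <- geometry_mask(geom)[1, , ] & geom$r_grid < cfg$cell$radius - 1
  vals <- corr$data[1, , ][inside]
  expect_lt(stats::sd(vals) / mean(vals), 0.01)
  # and without the correction the bowl leaves visible structure
  raw_vals <- ch$donor$data[1, , ][inside]
  expect_gt(stats::sd(raw_vals) / mean(raw_vals), 0.01)
})

test_that("photobleach fit is exact on noise-free decay and inert on constants", {
  H <- 16L; W <- 16L; Tn <- 40L
  mask <- array(TRUE, c(Tn, H, W))
  const <- channel_stack(array(500, c(Tn, H, W)), "donor", 0.5, 1)
  res0 <- correct_photobleach(const, mask)
  expect_equal(res0$k, 0)
  expect_equal(res0$stack$data, const$data)

  k <- 0.001
  decay <- array(NA_real_, c(Tn, H, W))
  for (t in seq_len(Tn)) decay[t, , ] <- 800 * exp(-k * (t - 1))
  st <- channel_stack(decay, "donor", 0.5, 1)
  res <- correct_photobleach(st, mask)
  expect_lt(abs(res$k - k), 1e-6)
  means <- vapply(seq_len(Tn), function(t) mean(res$stack$data[t, , ]), 0)
  expect_lt(max(abs(means - means[1]) / means[1]), 1e-6)

  expect_error(correct_photobleach(
    channel_stack(array(1, c(3, H, W)), "donor", 0.5, 1), mask[1:3, , ]),
    "T >= 5")
  empty <- mask
  empty[7, , ] <- FALSE
  expect_error(correct_photobleach(st, empty), "empty mask at frame 6")
})

test_that("photobleach rate is recovered within 10 % under default noise", {
  k <- 5e-4
  recovered <- vapply(1:20, function(s) {
    cfg <- tiny_config(
      grid = c(32L, 32L), n_frames = 300L, noise = TRUE, seed = 1000L + s,
      cell = list(center = c(8, 8), radius = 5.5, n_sections = 4L),
      nuisances = no_nuisances(bleach = c(donor = k, acceptor = 0),
                               rho = 6000, read_noise = 2))
    scn <- simulate_scenario(cfg, controls = FALSE)
    mask <- compute_mask(scn$donor, clean = FALSE)
    correct_photobleach(scn$donor, mask, force = TRUE)$k
  }, 0)
  expect_lt(abs(mean(recovered) - k) / k, 0.10)
  expect_gt(mean(abs(recovered - k) / k < 0.10), 0.8)
})

test_that("bleedthrough estimation matches exact slopes and the OLS oracle", {
  H <- 50L; W <- 40L
  set.seed(11)
  donor_img <- matrix(runif(H * W, 500, 3000), H, W)
  mk <- function(x) channel_stack(array(x, c(1, H, W)), "donor", 0.5, 1)
  # exact proportionality -> alpha recovered exactly
  bt <- estimate_bleedthrough(list(donor = mk(donor_img),
                                   acceptor = mk(0.6 * donor_img)))
  expect_equal(bt$alpha, 0.6, tolerance = 1e-12)
  expect_true(is.na(bt$beta))

  # 1 % multiplicative noise on 1e4 pixels: alpha within 0.35 +/- 0.01 and
  # within 1 bootstrap SE of the OLS-through-origin oracle on the same pixels
  H2 <- 100L; W2 <- 100L
  set.seed(12)
  x <- matrix(runif(H2 * W2, 1000, 4000), H2, W2)
  y <- 0.35 * x * (1 + 0.01 * rnorm(H2 * W2))
  bt2 <- estimate_bleedthrough(list(donor = mk2 <- channel_stack(
    array(x, c(1, H2, W2)), "donor", 0.5, 1),
    acceptor = channel_stack(array(y, c(1, H2, W2)), "donor", 0.5, 1)))
  expect_lt(abs(bt2$alpha - 0.35), 0.01)
  thr <- otsu_threshold(as.vector(x))
  sel <- as.vector(x) >= thr
  ols <- ols_origin_slope(as.vector(x)[sel], as.vector(y)[sel])
  expect_lt(abs(bt2$alpha - ols), max(bt2$alpha_se, 1e-4))

  expect_error(estimate_bleedthrough(list(
    donor = channel_stack(array(1, c(1, 5, 5)), "donor", 0.5, 1),
    acceptor = channel_stack(array(1, c(1, 5, 5)), "donor", 0.5, 1))),
    "too few")
})

test_that("FRET bleedthrough correction is exact arithmetic", {
  mk <- function(v) channel_stack(array(v, c(2, 4, 4)), "donor", 0.5, 1)
  out <- correct_fret(mk(100), mk(50), mk(20), alpha = 0.6, beta = 0.5)
  expect_true(all(out$data == 60))  # 100 - 30 - 10
  expect_true(attr(out, "bleedthrough")$beta_term_applied)
  out2 <- correct_fret(mk(100), mk(50), alpha = 0, beta = 0)
  expect_true(all(out2$data == 100))
  expect_false(attr(out2, "bleedthrough")$beta_term_applied)
  expect_error(correct_fret(mk(1), channel_stack(array(1, c(2, 5, 5)),
                                                 "donor", 0.5, 1), alpha = 0),
               "mismatch")
})

test_that("masking is exact on a two-level frame and flags constants", {
  H <- 30L; W <- 30L
  fr <- matrix(10, H, W)
  fr[10:20, 8:25] <- 1000
  st <- channel_stack(array(fr, c(1, H, W)), "donor", 0.5, 1)
  cm <- compute_mask(st)
  expect_identical(cm$mask[1, , ], fr == 1000)
  expect_false(cm$degenerate[1])

  cm0 <- compute_mask(channel_stack(array(7, c(1, H, W)), "donor", 0.5, 1))
  expect_true(cm0$degenerate[1])
  expect_false(any(cm0$mask))
})

test_that("mask cleanup keeps the largest component and fills holes", {
  H <- 30L; W <- 30L
  fr <- matrix(0, H, W)
  fr[5:25, 5:25] <- 1000
  fr[12:14, 12:14] <- 0      # hole inside the cell
  fr[2:3, 27:28] <- 1000     # small speck elsewhere
  st <- channel_stack(array(fr, c(1, H, W)), "donor", 0.5, 1)
  cm <- compute_mask(st)
  expect_true(all(cm$mask[1, 12:14, 12:14]))  # hole filled
  expect_false(any(cm$mask[1, 2:3, 27:28]))   # speck dropped
})

test_that("raising the threshold never grows the mask", {
  set.seed(20)
  fr <- matrix(runif(400, 0, 100), 20, 20)
  thr <- sort(runif(8, 5, 95))
  for (i in seq_len(length(thr) - 1)) {
    lo <- fr >= thr[i]
    hi <- fr >= thr[i + 1]
    expect_true(all(lo | !hi))  # hi subset of lo
  }
})

test_that("ratio is defined only in-mask, positive, and exact on equality", {
  H <- 12L; W <- 12L
  donor <- array(1000, c(2, H, W))
  mask <- array(FALSE, c(2, H, W))
  mask[, 4:9, 4:9] <- TRUE
  dn <- channel_stack(donor, "donor", 0.5, 1)
  ft <- channel_stack(donor, "corrected_fret", 0.5, 1)
  rm_ <- compute_ratio(ft, dn, mask, eps = 0.05)
  expect_true(all(rm_$ratio[mask] == 1))
  expect_true(all(is.na(rm_$ratio[!mask])))
  expect_true(all(is.finite(rm_$ratio[rm_$defined])))
  expect_true(all(rm_$ratio[rm_$defined] > 0))
  expect_error(compute_ratio(ft, dn, mask, eps = 1.5), "eps")
})

test_that("ratio is invariant to a uniform rescaling of both channels", {
  cfg <- tiny_config(n_frames = 4L, noise = FALSE,
                     activity = list(baseline = 1.2))
  scn <- simulate_scenario(cfg, controls = FALSE)
  run <- function(scale) {
    d <- channel_stack(scn$donor$data * scale, "donor", 0.5, 1)
    a <- channel_stack(scn$acceptor$data * scale, "raw_acceptor", 0.5, 1)
    ch <- apply_correction_chain(d, a, flatfields = scn$shading,
                                 alpha = cfg$nuisances$alpha,
                                 photobleach = FALSE, register = FALSE)
    ch$ratio
  }
  r1 <- run(1)
  r2 <- run(3.7)
  expect_equal(r1$defined, r2$defined)
  expect_equal(r1$ratio[r1$defined], r2$ratio[r1$defined], tolerance = 1e-9)
})

test_that("channel registration recovers a known integer shift", {
  cfg <- tiny_config(n_frames = 3L, noise = FALSE)
  scn <- simulate_scenario(cfg, controls = FALSE)
  shifted <- scn$acceptor$data
  for (t in 1:3) shifted[t, , ] <- scn$acceptor$data[
    t, c(47:48, 1:46), c(3:48, 1:2)]  # dy = +2, dx = -2 circular
  reg <- register_channels(scn$donor,
                           channel_stack(shifted, "raw_acceptor", 0.5, 1))
  expect_equal(unname(reg$shift), c(-2, 2))  # correction applied to acceptor
  expect_equal(reg$acceptor$data, scn$acceptor$data)
  set.seed(1)
  noise_stack <- channel_stack(
    array(runif(prod(dim(scn$acceptor$data)), 0, 100),
          dim(scn$acceptor$data)), "raw_acceptor", 0.5, 1)
  expect_error(register_channels(scn$donor, noise_stack), "unregistered")
})

test_that("mask from the chain overlaps the true mask at Jaccard >= 0.95", {
  cfg <- tiny_config(grid = c(96L, 96L), n_frames = 10L, noise = TRUE,
                     cell = list(center = c(24, 24), radius = 16,
                                 n_sections = 8L))
  scn <- simulate_scenario(cfg, controls = FALSE)
  chain <- apply_correction_chain(scn$donor, scn$acceptor,
                                  flatfields = scn$shading,
                                  alpha = cfg$nuisances$alpha, seed = 1)
  tm <- geometry_mask(scn$geometry)
  jac <- vapply(seq_len(10), function(t) {
    a <- tm[t, , ]; b <- chain$mask$mask[t, , ]
    sum(a & b) / sum(a | b)
  }, 0)
  expect_gte(min(jac), 0.95)
})
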