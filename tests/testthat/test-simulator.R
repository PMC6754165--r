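# Synthetic phantoms, speckle statistics, defocus rendering, multiplexed
# frames and mask-response simulation.

test_that("phantom generation is seeded, counted and bounded", {
  a <- make_phantom(seed = 42)
  b <- make_phantom(seed = 42)
  expect_identical(a$density, b$density)
  g20 <- make_phantom(beads = list(n = 20, radius = 0.3, intensity = 1),
                      seed = 1)
  expect_equal(nrow(g20$ground_truth), 20)
  d <- dim(g20$density)
  expect_true(all(g20$ground_truth$row >= 1 & g20$ground_truth$row <= d[1]))
  expect_true(all(g20$ground_truth$col >= 1 & g20$ground_truth$col <= d[2]))
  # beads never touch the lateral boundary
  r_px <- 0.3 / 0.108
  expect_true(all(g20$ground_truth$row > r_px &
                    g20$ground_truth$row < d[1] - r_px + 1))
  # slab-only phantom is constant
  slab <- make_phantom(beads = NULL, slab = 0.7, seed = 1)
  expect_true(all(slab$density == 0.7))
  expect_error(make_phantom(shape = c(8, 8, 4), beads = list(
    n = 1, radius = 10, intensity = 1)), "radius")
})

test_that("speckle fields are seeded, unit-mean and exponentially distributed", {
  s1 <- generate_speckle(c(128, 128), grain_size = 4, seed = 3)
  s2 <- generate_speckle(c(128, 128), grain_size = 4, seed = 3)
  expect_identical(s1$S, s2$S)
  expect_equal(mean(s1$S), 1, tolerance = 1e-9)
  expect_true(all(s1$S >= 0))
  # fully developed speckle: intensity ~ Exp(1); KS distance small at n=1e4
  big <- generate_speckle(c(256, 256), grain_size = 4, seed = 7)
  set.seed(1)
  samp <- sample(big$S, 1e4)
  ks <- suppressWarnings(ks.test(samp, "pexp", 1))
  expect_lt(unname(ks$statistic), 0.05)
  expect_gt(big$contrast, 0.8) # near unit contrast
  # grain approaching the field size: still unit mean
  coarse <- generate_speckle(c(64, 64), grain_size = 64, seed = 2)
  expect_equal(mean(coarse$S), 1, tolerance = 1e-9)
})

test_that("plane rendering separates in-focus and out-of-focus light", {
  # single bright bead exactly at focus
  ph <- make_phantom(shape = c(48, 48, 21), voxel = c(0.108, 0.108, 0.4),
                     beads = list(n = 1, radius = 0.3, intensity = 5,
                                  z_range = c(4.1, 4.3)), seed = 3)
  z_bead <- ph$ground_truth$z[1]
  at <- render_plane_images(ph, z_bead, NULL, psf_params(0.15, 1))
  expect_lt(max(at$out_focus), 1e-9 * max(at$in_focus))
  expect_equal(at$total, at$in_focus + at$out_focus)
  # same bead viewed 5 um out of focus: all light is out-of-focus and the
  # blurred blob conserves total energy within 2%
  off <- render_plane_images(ph, z_bead + 5, NULL, psf_params(0.15, 1))
  expect_lt(max(off$in_focus), 1e-9 * max(at$in_focus))
  expect_lt(abs(sum(off$total) - sum(at$total)) / sum(at$total), 0.02)
  expect_lt(max(off$total), max(at$total)) # dimmer, wider blob
})

test_that("speckle rendering satisfies the two-component imaging model exactly", {
  ph <- standard_phantom(seed = 11, n_beads = 5)
  S <- generate_speckle(c(64, 64), grain_size = 8, seed = 4)
  u <- render_plane_images(ph, 8, NULL, psf_params(0.15, 1))
  s <- render_plane_images(ph, 8, S, psf_params(0.15, 1))
  expect_lt(max(abs((s$total - u$total) - (S$S - 1) * u$in_focus)), 1e-10)
})

test_that("an empty phantom renders zero images with a warning", {
  ph <- make_phantom(shape = c(16, 16, 4), beads = NULL, slab = 0, seed = 1)
  expect_warning(out <- render_plane_images(ph, 1), "empty")
  expect_true(all(out$total == 0))
})

test_that("multiplexed frames place each plane in its tile, sharpest at its depth", {
  ph <- standard_phantom(seed = 13, n_beads = 1)
  mplan <- mfm_default_plan()
  grid <- tile_grid(3, 3, tile_px = 64)
  # noise off, 1-plane plan: single tile equals the direct render
  p1 <- plan_from_spacings(numeric(0), anchor = "first",
                           train = optical_train(), tile_layout = c(1, 1),
                           tile_px = 64)
  f1 <- render_multiplexed_frame(ph, p1, tile_grid(1, 1, 64),
                                 focus_z = 9)
  direct <- render_plane_images(ph, 9, NULL, psf_params())$total
  expect_equal(f1, direct)
  # bead appears sharpest in the tile whose delta_l matches its depth
  z_bead <- ph$ground_truth$z[1]
  focus_z <- z_bead - 0.8 # plane at delta_l = +0.8 is conjugate to the bead
  fr <- render_multiplexed_frame(ph, mplan, grid, focus_z = focus_z)
  tiles <- crop_tiles(fr, grid)
  sharp <- vapply(tiles, function(tl) {
    gx <- diff(tl)
    gy <- t(diff(t(tl)))
    sum(gx^2) + sum(gy^2)
  }, numeric(1))
  dl_sorted <- sort(mplan$planes$delta_l)
  expect_equal(dl_sorted[which.max(sharp)], 0.8)
  # doubling the phantom doubles the frame (noise off)
  ph2 <- ph
  ph2$density <- 2 * ph2$density
  fr2 <- render_multiplexed_frame(ph2, mplan, grid, focus_z = focus_z)
  expect_equal(fr2, 2 * fr, tolerance = 1e-12)
})

test_that("mask response localizes energy and respects conservation", {
  tr <- small_train()
  plan <- small_plan()
  # flat mask, on-axis probe: single focused spot in the centre tile at dL=0
  flat <- hilomfm:::new_phase_mask(matrix(0, 128, 128), tr, aperture_mask(tr))
  resp <- simulate_mask_response(flat, plan, tr, keep_intensity = TRUE)
  centre_plane <- which(plan$planes$delta_L == 0)
  expect_gt(resp$energy[centre_plane, centre_plane] / resp$probe_energy, 0.9)
  I0 <- resp$intensity[[centre_plane]]
  pk <- which(I0 == max(I0), arr.ind = TRUE)
  expect_lt(max(abs(pk[1, ] - (floor(128 / 2) + 1))), 1.5)
  # single off-axis lens phase: argmax of the energy table is its own cell
  plan2 <- plan_from_spacings(c(1.0), anchor = "first", train = tr,
                              tile_layout = c(1, 3), tile_px = 120,
                              tile_rc = matrix(c(0, 1, 0, 2), 2, byrow = TRUE),
                              weights = c(0, 1))
  phi <- init_superposition(plan2)
  r2 <- simulate_mask_response(phi, plan2, tr)
  expect_equal(unname(which(r2$energy == max(r2$energy), arr.ind = TRUE)[1, ]),
               c(2, 2))
  # rows never exceed the probe energy (losses only outside tiles)
  expect_true(all(rowSums(resp$energy) <= resp$probe_energy * (1 + 1e-9)))
  expect_true(all(rowSums(r2$energy) <= r2$probe_energy * (1 + 1e-9)))
})

test_that("scan simulation is deterministic for a fixed seed", {
  ph <- standard_phantom(seed = 3, n_beads = 2)
  mplan <- mfm_default_plan()
  grid <- tile_grid(3, 3, tile_px = 64)
  acq <- plan_acquisition(3.6, 0.4, 9, 2)
  f1 <- simulate_axial_scan(ph, mplan, grid, acq, seed = 5)
  f2 <- simulate_axial_scan(ph, mplan, grid, acq, seed = 5)
  expect_identical(f1[[1]]$speckle, f2[[1]]$speckle)
  expect_identical(f1[[1]]$uniform, f2[[1]]$uniform)
  # noise is reproducible too
  n1 <- render_multiplexed_frame(ph, mplan, grid, focus_z = 8,
                                 noise = list(photons = 100, read_sd = 0.01),
                                 seed = 9)
  n2 <- render_multiplexed_frame(ph, mplan, grid, focus_z = 8,
                                 noise = list(photons = 100, read_sd = 0.01),
                                 seed = 9)
  expect_identical(n1, n2)
})
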