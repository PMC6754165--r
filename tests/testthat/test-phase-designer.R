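# Multiplex planning and the weighted global Gerchberg-Saxton designer.

test_that("plan offsets are cumulative sums anchored as requested", {
  tr <- small_train()
  # nine planes at 0.4 um, centred: -4dz ... +4dz
  p9 <- plan_from_spacings(rep(0.4, 8), anchor = "center", train = tr,
                           tile_px = 120)
  expect_equal(p9$planes$delta_l, seq(-1.6, 1.6, by = 0.4))
  expect_equal(p9$planes$delta_L, 60^2 * p9$planes$delta_l)
  # degenerate one-plane plan
  p1 <- plan_from_spacings(numeric(0), anchor = "first", train = tr,
                           tile_layout = c(1, 1), tile_px = 120)
  expect_equal(p1$planes$delta_l, 0)
  expect_equal(p1$planes$delta_L, 0)
  # first-plane anchor cumulative sum
  p3 <- plan_from_spacings(c(0.5, 1.0), anchor = "first", train = tr,
                           tile_layout = c(1, 3), tile_px = 120)
  expect_equal(p3$planes$delta_l, c(0, 0.5, 1.5))
})

test_that("invalid plans are rejected", {
  tr <- small_train()
  expect_error(plan_from_spacings(c(0.4, -0.1), train = tr,
                                  tile_layout = c(1, 3), tile_px = 120),
               "positive")
  expect_error(plan_from_spacings(c(0.4, 0.4), anchor = "first", train = tr,
                                  tile_layout = c(1, 3), tile_px = 120,
                                  tile_rc = matrix(c(0, 0, 0, 1, 0, 1), 3, 2,
                                                   byrow = TRUE)),
               "duplicate")
  expect_error(plan_from_spacings(rep(0.4, 8), train = tr, tile_px = 120,
                                  weights = rep(1, 3)),
               "per plane")
  # zero-order plane must sit at delta_l = 0
  expect_error(plan_from_spacings(c(0.5, 1.0), anchor = "first", train = tr,
                                  tile_layout = c(1, 3), tile_px = 120,
                                  zero_order_plane = 2),
               "delta_l = 0")
})

test_that("single-plane superposition equals that plane's lens+tilt phase", {
  tr <- small_train()
  plan <- plan_from_spacings(c(2), anchor = "first", train = tr,
                             tile_layout = c(1, 3), tile_px = 120,
                             tile_rc = matrix(c(0, 1, 0, 2), 2, byrow = TRUE),
                             weights = c(0, 1))
  phi0 <- init_superposition(plan, gs_config())
  uv <- tile_centers(matrix(c(0, 2), 1), c(1, 3), 120, tr$camera_pitch)
  expected <- fresnel_lens_phase(tr, plan$planes$delta_L[2],
                                 c(uv[1, "u"], uv[1, "v"]), 0.55) %% (2 * pi)
  ap <- aperture_mask(tr)
  expect_lt(max(abs(phi0$phase[ap] - expected[ap])), 1e-9)
  expect_true(all(phi0$phase[!ap] == 0))
})

test_that("a tilt beyond the SLM Nyquist limit is rejected by name", {
  tr <- small_train()
  # a tile centre far beyond lambda f / (2 pitch) = 3437 um
  plan <- plan_from_spacings(c(0.4), anchor = "first", train = tr,
                             tile_layout = c(1, 9), tile_px = 600,
                             tile_rc = matrix(c(0, 0, 0, 8), 2, byrow = TRUE))
  expect_error(init_superposition(plan), "Nyquist")
})

test_that("two opposite tilts produce two dominant far-field spots", {
  tr <- small_train()
  plan <- plan_from_spacings(c(0.4), anchor = "center", train = tr,
                             tile_layout = c(1, 3), tile_px = 120,
                             tile_rc = matrix(c(0, 0, 0, 2), 2, byrow = TRUE))
  phi0 <- init_superposition(plan)
  resp <- simulate_mask_response(phi0, plan, tr)
  own <- diag(resp$energy) / resp$probe_energy
  expect_true(all(own > 0.2)) # each spot dominates its own tile
})

test_that("on-axis multifocal lens has axial intensity maxima near each delta_L", {
  tr <- optical_train(slm_shape = c(256, 256), slm_pitch = 16,
                      aperture_radius = 1500)
  dLs <- c(-50000, 0, 50000) # well separated against the ~10 mm axial spot
  phi <- Arg(Reduce(`+`, lapply(dLs, function(d)
    exp(1i * fresnel_lens_phase(tr, d, c(0, 0), lam_em)))))
  ap <- aperture_mask(tr)
  E0 <- matrix(0, 256, 256); E0[ap] <- 1
  E <- complex_field(E0 * exp(1i * phi) * ap, 16, lam_em)
  U <- fourier_lens_transform(E, tr$f_fourier)
  c0 <- floor(256 / 2) + 1
  zs <- seq(-60000, 60000, by = 2000)
  onax <- vapply(zs, function(z) {
    Ez <- fresnel_propagate(U, z)
    sum(Mod(Ez$field[(c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1)])^2)
  }, numeric(1))
  peaks <- zs[which(diff(sign(diff(onax))) == -2) + 1]
  for (d in dLs) {
    expect_true(any(abs(peaks - d) <= 5000))
  }
})

test_that("the GS loop leaves the phase untouched for max_iter = 1", {
  plan <- small_plan()
  phi0 <- init_superposition(plan)
  out <- wggs_optimize(plan, gs_config(max_iter = 1), phi0)
  d <- (out$phase - phi0$phase) %% (2 * pi)
  expect_lt(max(pmin(d, 2 * pi - d)), 1e-12)
})

test_that("with amplitude replacement disabled the phase is a fixed point", {
  plan <- small_plan()
  phi0 <- init_superposition(plan)
  out <- wggs_optimize(plan, gs_config(max_iter = 3), phi0,
                       amplitude_replacement = FALSE)
  ap <- phi0$aperture
  # phases agree up to wrap-around at the branch cut
  d <- (out$phase - phi0$phase) %% (2 * pi)
  d <- pmin(d, 2 * pi - d)
  expect_lt(max(d[ap]), 1e-8)
})

test_that("classical GS error is non-increasing for a single-plane target", {
  tr <- small_train()
  plan <- plan_from_spacings(numeric(0), anchor = "first", train = tr,
                             tile_layout = c(1, 1), tile_px = 120)
  # start away from the solution so the error has room to fall
  phi0 <- init_superposition(plan, gs_config(seed = 4, init_perturbation = 1))
  out <- wggs_optimize(plan, gs_config(max_iter = 12), phi0)
  mse <- out$provenance$convergence$mse
  expect_gte(length(mse), 10)
  expect_true(all(diff(mse) <= 1e-6))
})

test_that("GS refinement improves per-plane uniformity over the superposition mask", {
  plan <- small_plan()
  phi0 <- init_superposition(plan)
  mask <- wggs_optimize(plan, gs_config(max_iter = 16), phi0)
  r0 <- mask_report(phi0, plan)
  r1 <- mask_report(mask, plan)
  expect_lt(r1$uniformity_rsd, r0$uniformity_rsd)
  expect_gte(r1$uniformity_min_max, r0$uniformity_min_max)
  # every modulated tile receives energy
  act <- r1$per_plane$weight > 0
  expect_true(all(r1$per_plane$tile_energy_fraction[act] > 0))
})

test_that("errors on degenerate GS configurations", {
  plan <- small_plan()
  expect_error(gs_config(max_iter = 0), "max_iter")
  zero_w <- plan_from_spacings(rep(0.4, 8), train = small_train(),
                               tile_px = 120, weights = rep(0, 9))
  expect_error(wggs_optimize(zero_w, gs_config()), "weights are zero")
})

test_that("phase quantization is idempotent and nearly lossless at 256 levels", {
  plan <- small_plan()
  mask <- wggs_optimize(plan, gs_config(max_iter = 11))
  q1 <- quantize_phase(mask, 256)
  q2 <- quantize_phase(q1, 256)
  expect_equal(q1$phase, q2$phase)
  expect_true(all(q1$phase >= 0 & q1$phase < 2 * pi))
  # constant phase snaps to the nearest level
  tr128 <- small_train()
  flat <- quantize_phase(
    hilomfm:::new_phase_mask(matrix(pi, 128, 128), tr128,
                             matrix(TRUE, 128, 128)), 4)
  expect_equal(unique(as.vector(flat$phase)), pi)
  expect_error(quantize_phase(mask, 1), "levels")
  # per-plane energies move by < 2% relative at 256 levels
  r <- mask_report(mask, plan)
  rq <- mask_report(q1, plan)
  act <- r$per_plane$weight > 0
  rel <- abs(rq$per_plane$tile_energy_fraction[act] -
               r$per_plane$tile_energy_fraction[act]) /
    r$per_plane$tile_energy_fraction[act]
  expect_lt(max(rel), 0.02)
})

test_that("a flat mask sends essentially all energy to the zero-order tile", {
  plan <- small_plan()
  tr <- plan$train
  flat <- quantize_phase(
    hilomfm:::new_phase_mask(matrix(0, 128, 128), tr, aperture_mask(tr)), 2)
  r <- mask_report(flat, plan)
  expect_gt(r$zero_order_fraction, 0.9)
  expect_lt(r$diffracted_fraction, 0.1)
})

test_that("mirrored plans give axially mirrored simulated responses", {
  tr <- small_train()
  # two planes at delta_l = -/+0.5 um; the mirrored plan negates every
  # delta_l and reflects the tiles, which after reordering by ascending
  # delta_l is the same spacing list with the tile assignment swapped
  plan_f <- plan_from_spacings(c(1.0), anchor = "center", train = tr,
                               tile_layout = c(1, 3), tile_px = 120,
                               tile_rc = matrix(c(0, 0, 0, 2), 2, byrow = TRUE))
  plan_m <- plan_from_spacings(c(1.0), anchor = "center", train = tr,
                               tile_layout = c(1, 3), tile_px = 120,
                               tile_rc = matrix(c(0, 2, 0, 0), 2, byrow = TRUE))
  mask_f <- wggs_optimize(plan_f, gs_config(max_iter = 6))
  mask_m <- wggs_optimize(plan_m, gs_config(max_iter = 6))
  # plan_m negates delta_l (via the centred 2-plane anchor the offsets are
  # +/-0.5) and mirrors the tiles; its response table must be the reversed
  # response of the forward plan
  rf <- simulate_mask_response(mask_f, plan_f, tr)$energy
  rm <- simulate_mask_response(mask_m, plan_m, tr)$energy
  expect_lt(max(abs(rf - rm[2:1, 2:1])), 1e-6 * max(rf))
})

test_that("adaptive weights tighten uniformity on the nine-plane plan", {
  plan <- small_plan()
  static <- wggs_optimize(plan, gs_config(max_iter = 11))
  adapt <- wggs_optimize(plan, gs_config(max_iter = 11,
                                         adaptive_weights = TRUE))
  rs <- mask_report(static, plan)
  ra <- mask_report(adapt, plan)
  expect_lt(ra$uniformity_rsd, rs$uniformity_rsd * 1.5) # sanity: comparable
  expect_true(all(ra$per_plane$tile_energy_fraction[
    ra$per_plane$weight > 0] > 0))
})

test_that("mask export writes readable grayscale and float files", {
  plan <- small_plan()
  mask <- wggs_optimize(plan, gs_config(max_iter = 3))
  g <- tempfile(fileext = ".tif")
  fl <- tempfile(fileext = ".tif")
  lg <- tempfile(fileext = ".csv")
  export_phase_mask(mask, g, fl, lg)
  img <- read_image_stack(g)[[1]]
  expect_equal(dim(img), dim(mask$phase))
  flo <- read_image_stack(fl)[[1]]
  expect_lt(max(abs(flo * 2 * pi - mask$phase)), 1e-5)
  conv <- read.csv(lg)
  expect_true(all(c("iteration", "plane", "tile_energy", "mse") %in%
                    names(conv)))
  unlink(c(g, fl, lg))
})
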