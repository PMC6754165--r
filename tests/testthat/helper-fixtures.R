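# Shared fixtures, built in code.

lam_em <- 0.55 # emission wavelength used throughout (um)

# small optical train for fast design tests: same conventions as the default
# geometry, scaled to a 128^2 grid
small_train <- function(n = 128) {
  optical_train(slm_pitch = 16, slm_shape = c(n, n), aperture_radius = 900,
                camera_shape = c(512, 512))
}

# 9-plane plan on the small train (120-px tiles fit the conjugate grid)
small_plan <- function(dz = 0.4, n = 128) {
  plan_from_spacings(rep(dz, 8), anchor = "center", train = small_train(n),
                     tile_px = 120, zero_order_plane = 5)
}

# random band-limited complex field (content confined to low frequencies so
# paraxial propagation invariants hold on the discrete grid)
random_field <- function(n = 64, pitch = 8, seed = 1, bandlimit = 0.15) {
  set.seed(seed)
  z <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  f <- (((0:(n - 1)) + floor(n / 2)) %% n - floor(n / 2)) / n
  keep <- outer(abs(f) <= bandlimit, abs(f) <= bandlimit, "&")
  z <- fft(fft(z) * keep, inverse = TRUE) / (n * n)
  complex_field(z, pitch = pitch, wavelength = lam_em)
}

# synthetic HiLo pair obeying the two-component model exactly:
# I_u = I_in + I_out, I_s = S * I_in + I_out
model_pair <- function(I_in, I_out, S) {
  frame_pair(pmax(I_in + I_out, 0), pmax(S * I_in + I_out, 0))
}

# standard seeded bead phantom used by the end-to-end tests: 16 um of
# specimen in 45 slices, beads confined to the kept 40 sections
standard_phantom <- function(seed = 7, n_beads = 8) {
  make_phantom(shape = c(64, 64, 45), voxel = c(0.108, 0.108, 0.4),
               beads = list(n = n_beads, radius = 0.3, intensity = 1,
                            z_range = c(0.8, 15.2), min_separation = 1.5),
               slab = 0.05, seed = seed)
}

# pixel mask of the region far from every bead of a phantom
empty_region <- function(phantom, margin_px = 15) {
  d <- dim(phantom$density)
  gt <- phantom$ground_truth
  dmin <- matrix(Inf, d[1], d[2])
  for (b in seq_len(nrow(gt))) {
    dmin <- pmin(dmin, outer((seq_len(d[1]) - gt$row[b])^2,
                             (seq_len(d[2]) - gt$col[b])^2, "+"))
  }
  dmin > margin_px^2
}
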