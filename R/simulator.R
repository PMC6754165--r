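# Synthetic-data generator and optical forward model.

# FFT Gaussian blur with circular boundary; exact unit DC gain so the total
# intensity of each slice is conserved.
blur_gaussian <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  d <- dim(img)
  fy <- fft_freqs(d[1], 1)
  fx <- fft_freqs(d[2], 1)
  H <- exp(-2 * pi^2 * sigma_px^2 * outer(fy^2, fx^2, "+"))
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / length(img)
}

#' Defocus point-spread parameters
#'
#' Simplified incoherent defocus model: emission from a slice a distance
#' `|z - z_focus|` from the focal plane is blurred with a Gaussian kernel of
#' standard deviation `sigma(z) = sigma0 + slope * |z - z_focus|` (um),
#' i.e. the blur widens linearly with defocus as in a geometric cone model.
#'
#' @param sigma0 in-focus blur (um); the diffraction-limited spot scale.
#' @param slope blur growth per um of defocus (dimensionless).
#' @return an object of class `psf_params`.
#' @export
psf_params <- function(sigma0 = 0.15, slope = 1.0) {
  stopifnot(sigma0 >= 0, slope >= 0)
  structure(list(sigma0 = sigma0, slope = slope), class = "psf_params")
}

#' Synthetic 3-D fluorophore phantom
#'
#' Deterministic (seeded) phantom: a uniform background slab plus spherical
#' beads placed uniformly at random (never touching the lateral boundary) and
#' optionally simple random-walk filaments. Stands in for a real specimen;
#' purely synthetic.
#'
#' @param shape `c(ny, nx, nz)` voxels.
#' @param voxel `c(dx, dy, dz)` voxel size (um).
#' @param beads list with `n` (count), `radius` (um), `intensity`
#'   (peak value) and optionally `z_range = c(zmin, zmax)` (um) confining the
#'   bead centres axially and `min_separation` (um) enforcing a minimum
#'   lateral distance between bead centres; or `NULL` for none.
#' @param slab constant background concentration added everywhere.
#' @param filaments list with `n` (count), `thickness` (um) and `intensity`;
#'   or `NULL` for none.
#' @param seed integer seed; the phantom is bit-reproducible for a fixed
#'   seed.
#' @return an object of class `phantom`: list with `density` (3-D array),
#'   `voxel`, `seed` and `ground_truth` (data.frame of bead positions in um
#'   and voxel indices).
#' @export
make_phantom <- function(shape = c(64, 64, 40), voxel = c(0.108, 0.108, 0.4),
                         beads = list(n = 10, radius = 0.3, intensity = 1),
                         slab = 0, filaments = NULL, seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), all(voxel > 0))
  set.seed(seed)
  dens <- array(slab, dim = shape)
  gt <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                   intensity = numeric(), radius = numeric())
  if (!is.null(beads) && beads$n > 0) {
    r_um <- beads$radius
    margin_x <- r_um / voxel[1]
    margin_y <- r_um / voxel[2]
    if (2 * margin_x >= shape[2] || 2 * margin_y >= shape[1]) {
      stop("bead radius exceeds the lateral volume extent", call. = FALSE)
    }
    z_lo <- 1
    z_hi <- shape[3]
    if (!is.null(beads$z_range)) {
      z_lo <- max(1, beads$z_range[1] / voxel[3] + 0.5)
      z_hi <- min(shape[3], beads$z_range[2] / voxel[3] + 0.5)
    }
    placed <- matrix(numeric(0), 0, 2) # (cx, cy) in voxels
    min_sep_vox <- if (is.null(beads$min_separation)) 0 else
      beads$min_separation / mean(voxel[1:2])
    for (b in seq_len(beads$n)) {
      for (try in seq_len(500)) {
        cx <- stats::runif(1, margin_x + 1, shape[2] - margin_x)
        cy <- stats::runif(1, margin_y + 1, shape[1] - margin_y)
        if (!nrow(placed) || min_sep_vox == 0 ||
            min(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)) >=
              min_sep_vox) break
        if (try == 500) {
          stop("cannot place beads at the requested lateral separation",
               call. = FALSE)
        }
      }
      placed <- rbind(placed, c(cx, cy))
      cz <- stats::runif(1, z_lo, z_hi)
      rx <- r_um / voxel[1]; ry <- r_um / voxel[2]; rz <- r_um / voxel[3]
      xs <- max(1, floor(cx - rx - 1)):min(shape[2], ceiling(cx + rx + 1))
      ys <- max(1, floor(cy - ry - 1)):min(shape[1], ceiling(cy + ry + 1))
      zs <- max(1, floor(cz - rz - 1)):min(shape[3], ceiling(cz + rz + 1))
      for (k in zs) {
        dz2 <- ((k - cz) / max(rz, 1e-9))^2
        if (dz2 > 1) next
        dd <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, "+") + dz2
        sl <- dens[ys, xs, k]
        sl[dd <= 1] <- sl[dd <= 1] + beads$intensity
        dens[ys, xs, k] <- sl
      }
      gt <- rbind(gt, data.frame(
        x = (cx - 1) * voxel[1], y = (cy - 1) * voxel[2],
        z = (cz - 0.5) * voxel[3],
        intensity = beads$intensity, radius = r_um))
    }
    gt$col <- round(gt$x / voxel[1]) + 1
    gt$row <- round(gt$y / voxel[2]) + 1
    gt$slice <- pmin(shape[3], pmax(1, round(gt$z / voxel[3] + 0.5)))
  }
  if (!is.null(filaments) && filaments$n > 0) {
    for (fil in seq_len(filaments$n)) {
      pos <- c(stats::runif(1, 1, shape[1]), stats::runif(1, 1, shape[2]),
               stats::runif(1, 1, shape[3]))
      for (s in seq_len(4 * max(shape[1:2]))) {
        ij <- round(pos)
        if (all(ij >= 1) && all(ij <= shape)) {
          dens[ij[1], ij[2], ij[3]] <- dens[ij[1], ij[2], ij[3]] +
            filaments$intensity
        }
        pos <- pos + c(stats::rnorm(2, sd = 1), stats::rnorm(1, sd = 0.2))
        if (any(pos < 1) || any(pos > shape)) break
      }
    }
  }
  structure(list(density = dens, voxel = as.numeric(voxel), seed = seed,
                 ground_truth = gt),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("<phantom> %d x %d x %d voxels @ %.3g x %.3g x %.3g um, %d beads\n",
              d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3],
              nrow(x$ground_truth)))
  invisible(x)
}

#' Fully developed speckle illumination field
#'
#' Synthesizes speckle as the intensity of the Fourier transform of a
#' random-phase pupil whose radius sets the speckle grain (correlation
#' length about `grain_size` pixels), then normalizes the field to unit
#' spatial mean. Fully developed speckle: the single-point intensity
#' statistics are exponential.
#'
#' @param shape `c(rows, cols)` of the field.
#' @param grain_size speckle grain in pixels (>= 1).
#' @param seed integer seed.
#' @return an object of class `speckle_field`: list with `S` (non-negative
#'   matrix, mean exactly 1), `grain_size`, `contrast` (sd/mean) and `seed`.
#' @export
generate_speckle <- function(shape, grain_size = 4, seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape >= 2), grain_size >= 1)
  set.seed(seed)
  fy <- fft_freqs(shape[1], 1) * shape[1]
  fx <- fft_freqs(shape[2], 1) * shape[2]
  ry <- shape[1] / (2 * grain_size)
  rx <- shape[2] / (2 * grain_size)
  pupil <- outer((fy / ry)^2, (fx / rx)^2, "+") <= 1
  ph <- matrix(stats::runif(prod(shape), 0, 2 * pi), shape[1], shape[2])
  field <- stats::fft(pupil * exp(1i * ph))
  S <- Mod(field)^2
  S <- S / mean(S)
  structure(list(S = S, grain_size = grain_size,
                 contrast = stats::sd(S) / mean(S), seed = seed),
            class = "speckle_field")
}

illum_matrix <- function(illumination, shape) {
  if (is.null(illumination)) return(NULL)
  S <- if (inherits(illumination, "speckle_field")) illumination$S
       else illumination
  stopifnot(is.matrix(S), identical(dim(S), as.integer(shape)))
  S
}

#' Render in-focus / out-of-focus plane images of a phantom
#'
#' Incoherent imaging of the phantom as seen when focused at `focal_plane_z`:
#' the in-focus image `I_in` is the phantom slice nearest the focal plane
#' blurred with the in-focus kernel, and `I_out` sums the contributions of
#' every other slice blurred with the defocus kernel
#' `sigma(z) = sigma0 + slope |z - z_focus|` (see [psf_params()]). Slice k
#' sits at `z = (k - 0.5) * dz`.
#'
#' Under the default `speckle_model = "modulate_image"` the speckle
#' modulation multiplies the blurred in-focus image, so the two-component
#' imaging model `I_s = S * I_in + I_out` holds exactly by construction.
#' `speckle_model = "modulate_object"` applies the speckle to every slice
#' before blurring (defocus washes the speckle contrast out smoothly), a
#' more physical variant used for axial-response studies.
#'
#' @param phantom a [make_phantom()] phantom.
#' @param focal_plane_z focal plane position (um, in phantom coordinates).
#' @param illumination `NULL` for uniform illumination, or a
#'   [generate_speckle()] field / matrix matching the lateral shape.
#' @param psf a [psf_params()].
#' @param speckle_model `"modulate_image"` or `"modulate_object"` (see
#'   Details).
#' @return list with matrices `in_focus`, `out_focus` and `total`
#'   (`in_focus + out_focus` under uniform illumination, or the speckle
#'   total when `illumination` is given).
#' @export
render_plane_images <- function(phantom, focal_plane_z, illumination = NULL,
                                psf = psf_params(),
                                speckle_model = c("modulate_image",
                                                  "modulate_object")) {
  stopifnot(inherits(phantom, "phantom"), inherits(psf, "psf_params"))
  speckle_model <- match.arg(speckle_model)
  d <- dim(phantom$density)
  S <- illum_matrix(illumination, d[1:2])
  if (all(phantom$density == 0)) {
    warning("empty phantom: rendered images are zero", call. = FALSE)
    z0 <- matrix(0, d[1], d[2])
    return(list(in_focus = z0, out_focus = z0, total = z0))
  }
  dz <- phantom$voxel[3]
  zs <- (seq_len(d[3]) - 0.5) * dz
  k_focus <- which.min(abs(zs - focal_plane_z))
  in_focus_valid <- abs(zs[k_focus] - focal_plane_z) <= dz / 2 + 1e-9
  px <- mean(phantom$voxel[1:2])
  I_in <- matrix(0, d[1], d[2])
  I_out <- matrix(0, d[1], d[2])
  I_out_s <- matrix(0, d[1], d[2])
  use_object_model <- speckle_model == "modulate_object" && !is.null(S)
  for (k in seq_len(d[3])) {
    sl <- phantom$density[, , k]
    sigma_um <- psf$sigma0 + psf$slope * abs(zs[k] - focal_plane_z)
    if (k == k_focus && in_focus_valid) {
      I_in <- blur_gaussian(sl, sigma_um / px)
      if (use_object_model) {
        I_in_s <- blur_gaussian(sl * S, sigma_um / px)
      }
    } else {
      b <- blur_gaussian(sl, sigma_um / px)
      I_out <- I_out + b
      if (use_object_model) {
        I_out_s <- I_out_s + blur_gaussian(sl * S, sigma_um / px)
      }
    }
  }
  if (!(in_focus_valid)) I_in <- matrix(0, d[1], d[2])
  total <- if (is.null(S)) {
    I_in + I_out
  } else if (use_object_model) {
    (if (in_focus_valid) I_in_s else matrix(0, d[1], d[2])) + I_out_s
  } else {
    S * I_in + I_out
  }
  list(in_focus = I_in, out_focus = I_out, total = total)
}

#' Render a co-registered uniform/speckle pair for one focal plane
#'
#' Convenience wrapper around [render_plane_images()] producing the
#' [frame_pair()] the HiLo reconstruction consumes. The defocus blurs are
#' computed once and shared between the two illumination states.
#'
#' @inheritParams render_plane_images
#' @param speckle a [generate_speckle()] field or matrix.
#' @return a [frame_pair()].
#' @export
render_frame_pair <- function(phantom, focal_plane_z, speckle,
                              psf = psf_params(),
                              speckle_model = "modulate_image") {
  u <- render_plane_images(phantom, focal_plane_z, illumination = NULL,
                           psf = psf)
  s <- if (identical(speckle_model, "modulate_image")) {
    S <- illum_matrix(speckle, dim(phantom$density)[1:2])
    S * u$in_focus + u$out_focus
  } else {
    render_plane_images(phantom, focal_plane_z, illumination = speckle,
                        psf = psf, speckle_model = "modulate_object")$total
  }
  frame_pair(pmax(u$total, 0), pmax(s, 0),
             pitch = mean(phantom$voxel[1:2]),
             plane_meta = list(focal_plane_z = focal_plane_z))
}

#' Render one multiplexed camera frame
#'
#' Renders each plane of the multiplex plan at its object-side offset
#' `delta_l` (plus a scan offset) with [render_plane_images()] and pastes the
#' per-plane images into their camera tiles. The phantom's lateral shape must
#' equal the tile size. Optional Poisson shot noise and Gaussian read noise;
#' with noise disabled the tiles equal the per-plane renders exactly.
#'
#' @param phantom a [make_phantom()] phantom.
#' @param plan a [plan_from_spacings()] multiplex plan (uses `delta_l`).
#' @param grid a [tile_grid()]; `plane_order` rank k shows the k-th plane in
#'   ascending `delta_l` order.
#' @param illumination `NULL` (uniform) or a speckle field/matrix.
#' @param focus_z phantom z (um) conjugate to the plan's `delta_l = 0` plane;
#'   default the phantom mid-depth.
#' @param scan_offset additional axial offset (um) applied to every plane
#'   (the stage position).
#' @param psf a [psf_params()].
#' @param noise `NULL`, or list with `photons` (expected photons per
#'   intensity unit, Poisson) and `read_sd` (Gaussian read noise sd).
#' @param seed seed used when noise is enabled.
#' @param speckle_model passed to [render_plane_images()].
#' @return camera-frame matrix of the grid footprint size.
#' @export
render_multiplexed_frame <- function(phantom, plan, grid, illumination = NULL,
                                     focus_z = NULL, scan_offset = 0,
                                     psf = psf_params(), noise = NULL,
                                     seed = 1,
                                     speckle_model = "modulate_image") {
  stopifnot(inherits(phantom, "phantom"), inherits(plan, "multiplex_plan"),
            inherits(grid, "tile_grid"))
  d <- dim(phantom$density)
  if (!identical(as.integer(d[1:2]), rep(grid$tile_px, 2L))) {
    stop("phantom lateral shape must equal the tile size", call. = FALSE)
  }
  n <- nrow(plan$planes)
  if (grid$rows * grid$cols < n) {
    stop("tile grid holds fewer tiles than the plan has planes",
         call. = FALSE)
  }
  if (is.null(focus_z)) focus_z <- d[3] * phantom$voxel[3] / 2
  ord <- order(plan$planes$delta_l)
  zr <- range((seq_len(d[3]) - 0.5) * phantom$voxel[3])
  tiles <- vector("list", n)
  for (k in seq_len(n)) {
    i <- ord[k]
    fz <- focus_z + plan$planes$delta_l[i] + scan_offset
    if (fz < zr[1] - phantom$voxel[3] || fz > zr[2] + phantom$voxel[3]) {
      warning(sprintf("plane %d focuses at z = %.3g um, outside the phantom",
                      plan$planes$index[i], fz), call. = FALSE)
    }
    tiles[[k]] <- render_plane_images(phantom, fz, illumination, psf,
                                      speckle_model)$total
  }
  frame <- assemble_tiles(tiles, grid)
  if (!is.null(noise)) {
    set.seed(seed)
    if (!is.null(noise$photons) && noise$photons > 0) {
      frame <- matrix(stats::rpois(length(frame),
                                   pmax(frame, 0) * noise$photons) /
                        noise$photons,
                      nrow(frame), ncol(frame))
    }
    if (!is.null(noise$read_sd) && noise$read_sd > 0) {
      frame <- frame + matrix(stats::rnorm(length(frame), sd = noise$read_sd),
                              nrow(frame), ncol(frame))
    }
  }
  frame
}

#' Simulate a full axial scan of multiplexed frame pairs
#'
#' Produces the raw data of an acquisition: for each stage position the
#' uniform- and speckle-illumination multiplexed frames, with a fresh
#' speckle realization per position (seeded from `seed`).
#'
#' @param phantom a [make_phantom()] phantom.
#' @param plan a [plan_from_spacings()] multiplex plan.
#' @param grid a [tile_grid()].
#' @param acq an [plan_acquisition()] plan.
#' @param focus_z0 phantom z conjugate to `delta_l = 0` at the first
#'   position; default places the shallowest plane at the first section.
#' @param grain_size speckle grain (pixels).
#' @param psf a [psf_params()].
#' @param noise optional noise list (see [render_multiplexed_frame()]).
#' @param seed integer master seed.
#' @return list of [frame_pair()]s of multiplexed frames, one per scan
#'   position.
#' @export
simulate_axial_scan <- function(phantom, plan, grid, acq, focus_z0 = NULL,
                                grain_size = 8, psf = psf_params(),
                                noise = NULL, seed = 1) {
  stopifnot(inherits(acq, "acquisition_plan"))
  d <- dim(phantom$density)
  if (is.null(focus_z0)) {
    # first section (smallest delta_l at position 1) at the top of the phantom
    focus_z0 <- 0.5 * phantom$voxel[3] - min(plan$planes$delta_l)
  }
  frames <- vector("list", acq$scan_steps)
  for (p in seq_len(acq$scan_steps)) {
    off <- (p - 1) * acq$step_size
    sp <- generate_speckle(d[1:2], grain_size = grain_size,
                           seed = seed + 1000L * p)
    fu <- render_multiplexed_frame(phantom, plan, grid, illumination = NULL,
                                   focus_z = focus_z0, scan_offset = off,
                                   psf = psf, noise = noise,
                                   seed = seed + 2L * p)
    fs <- render_multiplexed_frame(phantom, plan, grid, illumination = sp,
                                   focus_z = focus_z0, scan_offset = off,
                                   psf = psf, noise = noise,
                                   seed = seed + 2L * p + 1L)
    frames[[p]] <- frame_pair(pmax(fu, 0), pmax(fs, 0),
                              pitch = mean(phantom$voxel[1:2]),
                              plane_meta = list(position = p,
                                                scan_offset = off))
  }
  frames
}

#' Simulated optical response of a phase mask
#'
#' Propagates a probe field through `aperture * exp(i mask)`, applies the
#' Fourier lens (focal length `train$f_fourier`) and Fresnel-propagates to
#' each plane's `delta_L`. Returns the intensity at every plane and the
#' energy captured within every tile window at every plane.
#'
#' @param mask a `phase_mask` on the train's SLM grid.
#' @param plan a [plan_from_spacings()] multiplex plan.
#' @param train an [optical_train()] (defaults to the plan's).
#' @param probe complex matrix probe field on the SLM grid, or `NULL` for
#'   the unit-energy uniform aperture field.
#' @param wavelength evaluation wavelength (um).
#' @param keep_intensity if `FALSE`, per-plane intensity images are dropped
#'   (energy table only), saving memory at large grids.
#' @return list with `energy` (planes x tiles matrix of absolute energies,
#'   `energy[i, j]` = energy within tile j's window at plane i's focal
#'   distance), `probe_energy`, `pitch_cam`, and (optionally) `intensity`
#'   (list of per-plane matrices).
#' @export
simulate_mask_response <- function(mask, plan, train = plan$train,
                                   probe = NULL, wavelength = 0.55,
                                   keep_intensity = FALSE) {
  stopifnot(inherits(mask, "phase_mask"), inherits(plan, "multiplex_plan"))
  if (!identical(dim(mask$phase), as.integer(train$slm_shape))) {
    stop("mask is not on the train's SLM grid", call. = FALSE)
  }
  if (is.null(probe)) probe <- input_amplitude(train) + 0i
  E <- probe * mask$aperture * exp(1i * mask$phase)
  pitch_slm <- rep(train$slm_pitch, 2)
  probe_energy <- sum(Mod(E)^2) * prod(pitch_slm)
  EB <- ft_lens_mat(E, pitch_slm, wavelength, train$f_fourier)
  pitch_cam <- wavelength * train$f_fourier / (train$slm_shape * train$slm_pitch)
  windows <- tile_windows(plan, wavelength)
  n <- nrow(plan$planes)
  energy <- matrix(0, n, n,
                   dimnames = list(plane = plan$planes$index,
                                   tile = plan$planes$index))
  intens <- if (keep_intensity) vector("list", n) else NULL
  for (i in seq_len(n)) {
    Ei <- fresnel_mat(EB, pitch_cam, wavelength, plan$planes$delta_L[i])
    I <- Mod(Ei)^2
    if (keep_intensity) intens[[i]] <- I
    for (j in seq_len(n)) {
      energy[i, j] <- sum(I[windows[[j]]]) * prod(pitch_cam)
    }
  }
  out <- list(energy = energy, probe_energy = probe_energy,
              pitch_cam = pitch_cam)
  if (keep_intensity) out$intensity <- intens
  out
}
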