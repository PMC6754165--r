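# Phase-mask design: superposition initialization and the weighted global
# Gerchberg-Saxton refinement.

#' Gerchberg-Saxton configuration
#'
#' @param max_iter loop bound of the iterative refinement (>= 1). One full
#'   pass of the loop updates the phase; `max_iter = 1` returns the initial
#'   phase unchanged (the loop runs while `n < max_iter`).
#' @param wavelength design wavelength (um); default 0.55 (the 550 nm
#'   bandpass-selected emission band).
#' @param seed integer seed for the optional randomized initialization
#'   perturbation; `NULL` leaves the deterministic superposition untouched.
#' @param adaptive_weights if `TRUE`, per-plane weights are rebalanced each
#'   iteration by `w(i) <- w(i) * mean(a) / a(i)` with `a(i)` the achieved
#'   amplitude (square root of the tile energy); default `FALSE` (static
#'   weights as printed in the design procedure).
#' @param quantization_levels optional number of discrete phase levels applied
#'   to the returned mask (real SLMs address discrete levels), or `NULL`.
#' @param init_perturbation standard deviation (radians) of a random phase
#'   perturbation added to the initial mask; 0 keeps the deterministic
#'   superposition initialization.
#' @return an object of class `gs_config`.
#' @export
gs_config <- function(max_iter = 30, wavelength = 0.55, seed = NULL,
                      adaptive_weights = FALSE, quantization_levels = NULL,
                      init_perturbation = 0) {
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1) {
    stop("`max_iter` must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(wavelength) || wavelength <= 0) {
    stop("`wavelength` must be positive", call. = FALSE)
  }
  structure(list(max_iter = max_iter, wavelength = wavelength, seed = seed,
                 adaptive_weights = isTRUE(adaptive_weights),
                 quantization_levels = quantization_levels,
                 init_perturbation = init_perturbation),
            class = "gs_config")
}

new_phase_mask <- function(phase, train, aperture, provenance = list()) {
  phase <- phase %% (2 * pi)
  phase[phase >= 2 * pi * (1 - 1e-12)] <- 0 # canonical branch at the wrap
  phase[!aperture] <- 0
  structure(list(phase = phase, train = train, aperture = aperture,
                 provenance = provenance),
            class = "phase_mask")
}

#' @export
print.phase_mask <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf("<phase_mask> %d x %d, phase in [0, 2pi), aperture radius %.4g mm\n",
              d[1], d[2], x$train$aperture_radius / 1e3))
  if (!is.null(x$provenance$iterations)) {
    cat(sprintf("  refined for %d iterations\n", x$provenance$iterations))
  }
  invisible(x)
}

#' Off-axis Fresnel-lens phase for one focal plane
#'
#' The unwrapped phase `pi * delta_L * r^2 / (lambda f^2) - 2 pi (u0 x +
#' v0 y) / (lambda f)` on the SLM grid: the quadratic term refocuses the
#' plane an axial distance `delta_L` beyond the Fourier-lens focus and the
#' linear term steers its image to the camera-plane point `(u0, v0)`.
#'
#' @param train an [optical_train()].
#' @param delta_L image-side axial offset (um).
#' @param tile_offset camera-plane target `(u0, v0)` (um).
#' @param wavelength wavelength (um).
#' @return real matrix of unwrapped phase (radians) on the SLM grid.
#' @export
fresnel_lens_phase <- function(train, delta_L, tile_offset = c(0, 0),
                               wavelength = 0.55) {
  stopifnot(inherits(train, "optical_train"))
  y <- grid_coords(train$slm_shape[1], train$slm_pitch)
  x <- grid_coords(train$slm_shape[2], train$slm_pitch)
  r2 <- outer(y^2, x^2, "+")
  lens <- pi * delta_L * r2 / (wavelength * train$f_fourier^2)
  tilt <- -2 * pi * (outer(rep(1, length(y)), x * tile_offset[1]) +
                     outer(y * tile_offset[2], rep(1, length(x)))) /
    (wavelength * train$f_fourier)
  lens + tilt
}

# per-plane lens + tilt phase on the SLM grid (radians, unwrapped)
plane_phase <- function(plan, i, wavelength) {
  uv <- plan_tile_centers(plan)
  fresnel_lens_phase(plan$train, plan$planes$delta_L[i],
                     c(uv[i, "u"], uv[i, "v"]), wavelength)
}

check_tilt_nyquist <- function(plan, wavelength) {
  tr <- plan$train
  uv <- plan_tile_centers(plan)
  lim <- wavelength * tr$f_fourier / (2 * tr$slm_pitch)
  bad <- which(pmax(abs(uv[, "u"]), abs(uv[, "v"])) > lim &
                 plan$planes$weight > 0)
  if (length(bad)) {
    stop(sprintf(
      "tile (%d, %d) of plane %d requires a tilt beyond the SLM Nyquist limit (offset %.3g um > %.3g um)",
      plan$planes$tile_row[bad[1]], plan$planes$tile_col[bad[1]],
      plan$planes$index[bad[1]],
      max(abs(uv[bad[1], ])), lim), call. = FALSE)
  }
  invisible(TRUE)
}

#' Superposition initialization of the multiplexing phase mask
#'
#' Builds the initial phase `phi_0 = Arg(sum_i exp(i * [Fresnel-lens phase for
#' delta_L(i) + linear tilt steering to tile i]))` over the clear aperture.
#' The lens term `pi * delta_L * r^2 / (lambda f^2)` refocuses plane i an
#' axial distance `delta_L(i)` beyond the Fourier-lens focus, and the tilt
#' `-2 pi (u_i x + v_i y) / (lambda f)` steers it laterally to its tile
#' centre. Zero-weight planes (the unmodulated zero order) contribute
#' nothing.
#'
#' @param plan a [plan_from_spacings()] multiplex plan.
#' @param config a [gs_config()].
#' @return a `phase_mask`.
#' @export
init_superposition <- function(plan, config = gs_config()) {
  stopifnot(inherits(plan, "multiplex_plan"), inherits(config, "gs_config"))
  check_tilt_nyquist(plan, config$wavelength)
  tr <- plan$train
  active <- which(plan$planes$weight > 0)
  if (!length(active)) {
    # nothing to modulate; a flat mask passes everything to the zero order
    acc <- matrix(1 + 0i, tr$slm_shape[1], tr$slm_shape[2])
  } else {
    acc <- matrix(0 + 0i, tr$slm_shape[1], tr$slm_shape[2])
    for (i in active) {
      acc <- acc + exp(1i * plane_phase(plan, i, config$wavelength))
    }
  }
  phi <- Arg(acc)
  if (config$init_perturbation > 0) {
    if (!is.null(config$seed)) set.seed(config$seed)
    phi <- phi + stats::rnorm(length(phi), sd = config$init_perturbation)
  }
  new_phase_mask(phi, tr, aperture_mask(tr),
                 provenance = list(stage = "superposition",
                                   planes = nrow(plan$planes)))
}

# unit-energy uniform-disk input amplitude on the SLM grid
input_amplitude <- function(train) {
  ap <- aperture_mask(train)
  E0 <- matrix(0, train$slm_shape[1], train$slm_shape[2])
  E0[ap] <- 1
  E0 / sqrt(sum(E0^2) * train$slm_pitch^2)
}

# per-plane unit-energy target amplitudes (focused aperture spot shifted to
# the tile centre) on the camera-side grid reached by the Fourier lens
make_targets <- function(plan, wavelength) {
  tr <- plan$train
  E0 <- input_amplitude(tr)
  spot <- Mod(ft_lens_mat(E0 + 0i, rep(tr$slm_pitch, 2), wavelength,
                          tr$f_fourier))
  pitch_cam <- wavelength * tr$f_fourier / (tr$slm_shape * tr$slm_pitch)
  uv <- plan_tile_centers(plan)
  d <- dim(spot)
  targets <- vector("list", nrow(plan$planes))
  for (i in seq_len(nrow(plan$planes))) {
    dr <- round(uv[i, "v"] / pitch_cam[1])
    dc <- round(uv[i, "u"] / pitch_cam[2])
    sh <- spot[(seq_len(d[1]) - 1 - dr) %% d[1] + 1,
               (seq_len(d[2]) - 1 - dc) %% d[2] + 1, drop = FALSE]
    targets[[i]] <- sh / sqrt(sum(sh^2) * prod(pitch_cam))
  }
  targets
}

# logical tile window per plane on the camera-side simulation grid
tile_windows <- function(plan, wavelength) {
  tr <- plan$train
  pitch_cam <- wavelength * tr$f_fourier / (tr$slm_shape * tr$slm_pitch)
  v <- grid_coords(tr$slm_shape[1], pitch_cam[1])
  u <- grid_coords(tr$slm_shape[2], pitch_cam[2])
  uv <- plan_tile_centers(plan)
  half <- plan$tile_px * tr$camera_pitch / 2
  lapply(seq_len(nrow(plan$planes)), function(i) {
    outer(abs(v - uv[i, "v"]) <= half, abs(u - uv[i, "u"]) <= half, "&")
  })
}

#' Weighted global Gerchberg-Saxton refinement
#'
#' Refines the multiplexing phase by the weighted global Gerchberg-Saxton
#' loop: each iteration forms `E_A = E_0 exp(i phi_n)`, transforms to the
#' camera side `E_B = F(E_A)`, and for each weighted plane i propagates
#' `E_C = T(E_B, delta_L(i))`, replaces the amplitude with the weighted
#' target `E_D = w(i) E_tar(i) exp(i Arg(E_C))`, propagates back
#' `E_E = T(E_D, -delta_L(i))` and inverse-transforms `E_F(i) = F^-1(E_E)`;
#' the new phase is `phi_n = Arg(sum_i E_F(i))`. The per-plane target
#' amplitude is a focused copy of the aperture field centred on the plane's
#' tile. Zero-weight planes are excluded from the sum.
#'
#' @param plan a [plan_from_spacings()] multiplex plan.
#' @param config a [gs_config()].
#' @param phi0 initial `phase_mask`; default [init_superposition()].
#' @param amplitude_replacement if `FALSE`, step (the amplitude substitution)
#'   is skipped and `|E_C|` is kept: the loop is then the identity and the
#'   input phase is a fixed point. Diagnostic use only.
#' @return a `phase_mask` whose `provenance` holds the iteration count and a
#'   `convergence` data.frame (per iteration and plane: tile energy fraction,
#'   mean-square amplitude error against the target, weight in force).
#' @export
wggs_optimize <- function(plan, config = gs_config(), phi0 = NULL,
                          amplitude_replacement = TRUE) {
  stopifnot(inherits(plan, "multiplex_plan"), inherits(config, "gs_config"))
  if (is.null(phi0)) phi0 <- init_superposition(plan, config)
  stopifnot(inherits(phi0, "phase_mask"))
  tr <- plan$train
  if (!identical(dim(phi0$phase), as.integer(tr$slm_shape))) {
    stop("`phi0` is not on the plan's SLM grid", call. = FALSE)
  }
  active <- which(plan$planes$weight > 0)
  if (!length(active)) stop("all plane weights are zero", call. = FALSE)

  lambda <- config$wavelength
  pitch_slm <- rep(tr$slm_pitch, 2)
  pitch_cam <- lambda * tr$f_fourier / (tr$slm_shape * tr$slm_pitch)
  E0 <- input_amplitude(tr)
  ap <- phi0$aperture
  targets <- make_targets(plan, lambda)
  windows <- tile_windows(plan, lambda)
  w <- plan$planes$weight
  w[active] <- w[active] / sqrt(sum(w[active]^2))

  phi <- phi0$phase
  log_rows <- list()
  n <- 1L
  while (n < config$max_iter) {
    EA <- E0 * exp(1i * phi)
    EB <- ft_lens_mat(EA, pitch_slm, lambda, tr$f_fourier)
    EG <- matrix(0 + 0i, nrow(EA), ncol(EA))
    achieved <- rep(NA_real_, nrow(plan$planes))
    for (i in active) {
      EC <- fresnel_mat(EB, pitch_cam, lambda, plan$planes$delta_L[i])
      achieved[i] <- sum(Mod(EC[windows[[i]]])^2) * prod(pitch_cam)
      mse <- sum((Mod(EC) - w[i] * targets[[i]])^2) * prod(pitch_cam)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        iteration = n, plane = plan$planes$index[i],
        tile_energy = achieved[i], mse = mse, weight = w[i])
      ED <- if (amplitude_replacement) {
        w[i] * targets[[i]] * exp(1i * Arg(EC))
      } else {
        EC
      }
      EE <- fresnel_mat(ED, pitch_cam, lambda, -plan$planes$delta_L[i])
      EG <- EG + ft_lens_mat(EE, pitch_cam, lambda, tr$f_fourier,
                             inverse = TRUE)
    }
    phi <- Arg(EG)
    if (config$adaptive_weights) {
      a <- sqrt(achieved[active])
      w[active] <- w[active] * mean(a) / a
      w[active] <- w[active] / sqrt(sum(w[active]^2))
    }
    n <- n + 1L
  }
  conv <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(iteration = integer(), plane = integer(),
               tile_energy = numeric(), mse = numeric(), weight = numeric())
  mask <- new_phase_mask(phi, tr, ap,
                         provenance = list(stage = "wggs",
                                           iterations = n - 1L,
                                           planes = nrow(plan$planes),
                                           convergence = conv))
  if (!is.null(config$quantization_levels)) {
    mask <- quantize_phase(mask, config$quantization_levels)
  }
  mask
}

#' Quantize a phase mask to discrete levels
#'
#' Snaps every phase value to the nearest of `levels` uniformly spaced values
#' in `[0, 2pi)` (real SLMs address discrete phase levels). Idempotent.
#'
#' @param mask a `phase_mask`.
#' @param levels number of levels (>= 2).
#' @return a quantized `phase_mask`.
#' @export
quantize_phase <- function(mask, levels) {
  stopifnot(inherits(mask, "phase_mask"))
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2) {
    stop("`levels` must be an integer >= 2", call. = FALSE)
  }
  step <- 2 * pi / levels
  q <- (round(mask$phase / step) * step) %% (2 * pi)
  prov <- mask$provenance
  prov$quantization_levels <- levels
  new_phase_mask(q, mask$train, mask$aperture, prov)
}

#' Summary metrics of a designed mask
#'
#' Simulates the optical response of `mask` under the plan's geometry (see
#' [simulate_mask_response()]) and summarises it: the energy fraction each
#' plane delivers into its own tile at its own focal plane, the uniformity of
#' those fractions (min/max ratio and relative standard deviation over the
#' weighted planes), the zero-order fraction (energy in the zero-weight
#' plane's tile at its plane, stray light in simulation since the unmodulated
#' hardware reflection is not modelled), and a conservative crosstalk
#' fraction: all probe energy not delivered into a designed tile at its
#' designed plane (ghost orders, spill into wrong tiles and light outside
#' every tile window).
#'
#' @param mask a `phase_mask`.
#' @param plan the `multiplex_plan` the mask was designed for.
#' @param wavelength evaluation wavelength (um).
#' @return a list with `per_plane` (data.frame: plane index, delta_L, weight,
#'   `tile_energy_fraction`), `uniformity_min_max`, `uniformity_rsd`,
#'   `diffracted_fraction`, `zero_order_fraction` and `crosstalk_fraction`.
#' @export
mask_report <- function(mask, plan, wavelength = 0.55) {
  stopifnot(inherits(mask, "phase_mask"), inherits(plan, "multiplex_plan"))
  resp <- simulate_mask_response(mask, plan, plan$train,
                                 wavelength = wavelength)
  own <- diag(resp$energy)
  total <- resp$probe_energy
  active <- plan$planes$weight > 0
  frac <- own / total
  diff_frac <- sum(frac[active])
  zi <- which(!active)
  zero_frac <- if (length(zi)) sum(frac[zi]) else 0
  u <- frac[active]
  list(
    per_plane = data.frame(plane = plan$planes$index,
                           delta_L = plan$planes$delta_L,
                           weight = plan$planes$weight,
                           tile_energy_fraction = frac),
    uniformity_min_max = min(u) / max(u),
    uniformity_rsd = stats::sd(u) / mean(u),
    diffracted_fraction = diff_frac,
    zero_order_fraction = zero_frac,
    crosstalk_fraction = 1 - diff_frac - zero_frac)
}

#' Export a phase mask to image files
#'
#' Writes the phase as an 8-bit grayscale TIFF (phase mapped `[0, 2pi) ->
#' [0, 255]`, the form an SLM driver consumes) and, optionally, as a lossless
#' 32-bit float TIFF and the convergence log as CSV.
#'
#' @param mask a `phase_mask`.
#' @param gray_file path of the 8-bit grayscale TIFF.
#' @param float_file optional path of the 32-bit float TIFF (phase/2pi).
#' @param log_file optional path of the convergence-log CSV.
#' @return invisibly, the paths written.
#' @export
export_phase_mask <- function(mask, gray_file, float_file = NULL,
                              log_file = NULL) {
  stopifnot(inherits(mask, "phase_mask"))
  ph <- mask$phase / (2 * pi) # [0, 1)
  tiff::writeTIFF(round(ph * 255) / 255, gray_file, bits.per.sample = 8)
  written <- gray_file
  if (!is.null(float_file)) {
    tiff::writeTIFF(ph, float_file, bits.per.sample = 32)
    written <- c(written, float_file)
  }
  if (!is.null(log_file) && !is.null(mask$provenance$convergence)) {
    utils::write.csv(mask$provenance$convergence, log_file, row.names = FALSE)
    written <- c(written, log_file)
  }
  invisible(written)
}
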