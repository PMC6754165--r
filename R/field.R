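#' Sampled complex optical field
#'
#' A `complex_field` carries a sampled 2-D complex amplitude together with the
#' physical sample pitch and wavelength, so that propagation operators can keep
#' track of grid calibration. The array origin is at the grid centre (row/column
#' index `floor(n/2) + 1`), and all lengths are in micrometres.
#'
#' @param amplitude_phase complex (or numeric) matrix, both dimensions >= 2.
#' @param pitch sample pitch in um; a scalar or a length-2 `(row, col)` vector.
#' @param wavelength wavelength in um (> 0).
#' @param plane_label free-text label for the plane the field lives in.
#'
#' @return An object of class `complex_field`: a list with elements `field`
#'   (complex matrix), `pitch` (length-2 numeric), `wavelength` and
#'   `plane_label`.
#' @examples
#' E <- complex_field(matrix(1, 32, 32), pitch = 8, wavelength = 0.55)
#' field_energy(E)
#' @export
complex_field <- function(amplitude_phase, pitch, wavelength,
                          plane_label = "") {
  if (!is.matrix(amplitude_phase)) {
    stop("`amplitude_phase` must be a matrix", call. = FALSE)
  }
  if (any(dim(amplitude_phase) < 2)) {
    stop("field grid must be at least 2 x 2", call. = FALSE)
  }
  if (is.numeric(amplitude_phase)) {
    storage.mode(amplitude_phase) <- "complex"
  }
  pitch <- as.numeric(pitch)
  if (length(pitch) == 1) pitch <- c(pitch, pitch)
  if (length(pitch) != 2 || any(!is.finite(pitch)) || any(pitch <= 0)) {
    stop("`pitch` must be one or two strictly positive numbers", call. = FALSE)
  }
  if (!is.numeric(wavelength) || length(wavelength) != 1 || wavelength <= 0) {
    stop("`wavelength` must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(Mod(amplitude_phase)))) {
    stop("field contains non-finite values", call. = FALSE)
  }
  structure(
    list(field = amplitude_phase, pitch = pitch,
         wavelength = wavelength, plane_label = as.character(plane_label)),
    class = "complex_field"
  )
}

#' Total energy of a field
#'
#' Discrete approximation of the integral of |E|^2, i.e.
#' `sum(|E|^2) * pitch_row * pitch_col`.
#'
#' @param field a [complex_field()].
#' @return scalar energy (arbitrary units * um^2).
#' @export
field_energy <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  sum(Mod(field$field)^2) * prod(field$pitch)
}

#' @export
print.complex_field <- function(x, ...) {
  d <- dim(x$field)
  cat(sprintf(
    "<complex_field> %d x %d, pitch %.4g x %.4g um, lambda %.4g um%s\n",
    d[1], d[2], x$pitch[1], x$pitch[2], x$wavelength,
    if (nzchar(x$plane_label)) paste0(" [", x$plane_label, "]") else ""))
  cat(sprintf("  energy %.6g\n", field_energy(x)))
  invisible(x)
}

#' Physical coordinates of the sample centres along one axis
#'
#' Coordinates are centred on the grid: sample `floor(n/2) + 1` sits at 0.
#'
#' @param n number of samples.
#' @param pitch sample pitch (um).
#' @return numeric vector of length `n` (um).
#' @export
grid_coords <- function(n, pitch) (seq_len(n) - 1 - floor(n / 2)) * pitch

#' Optical-train geometry
#'
#' Bundles the fixed geometry of the imaging path: the focal length of the
#' Fourier-transform lens in front of the SLM, the overall magnification of
#' the imaging system, the SLM sampling grid with its circular clear aperture
#' (the relayed back aperture of the objective), and the camera grid.
#'
#' Defaults describe a 60x system with a 200 mm Fourier lens, a 512 x 512
#' simulation grid at the SLM's native 8 um pitch, and a 6.5 um camera pixel.
#' The default 1.8 mm aperture radius is a proportionally reduced clear
#' aperture: at 512 samples one conjugate grid cannot hold both the full
#' 3.81 mm relayed back aperture and the full 3 x 3 footprint of 501-pixel
#' camera tiles (that needs about 700 samples per axis), so the simulation
#' covers the central portion of the SLM. Pass a finer grid (e.g.
#' `slm_shape = c(1024, 1024)`, `aperture_radius = 3810`) for a
#' full-aperture design.
#'
#' @param f_fourier focal length of the Fourier lens (um; default 200 mm).
#' @param magnification lateral magnification M of the imaging system.
#' @param slm_pitch SLM-plane sample pitch (um).
#' @param slm_shape `c(rows, cols)` of the SLM grid.
#' @param aperture_radius radius of the relayed back aperture on the SLM (um).
#' @param camera_pitch camera pixel pitch (um).
#' @param camera_shape `c(rows, cols)` of the camera chip.
#' @return An object of class `optical_train`.
#' @examples
#' tr <- optical_train()
#' tr$magnification
#' @export
optical_train <- function(f_fourier = 200e3,
                          magnification = 60,
                          slm_pitch = 8,
                          slm_shape = c(512, 512),
                          aperture_radius = 1800,
                          camera_pitch = 6.5,
                          camera_shape = c(2048, 2048)) {
  vals <- c(f_fourier = f_fourier, magnification = magnification,
            slm_pitch = slm_pitch, aperture_radius = aperture_radius,
            camera_pitch = camera_pitch)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all optical-train lengths must be strictly positive", call. = FALSE)
  }
  slm_shape <- as.integer(slm_shape)
  camera_shape <- as.integer(camera_shape)
  if (length(slm_shape) != 2 || any(slm_shape < 2)) {
    stop("`slm_shape` must be two integers >= 2", call. = FALSE)
  }
  half_span <- min(slm_shape) * slm_pitch / 2
  if (aperture_radius > half_span) {
    stop(sprintf(
      "aperture radius %.3g um does not fit inside the SLM short dimension (%.3g um half-span)",
      aperture_radius, half_span), call. = FALSE)
  }
  structure(
    list(f_fourier = f_fourier, magnification = magnification,
         slm_pitch = slm_pitch, slm_shape = slm_shape,
         aperture_radius = aperture_radius,
         camera_pitch = camera_pitch, camera_shape = camera_shape),
    class = "optical_train")
}

#' @export
print.optical_train <- function(x, ...) {
  cat(sprintf(
    paste0("<optical_train> f_fourier %.4g mm, M %.4g, SLM %dx%d @ %.4g um,\n",
           "  aperture radius %.4g mm, camera %dx%d @ %.4g um\n"),
    x$f_fourier / 1e3, x$magnification, x$slm_shape[1], x$slm_shape[2],
    x$slm_pitch, x$aperture_radius / 1e3,
    x$camera_shape[1], x$camera_shape[2], x$camera_pitch))
  invisible(x)
}

#' Boolean circular-aperture mask on the SLM grid
#'
#' @param train an [optical_train()].
#' @return logical matrix, TRUE inside the clear aperture.
#' @export
aperture_mask <- function(train) {
  stopifnot(inherits(train, "optical_train"))
  y <- grid_coords(train$slm_shape[1], train$slm_pitch)
  x <- grid_coords(train$slm_shape[2], train$slm_pitch)
  outer(y^2, x^2, "+") <= train$aperture_radius^2
}

#' Overall magnification from the stated focal lengths
#'
#' The lateral magnification of the two-stage imaging path: objective + tube
#' lens (`f_tube / f_objective`) followed by the 4-f relay onto the camera
#' (`f_fourier / f_relay`). With the defaults (a 40x/200 mm-design objective,
#' 150 mm tube lens, 100 mm relay and 200 mm Fourier lens) this is 60.
#'
#' @param f_objective objective focal length (mm).
#' @param f_tube tube-lens focal length (mm).
#' @param f_relay relay-lens focal length (mm).
#' @param f_fourier Fourier/condenser-lens focal length (mm).
#' @return scalar magnification.
#' @export
system_magnification <- function(f_objective = 200 / 40, f_tube = 150,
                                 f_relay = 100, f_fourier = 200) {
  stopifnot(f_objective > 0, f_tube > 0, f_relay > 0, f_fourier > 0)
  (f_tube / f_objective) * (f_fourier / f_relay)
}
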