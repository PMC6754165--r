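# Sampled wave-optics primitives.
#
# Grid convention (used everywhere in the package): the array origin is the
# centre sample, index floor(n/2) + 1 along each axis; frequency axes are kept
# in FFT order internally and shifted only where a centred spectrum is needed.
# All lengths are micrometres.

# circular shift putting the centre sample at index 1 (and back)
fftshift2 <- function(x) {
  d <- dim(x)
  x[(seq_len(d[1]) - 1 - floor(d[1] / 2)) %% d[1] + 1,
    (seq_len(d[2]) - 1 - floor(d[2] / 2)) %% d[2] + 1, drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  x[(seq_len(d[1]) - 1 + floor(d[1] / 2)) %% d[1] + 1,
    (seq_len(d[2]) - 1 + floor(d[2] / 2)) %% d[2] + 1, drop = FALSE]
}

# FFT-ordered spatial frequencies for n samples at `pitch`
fft_freqs <- function(n, pitch) {
  (((0:(n - 1)) + floor(n / 2)) %% n - floor(n / 2)) / (n * pitch)
}

# low-level centred lens Fourier transform on a bare complex matrix;
# returns the matrix, with the new pitch computed by the caller
ft_lens_mat <- function(E, pitch, wavelength, f, inverse = FALSE) {
  if (!inverse) {
    fftshift2(stats::fft(ifftshift2(E), inverse = TRUE)) *
      (prod(pitch) / (1i * wavelength * f))
  } else {
    fftshift2(stats::fft(ifftshift2(E), inverse = FALSE)) *
      (prod(pitch) / (-1i * wavelength * f))
  }
}

# low-level Fresnel transfer-function propagation on a bare complex matrix
fresnel_mat <- function(E, pitch, wavelength, distance) {
  if (distance == 0) return(E)
  d <- dim(E)
  fy <- fft_freqs(d[1], pitch[1])
  fx <- fft_freqs(d[2], pitch[2])
  H <- exp(-1i * pi * wavelength * distance * outer(fy^2, fx^2, "+"))
  stats::fft(stats::fft(E) * H, inverse = TRUE) / length(E)
}

#' Lens Fourier transform of a sampled field
#'
#' Computes the optical Fourier transform performed by a lens of focal length
#' `f`: `U(u, v) = 1/(i lambda f) * integral E(x, y) exp(i 2 pi (u x + v y) /
#' (lambda f)) dx dy`, evaluated as a centred DFT. The output grid pitch is
#' rescaled to `lambda * f / (n * pitch_in)` along each axis, so the transform
#' is exactly unitary in energy and `fourier_lens_transform(U, f, inverse =
#' TRUE)` recovers the input field on the original grid to machine precision.
#'
#' @param field a [complex_field()].
#' @param f lens focal length (um, > 0).
#' @param inverse if `TRUE`, apply the inverse transform.
#' @return a [complex_field()] on the conjugate grid.
#' @examples
#' E <- complex_field(matrix(complex(real = rnorm(64^2)), 64, 64), 8, 0.55)
#' U <- fourier_lens_transform(E, f = 2e5)
#' E2 <- fourier_lens_transform(U, f = 2e5, inverse = TRUE)
#' max(Mod(E$field - E2$field)) # ~1e-15
#' @export
fourier_lens_transform <- function(field, f, inverse = FALSE) {
  stopifnot(inherits(field, "complex_field"))
  if (!is.numeric(f) || length(f) != 1 || !is.finite(f) || f <= 0) {
    stop("focal length `f` must be a single positive number", call. = FALSE)
  }
  d <- dim(field$field)
  if (any(d < 2)) stop("field grid too small for a transform", call. = FALSE)
  U <- ft_lens_mat(field$field, field$pitch, field$wavelength, f, inverse)
  pitch_out <- field$wavelength * f / (d * field$pitch)
  complex_field(U, pitch = pitch_out, wavelength = field$wavelength,
                plane_label = paste0(field$plane_label,
                                     if (inverse) " <-F-" else " -F->"))
}

#' Fresnel free-space propagation
#'
#' Propagates a sampled field over a (signed) distance `distance` with the
#' paraxial Fresnel kernel `1/(i lambda dL) exp(i pi r^2 / (lambda dL))`,
#' implemented as an FFT transfer function `exp(-i pi lambda dL |f|^2)` so the
#' grid pitch is unchanged and energy is conserved exactly. `distance = 0`
#' returns the field unchanged; `|distance|` below `min_distance` (but
#' non-zero) degenerates the kernel and falls back to the identity with a
#' message.
#'
#' The transfer function is adequately sampled only while the kernel phase
#' advances by less than pi between adjacent frequency samples over the
#' field's occupied bandwidth; a violation (aliasing of the kernel's
#' high-frequency phase) emits a warning, not an error. For a full-bandwidth
#' field this reduces to the usual bound `|distance| <= n * pitch^2 /
#' lambda`; band-limited fields may propagate much farther.
#'
#' @param field a [complex_field()].
#' @param distance signed propagation distance dL (um).
#' @param min_distance numerical floor below which propagation is treated as
#'   the identity (um).
#' @return a [complex_field()] on the same grid.
#' @export
fresnel_propagate <- function(field, distance, min_distance = 1e-9) {
  stopifnot(inherits(field, "complex_field"))
  if (!is.numeric(distance) || length(distance) != 1 || !is.finite(distance)) {
    stop("`distance` must be a single finite number", call. = FALSE)
  }
  if (distance == 0) return(field)
  if (abs(distance) < min_distance) {
    message(sprintf(
      "fresnel_propagate: |distance| = %.3g um below the numerical floor; returning the field unchanged",
      abs(distance)))
    return(field)
  }
  d <- dim(field$field)
  # occupied bandwidth: largest frequency radius holding significant power
  spec <- Mod(stats::fft(field$field))^2
  fy <- fft_freqs(d[1], field$pitch[1])
  fx <- fft_freqs(d[2], field$pitch[2])
  f2 <- outer(fy^2, fx^2, "+")
  occupied <- spec > 1e-12 * max(spec)
  f_eff <- sqrt(max(f2[occupied]))
  df <- max(1 / (d * field$pitch))
  if (f_eff > 0 && 2 * pi * field$wavelength * abs(distance) * f_eff * df > pi) {
    zmax <- 1 / (2 * field$wavelength * f_eff * df)
    warning(sprintf(
      "Fresnel transfer function undersampled: |distance| = %.3g um exceeds the sampling limit %.3g um for this field's bandwidth",
      abs(distance), zmax), call. = FALSE)
  }
  Ez <- fresnel_mat(field$field, field$pitch, field$wavelength, distance)
  complex_field(Ez, pitch = field$pitch, wavelength = field$wavelength,
                plane_label = field$plane_label)
}

#' Object-side to image-side axial distance
#'
#' An object-side defocus `delta_l` maps to an image-side propagation distance
#' `delta_L = M^2 * delta_l` (longitudinal magnification of a system with
#' lateral magnification M). Sign is preserved.
#'
#' @param delta_l object-side offset(s) from the nominal focal plane (um).
#' @param M lateral magnification (> 0).
#' @return image-side distance(s) dL (um).
#' @examples
#' object_to_image_distance(0.4, 60) # 1440
#' @export
object_to_image_distance <- function(delta_l, M) {
  if (!is.numeric(M) || length(M) != 1 || !is.finite(M) || M <= 0) {
    stop("magnification `M` must be a single positive number", call. = FALSE)
  }
  M^2 * delta_l
}
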