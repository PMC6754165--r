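# HiLo two-frame optical sectioning.

#' Co-registered uniform / speckle frame pair
#'
#' @param uniform 2-D non-negative image taken under uniform illumination.
#' @param speckle 2-D non-negative image of the same scene under speckle
#'   illumination.
#' @param pitch object-space pixel size (um).
#' @param plane_meta optional list of plane metadata (plane index, delta_l).
#' @return an object of class `frame_pair`.
#' @export
frame_pair <- function(uniform, speckle, pitch = 1, plane_meta = list()) {
  if (!is.matrix(uniform) || !is.matrix(speckle)) {
    stop("both frames must be matrices", call. = FALSE)
  }
  if (!identical(dim(uniform), dim(speckle))) {
    stop("uniform and speckle frames must have the same shape", call. = FALSE)
  }
  if (!all(is.finite(uniform)) || !all(is.finite(speckle))) {
    stop("frames contain non-finite values", call. = FALSE)
  }
  if (min(uniform) < 0 || min(speckle) < 0) {
    stop("frames must be non-negative", call. = FALSE)
  }
  structure(list(uniform = uniform, speckle = speckle,
                 pitch = pitch, plane_meta = plane_meta),
            class = "frame_pair")
}

#' HiLo reconstruction parameters
#'
#' @param lp_sigma standard deviation of the Gaussian low-pass filter in
#'   normalized spatial frequency (cycles per pixel). The default 1/16 puts
#'   the filter's ~2-sigma cutoff at 1/8 of the sampling frequency.
#' @param eta_mode `"spectral_norm"` (the scaling factor eta is the ratio of
#'   the filtered spectral norms, computed per image pair) or `"fixed"`.
#' @param eta_fixed scalar eta used when `eta_mode = "fixed"` and as the
#'   fallback when the speckle difference image is degenerate.
#' @param rectify_difference if `TRUE`, `|I_D|` is low-passed instead of the
#'   signed difference (a common variant); default `FALSE`, the signed
#'   difference as written.
#' @return an object of class `hilo_params`.
#' @export
hilo_params <- function(lp_sigma = 1 / 16, eta_mode = c("spectral_norm", "fixed"),
                        eta_fixed = 1, rectify_difference = FALSE) {
  if (!is.numeric(lp_sigma) || lp_sigma <= 0) {
    stop("`lp_sigma` must be positive", call. = FALSE)
  }
  eta_mode <- match.arg(eta_mode)
  if (!is.numeric(eta_fixed) || eta_fixed <= 0) {
    stop("`eta_fixed` must be positive", call. = FALSE)
  }
  structure(list(lp_sigma = lp_sigma, eta_mode = eta_mode,
                 eta_fixed = eta_fixed,
                 rectify_difference = isTRUE(rectify_difference)),
            class = "hilo_params")
}

#' Speckle/uniform difference image
#'
#' `I_D = I_s - I_u`. When the two-component imaging model holds (`I_u =
#' I_in + I_out`, `I_s = S * I_in + I_out`), the out-of-focus term cancels
#' exactly and `I_D = (S - 1) * I_in`.
#'
#' @param pair a [frame_pair()].
#' @return signed difference matrix.
#' @export
difference_image <- function(pair) {
  stopifnot(inherits(pair, "frame_pair"))
  pair$speckle - pair$uniform
}

#' Complementary Gaussian low-pass / high-pass frequency filters
#'
#' Builds the frequency-domain pair `LP(k) = exp(-|k|^2 / (2 sigma^2))` (a
#' centred Gaussian with `LP(0) = 1`) and `HP = 1 - LP`, on the FFT-ordered
#' frequency grid for an image of the given shape, so `LP + HP = 1`
#' everywhere.
#'
#' @param shape `c(rows, cols)` of the image.
#' @param params a [hilo_params()] (uses `lp_sigma`, cycles/pixel).
#' @return list with matrices `lp` and `hp` in FFT order.
#' @export
gaussian_partition <- function(shape, params = hilo_params()) {
  stopifnot(inherits(params, "hilo_params"))
  fy <- fft_freqs(shape[1], 1)
  fx <- fft_freqs(shape[2], 1)
  k2 <- outer(fy^2, fx^2, "+")
  lp <- exp(-k2 / (2 * params$lp_sigma^2))
  list(lp = lp, hp = 1 - lp)
}

# mirror-pad an image by `pad` pixels on every side
pad_reflect <- function(img, pad) {
  d <- dim(img)
  ridx <- c(rev(seq_len(min(pad, d[1]))), seq_len(d[1]),
            d[1] + 1 - rev(seq_len(min(pad, d[1]))))
  cidx <- c(rev(seq_len(min(pad, d[2]))), seq_len(d[2]),
            d[2] + 1 - rev(seq_len(min(pad, d[2]))))
  img[ridx, cidx, drop = FALSE]
}

#' Apply the Gaussian low- or high-pass filter to an image
#'
#' Filters in the frequency domain with the [gaussian_partition()] pair,
#' using mirror (reflective) boundary padding of about one filter support to
#' suppress wrap-around. Exposed mainly for diagnostics such as axial
#' sectioning-response measurements of the low-passed difference image.
#'
#' @param img image matrix.
#' @param which `"lp"` or `"hp"`.
#' @param params a [hilo_params()].
#' @return filtered image matrix.
#' @export
filter_freq <- function(img, which = c("lp", "hp"), params = hilo_params()) {
  which <- match.arg(which)
  pad <- min(dim(img) %/% 2, max(8L, ceiling(1 / (2 * pi * params$lp_sigma) * 3)))
  p <- pad_reflect(img, pad)
  filt <- gaussian_partition(dim(p), params)[[which]]
  out <- Re(stats::fft(stats::fft(p) * filt, inverse = TRUE)) / length(p)
  d <- dim(img)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), drop = FALSE]
}

# L2 spectral norms excluding DC of the filtered images, on the padded grid
eta_norms <- function(I_u, I_D, params) {
  pad <- min(dim(I_u) %/% 2, max(8L, ceiling(1 / (2 * pi * params$lp_sigma) * 3)))
  pu <- pad_reflect(I_u, pad)
  pd <- pad_reflect(I_D, pad)
  filt <- gaussian_partition(dim(pu), params)
  Fu <- stats::fft(pu) * filt$hp
  Fd <- stats::fft(pd) * filt$lp
  Fu[1, 1] <- 0
  Fd[1, 1] <- 0
  c(num = sqrt(sum(Mod(Fu)^2)), den = sqrt(sum(Mod(Fd)^2)))
}

#' HiLo scaling factor eta
#'
#' `eta = ||F(I_u) HP|| / ||F(I_D) LP||`, with `||.||` the L2 norm over all
#' spatial frequencies excluding DC (the high-pass numerator is DC-free by
#' construction since `HP(0) = 0`). It matches the spectral magnitude of the
#' low- and high-frequency components at the crossover so the two can be
#' fused seamlessly.
#'
#' @param I_u uniform-illumination image.
#' @param I_D difference image (see [difference_image()]).
#' @param params a [hilo_params()].
#' @return scalar eta.
#' @export
eta_scale <- function(I_u, I_D, params = hilo_params()) {
  stopifnot(inherits(params, "hilo_params"))
  if (params$eta_mode == "fixed") return(params$eta_fixed)
  nm <- eta_norms(I_u, I_D, params)
  if (nm["den"] <= .Machine$double.eps * max(1, nm["num"])) {
    stop(paste("the low-passed difference image has no energy;",
               "use eta_mode = \"fixed\" (hilo_params) for this pair"),
         call. = FALSE)
  }
  unname(nm["num"] / nm["den"])
}

#' HiLo optically sectioned reconstruction
#'
#' Fuses the low-frequency content of the speckle/uniform difference image
#' with the high-frequency content of the uniform image:
#' `I_HiLo = eta * LP(I_D) + HP(I_u)`, where `LP`/`HP` are the complementary
#' Gaussian frequency filters of [gaussian_partition()] (applied with mirror
#' boundary padding) and eta is the spectral scaling factor of
#' [eta_scale()]. The output is clipped at zero; the clipped fraction is
#' attached as attribute `"clip_fraction"` and the eta used as `"eta"`.
#'
#' If the difference image is degenerate (no speckle modulation), eta falls
#' back to `params$eta_fixed` with a warning and the output reduces to the
#' high-pass of the uniform image.
#'
#' @param pair a [frame_pair()].
#' @param params a [hilo_params()].
#' @return sectioned image matrix with attributes `eta` and `clip_fraction`.
#' @export
hilo_reconstruct <- function(pair, params = hilo_params()) {
  stopifnot(inherits(pair, "frame_pair"), inherits(params, "hilo_params"))
  I_D <- difference_image(pair)
  if (params$rectify_difference) I_D <- abs(I_D)
  eta <- tryCatch(
    eta_scale(pair$uniform, I_D, params),
    error = function(e) {
      warning("degenerate speckle difference; falling back to fixed eta = ",
              params$eta_fixed, call. = FALSE)
      params$eta_fixed
    })
  I_lp <- filter_freq(I_D, "lp", params)
  I_hp <- filter_freq(pair$uniform, "hp", params)
  out <- eta * I_lp + I_hp
  clip <- mean(out < 0)
  out[out < 0] <- 0
  attr(out, "eta") <- eta
  attr(out, "clip_fraction") <- clip
  out
}
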