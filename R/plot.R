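# Display helpers (base graphics).

img_show <- function(m, main = "", col = grDevices::gray.colors(256, 0, 1),
                     ...) {
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE, asp = 1,
                  col = col, main = main, useRaster = TRUE, ...)
}

#' @export
plot.phase_mask <- function(x, ...) {
  img_show(x$phase, main = "phase mask [0, 2pi)",
           col = grDevices::hcl.colors(256, "viridis"), ...)
  invisible(x)
}

#' @export
plot.frame_pair <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  img_show(x$uniform, main = "uniform")
  img_show(x$speckle, main = "speckle")
  invisible(x)
}

#' @export
plot.volume_stack <- function(x, sections = NULL, ...) {
  nz <- dim(x$sections)[3]
  if (is.null(sections)) {
    sections <- unique(round(seq(1, nz, length.out = min(9, nz))))
  }
  nr <- floor(sqrt(length(sections)))
  nc <- ceiling(length(sections) / nr)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  mx <- max(x$sections)
  for (k in sections) {
    img_show(x$sections[, , k] / max(mx, .Machine$double.eps),
             main = sprintf("z = %.2f um", (k - 1) * x$dz))
  }
  invisible(x)
}

#' @export
plot.phantom <- function(x, ...) {
  proj <- apply(x$density, c(1, 2), max)
  img_show(proj / max(proj, .Machine$double.eps),
           main = "phantom (max projection)", ...)
  invisible(x)
}
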