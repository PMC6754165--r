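# Multiplex plans: which object depths map to which camera tiles.

#' Camera-plane tile centres
#'
#' Physical (u, v) coordinates (um) of the centre of each tile of an
#' `rows x cols` tile grid, relative to the optical axis, for tiles of
#' `tile_px` camera pixels at `camera_pitch` um. Row index increases with +v,
#' column index with +u; the grid is centred on the axis.
#'
#' @param tile_rc integer matrix or 2-column data of `(row, col)` 0-based tile
#'   indices.
#' @param layout `c(rows, cols)` of the tile grid.
#' @param tile_px tile side length in camera pixels.
#' @param camera_pitch camera pixel pitch (um).
#' @return matrix with columns `u`, `v` (um).
#' @export
tile_centers <- function(tile_rc, layout, tile_px, camera_pitch) {
  tile_rc <- matrix(as.numeric(tile_rc), ncol = 2)
  side <- tile_px * camera_pitch
  u <- (tile_rc[, 2] - (layout[2] - 1) / 2) * side
  v <- (tile_rc[, 1] - (layout[1] - 1) / 2) * side
  cbind(u = u, v = v)
}

#' Build a multiplex plan from focal-plane spacings
#'
#' Turns a list of desired focal-plane spacings `d_1 ... d_{N-1}` into the
#' per-plane object-side offsets (cumulative sums of the spacings, shifted so
#' the anchor plane sits at `delta_l = 0`), the image-side propagation
#' distances `delta_L = M^2 delta_l`, the camera tile assigned to each plane,
#' and the per-plane weight used by the phase designer.
#'
#' With `anchor = "center"` and an odd plane count the offsets are symmetric
#' about 0 (e.g. nine planes at 0.4 um spacing give -1.6, -1.2, ..., +1.6 um);
#' `anchor = "first"` pins the first plane at 0.
#'
#' A single plane may act as the unmodulated zero-order pass-through: it must
#' have `delta_l = 0` and is given weight 0 (see `zero_order_plane`).
#'
#' @param spacings positive spacings d_i (um); length N-1 for N planes (empty
#'   for a single plane).
#' @param anchor `"center"`, `"first"`, or a 1-based plane index anchored at
#'   `delta_l = 0`.
#' @param train an [optical_train()].
#' @param tile_layout `c(rows, cols)` of the camera tile grid.
#' @param tile_px tile side length in camera pixels (default 501).
#' @param weights per-plane weights `w(i) >= 0`; default 1 for every plane
#'   (the zero-order plane, if any, is forced to 0).
#' @param tile_rc optional N x 2 matrix of 0-based `(row, col)` tile indices;
#'   default assigns planes to tiles in row-major order.
#' @param zero_order_plane 1-based index of the plane carried by the
#'   unmodulated zero order, or `NULL` for none. That plane must have
#'   `delta_l = 0`; its weight is set to 0 and it is excluded from the
#'   Gerchberg-Saxton target sum.
#' @return An object of class `multiplex_plan`: a list with `planes` (a
#'   data.frame with columns `index`, `delta_l`, `delta_L`, `tile_row`,
#'   `tile_col`, `weight`), `spacings`, `tile_layout`, `tile_px` and `train`.
#' @examples
#' plan <- plan_from_spacings(rep(0.4, 8), anchor = "center",
#'                            train = optical_train(),
#'                            zero_order_plane = 5)
#' plan$planes$delta_l
#' @export
plan_from_spacings <- function(spacings, anchor = "center",
                               train = optical_train(),
                               tile_layout = c(3, 3), tile_px = 501,
                               weights = NULL, tile_rc = NULL,
                               zero_order_plane = NULL) {
  stopifnot(inherits(train, "optical_train"))
  spacings <- as.numeric(spacings)
  if (length(spacings) && any(spacings <= 0)) {
    stop("all spacings must be strictly positive", call. = FALSE)
  }
  n <- length(spacings) + 1L
  dl <- c(0, cumsum(spacings))
  if (identical(anchor, "center")) {
    dl <- dl - dl[(n + 1L) %/% 2L]
  } else if (identical(anchor, "first")) {
    # already anchored at the first plane
  } else if (is.numeric(anchor) && length(anchor) == 1 &&
             anchor >= 1 && anchor <= n) {
    dl <- dl - dl[as.integer(anchor)]
  } else {
    stop("`anchor` must be \"center\", \"first\" or a plane index", call. = FALSE)
  }
  if (is.null(tile_rc)) {
    if (prod(tile_layout) < n) {
      stop(sprintf("tile layout %dx%d cannot hold %d planes",
                   tile_layout[1], tile_layout[2], n), call. = FALSE)
    }
    idx <- seq_len(n) - 1L
    tile_rc <- cbind(idx %/% tile_layout[2], idx %% tile_layout[2])
  } else {
    tile_rc <- matrix(as.integer(tile_rc), ncol = 2)
    if (nrow(tile_rc) != n) {
      stop("`tile_rc` must have one row per plane", call. = FALSE)
    }
  }
  if (anyDuplicated(paste(tile_rc[, 1], tile_rc[, 2]))) {
    stop("duplicate tile assignments in the plan", call. = FALSE)
  }
  if (any(tile_rc[, 1] < 0 | tile_rc[, 1] >= tile_layout[1] |
          tile_rc[, 2] < 0 | tile_rc[, 2] >= tile_layout[2])) {
    stop("tile indices fall outside the tile layout", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)
  if (length(weights) != n || any(weights < 0)) {
    stop("`weights` must be one non-negative number per plane", call. = FALSE)
  }
  if (!is.null(zero_order_plane)) {
    z <- as.integer(zero_order_plane)
    if (z < 1 || z > n) stop("`zero_order_plane` out of range", call. = FALSE)
    if (abs(dl[z]) > 1e-12) {
      stop("the zero-order plane must sit at delta_l = 0", call. = FALSE)
    }
    weights[z] <- 0
  }
  planes <- data.frame(
    index = seq_len(n) - 1L,
    delta_l = dl,
    delta_L = object_to_image_distance(dl, train$magnification),
    tile_row = as.integer(tile_rc[, 1]),
    tile_col = as.integer(tile_rc[, 2]),
    weight = weights)
  structure(
    list(planes = planes, spacings = spacings,
         tile_layout = as.integer(tile_layout), tile_px = as.integer(tile_px),
         zero_order_plane = if (is.null(zero_order_plane)) NA_integer_
                            else as.integer(zero_order_plane),
         train = train),
    class = "multiplex_plan")
}

#' Default nine-plane multiplex plan
#'
#' Nine focal planes at `dz` spacing (default 0.4 um, giving offsets
#' -4 dz ... +4 dz), a 3 x 3 tile grid of 501-pixel tiles, with the central
#' plane (`delta_l = 0`, centre tile) carried by the unmodulated zero order
#' (weight 0).
#'
#' @param dz spacing between adjacent focal planes (um).
#' @param train an [optical_train()].
#' @param tile_px tile side length in camera pixels.
#' @return a `multiplex_plan`.
#' @export
mfm_default_plan <- function(dz = 0.4, train = optical_train(),
                             tile_px = 501) {
  plan_from_spacings(rep(dz, 8), anchor = "center", train = train,
                     tile_layout = c(3, 3), tile_px = tile_px,
                     zero_order_plane = 5)
}

#' @export
print.multiplex_plan <- function(x, ...) {
  cat(sprintf("<multiplex_plan> %d planes on a %dx%d tile grid (%d px tiles)\n",
              nrow(x$planes), x$tile_layout[1], x$tile_layout[2], x$tile_px))
  print(x$planes, row.names = FALSE)
  invisible(x)
}

# (u, v) camera-plane centre of each plane's tile, um
plan_tile_centers <- function(plan) {
  tile_centers(cbind(plan$planes$tile_row, plan$planes$tile_col),
               plan$tile_layout, plan$tile_px, plan$train$camera_pitch)
}
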