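# End-to-end volume reconstruction: tile cropping, per-plane HiLo, axial
# interleaving, acquisition arithmetic.

#' Camera tile grid
#'
#' Describes how the camera frame is subdivided into `rows x cols` disjoint
#' tiles of `tile_px` pixels, and which multiplexed plane each tile shows.
#'
#' @param rows,cols tile counts (default 3 x 3).
#' @param tile_px tile side length in pixels (default 501).
#' @param origin 1-based `(row, col)` pixel of the top-left corner of tile
#'   (1, 1) on the camera frame; `NULL` centres the footprint at crop time.
#' @param plane_order integer `rows x cols` matrix mapping tile `(r, c)` to a
#'   plane rank 1..n (1 = smallest delta_l). Default row-major 1..rows*cols.
#' @return an object of class `tile_grid`.
#' @export
tile_grid <- function(rows = 3, cols = 3, tile_px = 501, origin = NULL,
                      plane_order = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  tile_px <- as.integer(tile_px)
  stopifnot(rows >= 1, cols >= 1, tile_px >= 1)
  if (is.null(plane_order)) {
    plane_order <- matrix(seq_len(rows * cols), rows, cols, byrow = TRUE)
  }
  plane_order <- matrix(as.integer(plane_order), rows, cols)
  if (!setequal(plane_order, seq_len(rows * cols))) {
    stop("`plane_order` must be a permutation of 1..rows*cols", call. = FALSE)
  }
  structure(list(rows = rows, cols = cols, tile_px = tile_px,
                 origin = origin, plane_order = plane_order),
            class = "tile_grid")
}

tile_origin <- function(grid, frame_dim) {
  foot <- c(grid$rows, grid$cols) * grid$tile_px
  if (!is.null(grid$origin)) return(as.integer(grid$origin))
  as.integer(floor((frame_dim - foot) / 2)) + 1L
}

#' Crop a multiplexed camera frame into per-plane sub-images
#'
#' Pure crop, no resampling: tile `(r, c)` of the grid is extracted and
#' returned at position `plane_order[r, c]` of the output list, so the list
#' is ordered by plane rank.
#'
#' @param frame camera image matrix.
#' @param grid a [tile_grid()].
#' @return list of `tile_px x tile_px` matrices in plane order, with
#'   attribute `"origin"` (the footprint's top-left pixel).
#' @export
crop_tiles <- function(frame, grid) {
  stopifnot(is.matrix(frame), inherits(grid, "tile_grid"))
  org <- tile_origin(grid, dim(frame))
  foot <- c(grid$rows, grid$cols) * grid$tile_px
  if (any(org < 1) || org[1] + foot[1] - 1 > nrow(frame) ||
      org[2] + foot[2] - 1 > ncol(frame)) {
    stop(sprintf(
      "tile grid footprint %dx%d at origin (%d, %d) exceeds the %dx%d frame",
      foot[1], foot[2], org[1], org[2], nrow(frame), ncol(frame)),
      call. = FALSE)
  }
  out <- vector("list", grid$rows * grid$cols)
  for (r in seq_len(grid$rows)) {
    for (c in seq_len(grid$cols)) {
      ri <- org[1] + (r - 1L) * grid$tile_px + seq_len(grid$tile_px) - 1L
      ci <- org[2] + (c - 1L) * grid$tile_px + seq_len(grid$tile_px) - 1L
      out[[grid$plane_order[r, c]]] <- frame[ri, ci]
    }
  }
  attr(out, "origin") <- org
  out
}

#' Reassemble per-plane tiles into a frame footprint
#'
#' Inverse of [crop_tiles()] over the grid footprint.
#'
#' @param tiles list of tiles in plane order.
#' @param grid a [tile_grid()].
#' @return matrix of the footprint size.
#' @export
assemble_tiles <- function(tiles, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  foot <- c(grid$rows, grid$cols) * grid$tile_px
  out <- matrix(0, foot[1], foot[2])
  for (r in seq_len(grid$rows)) {
    for (c in seq_len(grid$cols)) {
      ri <- (r - 1L) * grid$tile_px + seq_len(grid$tile_px)
      ci <- (c - 1L) * grid$tile_px + seq_len(grid$tile_px)
      out[ri, ci] <- tiles[[grid$plane_order[r, c]]]
    }
  }
  out
}

#' Acquisition planning arithmetic
#'
#' For a target axial extent imaged with `n_planes` simultaneous focal planes
#' at section spacing `dz` and `frames_per_position` illumination states per
#' stage position: the stage step is `n_planes * dz`, the number of stage
#' positions is `ceil(depth / (n_planes * dz))`, the raw-frame count is
#' `positions * frames_per_position`, `positions * n_planes` sections are
#' generated of which `round(depth / dz)` are kept (the trailing excess
#' images beyond the specimen and is discarded). The speed-up over
#' one-exposure-per-section widefield is `n_planes / frames_per_position`,
#' and with a camera frame rate the volume rate is
#' `camera_rate / frames_per_position` (one multiplexed volume per
#' `frames_per_position` exposures).
#'
#' @param depth target axial extent (um, > 0).
#' @param dz section spacing (um).
#' @param n_planes simultaneous focal planes per exposure.
#' @param frames_per_position illumination states per stage position
#'   (2 = uniform + speckle).
#' @param camera_rate optional camera frame rate (Hz) for the volume-rate
#'   report.
#' @return an object of class `acquisition_plan`: a list with `n_planes`,
#'   `dz`, `step_size`, `scan_steps`, `frames_per_position`, `raw_frames`,
#'   `sections_generated`, `sections_kept`, `sections_discarded`,
#'   `speedup_factor` and `volume_rate` (NA without a camera rate).
#' @examples
#' plan_acquisition(16, 0.4, 9, 2, camera_rate = 200)
#' @export
plan_acquisition <- function(depth, dz, n_planes, frames_per_position = 2,
                             camera_rate = NULL) {
  if (!is.numeric(depth) || depth <= 0) {
    stop("`depth` must be positive", call. = FALSE)
  }
  stopifnot(dz > 0, n_planes >= 1, frames_per_position >= 1)
  n_planes <- as.integer(n_planes)
  frames_per_position <- as.integer(frames_per_position)
  step_size <- n_planes * dz
  scan_steps <- as.integer(ceiling(depth / step_size - 1e-9))
  sections_generated <- scan_steps * n_planes
  sections_kept <- as.integer(round(depth / dz))
  structure(list(
    n_planes = n_planes, dz = dz, step_size = step_size,
    scan_steps = scan_steps, frames_per_position = frames_per_position,
    raw_frames = scan_steps * frames_per_position,
    sections_generated = sections_generated,
    sections_kept = sections_kept,
    sections_discarded = sections_generated - sections_kept,
    speedup_factor = n_planes / frames_per_position,
    volume_rate = if (is.null(camera_rate)) NA_real_
                  else camera_rate / frames_per_position),
    class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf(
    paste0("<acquisition_plan> %d planes x %d positions (step %.3g um, dz %.3g um)\n",
           "  raw frames %d; sections %d generated, %d kept, %d discarded\n",
           "  speed-up x%.3g%s\n"),
    x$n_planes, x$scan_steps, x$step_size, x$dz, x$raw_frames,
    x$sections_generated, x$sections_kept, x$sections_discarded,
    x$speedup_factor,
    if (is.na(x$volume_rate)) "" else
      sprintf(", volume rate %.3g Hz", x$volume_rate)))
  invisible(x)
}

new_volume_stack <- function(sections, dz, pixel_size, provenance = list()) {
  structure(list(sections = sections, dz = dz, pixel_size = pixel_size,
                 provenance = provenance),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$sections)
  cat(sprintf("<volume_stack> %d sections of %d x %d px, dz %.3g um, pixel %.4g um\n",
              d[3], d[1], d[2], x$dz, x$pixel_size))
  invisible(x)
}

#' Section z coordinates of a volume stack
#' @param stack a `volume_stack`.
#' @return numeric vector of section z positions (um, first section at 0).
#' @export
stack_z <- function(stack) {
  stopifnot(inherits(stack, "volume_stack"))
  (seq_len(dim(stack$sections)[3]) - 1) * stack$dz
}

reconstruct_core <- function(frames, grid, plan, hilo_params_ = hilo_params(),
                             use_hilo = TRUE, normalize = FALSE,
                             pixel_size = NA_real_) {
  stopifnot(inherits(grid, "tile_grid"), inherits(plan, "acquisition_plan"))
  if (length(frames) != plan$scan_steps) {
    stop(sprintf("expected %d scan positions, got %d frame pairs",
                 plan$scan_steps, length(frames)), call. = FALSE)
  }
  n <- plan$n_planes
  if (grid$rows * grid$cols < n) {
    stop("tile grid holds fewer tiles than planes", call. = FALSE)
  }
  sections <- vector("list", plan$sections_generated)
  etas <- rep(NA_real_, plan$sections_generated)
  for (p in seq_along(frames)) {
    fp <- frames[[p]]
    if (use_hilo) {
      if (!inherits(fp, "frame_pair")) {
        stop(sprintf("scan position %d is missing an illumination state (need a frame_pair)", p),
             call. = FALSE)
      }
      tu <- crop_tiles(fp$uniform, grid)
      ts <- crop_tiles(fp$speckle, grid)
    } else {
      u <- if (inherits(fp, "frame_pair")) fp$uniform else fp
      if (!is.matrix(u)) {
        stop(sprintf("scan position %d holds no uniform frame", p),
             call. = FALSE)
      }
      tu <- crop_tiles(u, grid)
    }
    for (k in seq_len(n)) {
      z_idx <- (p - 1L) * n + k
      if (use_hilo) {
        sec <- hilo_reconstruct(frame_pair(tu[[k]], ts[[k]]), hilo_params_)
        etas[z_idx] <- attr(sec, "eta")
        attributes(sec) <- list(dim = dim(sec))
      } else {
        sec <- tu[[k]]
      }
      if (normalize) {
        tot <- sum(sec)
        if (tot > 0) sec <- sec * (length(sec) / tot)
      }
      sections[[z_idx]] <- sec
    }
  }
  keep <- seq_len(plan$sections_kept)
  arr <- array(unlist(sections[keep]),
               dim = c(dim(sections[[1]]), length(keep)))
  new_volume_stack(arr, dz = plan$dz, pixel_size = pixel_size,
                   provenance = list(plan = unclass(plan),
                                     hilo = use_hilo,
                                     normalized = normalize,
                                     eta = etas[keep]))
}

#' Reconstruct an optically sectioned volume from an axial scan
#'
#' For each scan position the multiplexed uniform and speckle frames are
#' cropped into per-plane tiles (ordered by ascending `delta_l` via the
#' grid's `plane_order`), each tile pair is sectioned with
#' [hilo_reconstruct()], and the sections are interleaved so that section
#' `z`-index = `(position - 1) * n_planes + plane_rank`. The trailing
#' `sections_discarded` sections (imaging beyond the specimen) are dropped
#' from the end of the stack.
#'
#' @param frames list of [frame_pair()]s, one per scan position, in scan
#'   order (stage advancing by `plan$step_size` per position).
#' @param grid a [tile_grid()].
#' @param plan an [plan_acquisition()] plan.
#' @param hilo a [hilo_params()].
#' @param normalize if `TRUE`, rescale every section to equal total intensity
#'   (integral normalization); default `FALSE`.
#' @param hilo_bypass if `TRUE`, skip HiLo and stack the uniform tiles
#'   directly (equivalent to [widefield_baseline()]).
#' @param pixel_size object-space lateral pixel size (um) recorded in the
#'   stack.
#' @return a `volume_stack` of `sections_kept` sections.
#' @export
reconstruct_volume <- function(frames, grid, plan, hilo = hilo_params(),
                               normalize = FALSE, hilo_bypass = FALSE,
                               pixel_size = NA_real_) {
  reconstruct_core(frames, grid, plan, hilo, use_hilo = !hilo_bypass,
                   normalize = normalize, pixel_size = pixel_size)
}

#' Widefield baseline volume (no HiLo)
#'
#' Same interleaving as [reconstruct_volume()] but using only the
#' uniform-illumination frame at each position: the comparison baseline of
#' cropped, stacked widefield tiles.
#'
#' @inheritParams reconstruct_volume
#' @return a `volume_stack`.
#' @export
widefield_baseline <- function(frames, grid, plan, normalize = FALSE,
                               pixel_size = NA_real_) {
  reconstruct_core(frames, grid, plan, use_hilo = FALSE,
                   normalize = normalize, pixel_size = pixel_size)
}
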