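# TIFF and config I/O.

#' Write a list of images as a multi-page TIFF
#'
#' Images are written as 32-bit float pages. Values are stored as-is divided
#' by `scale`; pass `scale = max(...)` to keep within [0, 1] for maximum
#' viewer compatibility (the scale used is recorded in the return value).
#'
#' @param images a matrix, a list of matrices, or a 3-D array (sections along
#'   the third dimension).
#' @param path output file path.
#' @param scale divisor applied before writing; `NULL` picks the global
#'   maximum (or 1 when the data are all zero / already within [0, 1]).
#' @return invisibly, the scale used.
#' @export
write_image_stack <- function(images, path, scale = NULL) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3) {
    images <- lapply(seq_len(dim(images)[3]), function(k) images[, , k])
  }
  mx <- max(vapply(images, max, numeric(1)), 0)
  if (is.null(scale)) scale <- if (mx > 1) mx else 1
  pages <- lapply(images, function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  invisible(scale)
}

#' Read a single- or multi-page TIFF as a list of matrices
#'
#' Float TIFFs are returned as stored; integer TIFFs are normalized to
#' `[0, 1]` (the usual R image convention — a linear rescaling that the HiLo
#' chain is insensitive to).
#'
#' @param path TIFF file path.
#' @return list of numeric matrices.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1] # drop extra channels
    p
  })
}

#' Write a reconstructed volume stack
#'
#' Writes the sections as a multi-page 32-bit float TIFF plus a JSON sidecar
#' holding the spacing, pixel size, intensity scale and provenance.
#'
#' @param stack a `volume_stack`.
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return invisibly, the sidecar path.
#' @export
write_volume_stack <- function(stack, path) {
  stopifnot(inherits(stack, "volume_stack"))
  scale <- write_image_stack(stack$sections, path)
  meta <- list(dz_um = stack$dz, pixel_size_um = stack$pixel_size,
               n_sections = dim(stack$sections)[3],
               intensity_scale = scale,
               provenance = stack$provenance)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML (or JSON) configuration with optional sections `optics`
#' (arguments of [optical_train()]), `plan` (`spacings`, `anchor`,
#' `tile_layout`, `tile_px`, `weights`, `zero_order_plane`), `tiles`
#' (arguments of [tile_grid()]), `hilo` (arguments of [hilo_params()]),
#' `gs` (arguments of [gs_config()]) and `acquisition` (arguments of
#' [plan_acquisition()]), and builds the corresponding objects. Unknown keys
#' are rejected. Lengths follow each constructor's units (um unless stated).
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return list with any of `train`, `plan`, `grid`, `hilo`, `gs`, `acq`
#'   plus `config_hash` (md5 of the canonicalized config).
#' @export
read_mfm_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("optics", "plan", "tiles", "hilo", "gs", "acquisition", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  out <- list(seed = cfg$seed)
  out$train <- do.call(optical_train, cfg$optics %||% list())
  if (!is.null(cfg$plan)) {
    args <- cfg$plan
    args$train <- out$train
    out$plan <- do.call(plan_from_spacings, args)
  }
  if (!is.null(cfg$tiles)) out$grid <- do.call(tile_grid, cfg$tiles)
  if (!is.null(cfg$hilo)) out$hilo <- do.call(hilo_params, cfg$hilo)
  if (!is.null(cfg$gs)) out$gs <- do.call(gs_config, cfg$gs)
  if (!is.null(cfg$acquisition)) {
    out$acq <- do.call(plan_acquisition, cfg$acquisition)
  }
  out$config_hash <- digest_config(cfg)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order-independent fingerprint of a config list (no external digest dep)
digest_config <- function(cfg) {
  canon <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(canon)) *
                        (seq_along(utf8ToInt(as.character(canon))) %% 97 + 1)) %%
            .Machine$integer.max)
}
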