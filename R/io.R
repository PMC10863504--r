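## Readers and writers: 16-bit grayscale TIFF with JSON sidecars for raster
## images, JSON for corelet images, and a binary container (R serialization)
## for transmission matrices and mode sets.

#' Write a raster image as 16-bit TIFF plus JSON sidecar
#'
#' Pixels are written as uncompressed 16-bit grayscale counts; out-of-mask
#' (invalid) pixels are filled with 0 in the file and the mask is recorded
#' in the sidecar, so the round trip is exact.  Values must be nonnegative
#' integers; values above 65535 are clipped with a warning.
#'
#' @param image a [raster_image()] with integer-valued pixels.
#' @param path output `.tif` path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_raster_image <- function(image, path) {
  if (!inherits(image, "raster_image"))
    hf_invalid("`image` must be a raster_image")
  px <- image$pixels
  px[is.na(px)] <- 0
  px <- round(px)
  if (any(px < 0)) hf_invalid("pixel counts must be nonnegative")
  if (any(px > 65535)) {
    warning("pixel counts above 65535 clipped in the 16-bit export")
    px[px > 65535] <- 65535
  }
  ## TIFF rows run top-down; flip so row 1 (our -y) lands at the bottom
  tiff::writeTIFF(px[rev(seq_len(nrow(px))), , drop = FALSE] / 65535, path,
                  bits.per.sample = 16L, compression = "none")
  side <- list(
    shape = dim(image$pixels), pitch_um = image$pitch,
    core_diameter_um = image$plan$core_diameter,
    working_distance_um = image$plan$working_distance,
    scale = 65535L,
    mask_true_index = which(image$mask),
    metadata = image$metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster image written by [write_raster_image()]
#'
#' @param path the `.tif` path (sidecar expected at `<path>.json`).
#' @return a [raster_image()]-like object with integer pixel counts and NA
#'   outside the recorded mask.
#' @export
read_raster_image <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path)
  px <- round(px * side$scale)
  px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
  mask <- matrix(FALSE, side$shape[1], side$shape[2])
  mask[side$mask_true_index] <- TRUE
  px[!mask] <- NA_real_
  plan <- list(n = side$shape[1], pitch = side$pitch_um,
               core_diameter = side$core_diameter_um,
               working_distance = side$working_distance_um, mask = mask)
  structure(list(pixels = px, mask = mask, pitch = side$pitch_um,
                 plan = plan, metadata = side$metadata),
            class = "raster_image")
}

#' Write a corelet image as JSON
#'
#' Values and lattice positions in spiral order.
#'
#' @param image a `corelet_image` ([corelet_scan_image()]).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_corelet_image <- function(image, path) {
  jsonlite::write_json(list(spiral_rank = image$spiral_rank,
                            x_um = image$x, y_um = image$y,
                            value = image$value),
                       path, digits = NA)
  invisible(path)
}

#' Read a corelet image written by [write_corelet_image()]
#' @param path the `.json` path.
#' @return a `corelet_image` data frame.
#' @export
read_corelet_image <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- data.frame(spiral_rank = d$spiral_rank, x = d$x_um, y = d$y_um,
                    value = d$value)
  class(out) <- c("corelet_image", "data.frame")
  out
}

#' Persist a transmission matrix or mode set to a binary container
#'
#' One self-describing binary file (R serialization, version 3) holding the
#' arrays plus seed and provenance metadata.
#'
#' @param object a `transmission_matrix`, `mode_set` or `measured_tm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_container <- function(object, path) {
  saveRDS(list(format = "holofiber-container", version = 1L,
               class = class(object)[1], object = object),
          path, version = 3)
  invisible(path)
}

#' Read an object written by [write_container()]
#' @param path container path.
#' @return the stored object.
#' @export
read_container <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "holofiber-container"))
    hf_invalid("not a holofiber container file")
  x$object
}
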