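## Reading and writing the pipeline's on-disk formats: single-channel TIFF
## band images in, PNG masks, float TIFF index rasters, CSV feature tables
## and a JSON session manifest out.

BANDS <- c("green", "red", "red_edge", "nir")

#' Construct a band image
#'
#' A single spectral band held as a 2-D reflectance raster. Pixel values are
#' real-valued so downstream index arithmetic "admits decimal values";
#' integer sensor data must be rescaled to [0, 1] first (see
#' [read_band_tiff()]).
#'
#' @param pixels numeric matrix, finite and non-negative where defined
#'   (NA marks undefined pixels, e.g. borders exposed by shifting).
#' @param band one of `"green"`, `"red"`, `"red_edge"`, `"nir"`.
#' @return object of class `band_image` with fields `pixels` and `band`.
#' @export
band_image <- function(pixels, band) {
  assert_matrix(pixels, "pixels")
  band <- match.arg(band, BANDS)
  vals <- pixels[!is.na(pixels)]
  if (length(vals) && (any(!is.finite(vals)) || any(vals < 0)))
    stop_arg("pixel values must be finite and >= 0 where defined")
  structure(list(pixels = pixels, band = band), class = "band_image")
}

#' @export
print.band_image <- function(x, ...) {
  cat(sprintf("<band_image> %s, %d x %d px\n",
              x$band, nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' @export
dim.band_image <- function(x) dim(x$pixels)

#' Read one spectral band from a single-channel TIFF
#'
#' 8- and 16-bit integer images are rescaled to [0, 1] by dividing by the
#' type maximum (255 or 65535); floating-point TIFFs are taken as already
#' calibrated reflectance. The rescale is monotone, so percentile-based
#' segmentation and normalized indices are unaffected by its choice.
#'
#' @param path path to a TIFF file.
#' @param band band label to attach.
#' @return a [band_image()].
#' @export
read_band_tiff <- function(path, band) {
  band <- match.arg(band, BANDS)
  if (!file.exists(path)) stop_arg("cannot read TIFF: ", path)
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 1L) px <- px[, , 1L]
    else stop_arg("expected a single-channel image for a spectral band, got ",
                  dim(px)[3], " channels: ", path)
  }
  band_image(px, band)
}

#' Write a band image as TIFF
#'
#' Float 32-bit output; undefined pixels are encoded as `nodata`.
#' @param img a [band_image()] or numeric matrix.
#' @param path output path.
#' @param nodata sentinel written in place of NA.
#' @export
write_band_tiff <- function(img, path, nodata = -9999) {
  px <- if (inherits(img, "band_image")) img$pixels else img
  assert_matrix(px)
  px[is.na(px)] <- nodata
  tiff::writeTIFF(px, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Write a binary plant mask as a lossless PNG
#'
#' @param mask a [plant_mask()] or logical matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  px <- if (inherits(mask, "plant_mask")) mask$pixels else mask
  if (!is.matrix(px)) stop_arg("mask must be a matrix")
  px <- !is.na(px) & (px != 0)
  png::writePNG(matrix(as.numeric(px), nrow(px), ncol(px)), path)
  invisible(path)
}

#' Read a mask PNG written by [write_mask()]
#'
#' @param path path to the PNG.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  px > 0.5
}

#' Write an index raster as float TIFF with a JSON sidecar
#'
#' TIFF float storage here carries values in [0, 1], so index values
#' (which range over [-1, 1] for normalized differences and are unbounded
#' for ratios) are stored affinely encoded: defined values are mapped
#' linearly onto [0.25, 1] and undefined pixels (NA) to exactly 0. The
#' `<path>.json` sidecar records the offset/scale so [read_index_tiff()]
#' restores the original values (float32 precision) and the NA pattern.
#'
#' @param index an [index_image()] or numeric matrix.
#' @param path output path (sidecar written next to it).
#' @export
write_index_tiff <- function(index, path) {
  px <- if (inherits(index, "index_image")) index$values else index
  nm <- if (inherits(index, "index_image")) index$name else NA_character_
  assert_matrix(px)
  def <- !is.na(px)
  if (any(def)) {
    lo <- min(px[def]); hi <- max(px[def])
    span <- if (hi > lo) hi - lo else 1
  } else {
    lo <- 0; span <- 1
  }
  enc <- matrix(0, nrow(px), ncol(px))
  enc[def] <- 0.25 + 0.75 * (px[def] - lo) / span
  tiff::writeTIFF(enc, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(index = nm, offset = lo, scale = span),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_index_tiff
#' @export
read_index_tiff <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  meta <- jsonlite::read_json(paste0(path, ".json"))
  out <- matrix(NA_real_, nrow(px), ncol(px))
  def <- px >= 0.125                       # 0 = undefined, >= 0.25 defined
  out[def] <- (px[def] - 0.25) / 0.75 * meta$scale + meta$offset
  out
}

#' Write a long-format feature table as CSV
#'
#' Columns `plant_id, treatment, week, variable, value`; values are
#' serialized with 17 significant digits so read-back is value-exact and
#' repeated runs are byte-identical.
#'
#' @param rows data.frame with the five trial-table columns.
#' @param path output path.
#' @export
write_feature_table <- function(rows, path) {
  cols <- c("plant_id", "treatment", "week", "variable", "value")
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop_arg("rows must be a non-empty data.frame")
  if (!all(cols %in% names(rows)))
    stop_arg("feature table needs columns: ", paste(cols, collapse = ", "))
  rows <- rows[, cols]
  out <- rows
  out$value <- ifelse(is.na(rows$value), "NA", sprintf("%.17g", rows$value))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  df$week <- as.integer(df$week)
  df
}

#' Read or write a session manifest
#'
#' The manifest lists one entry per plant acquisition: plant id, treatment
#' label (T0-T3), week, camera height in metres, and the four per-band TIFF
#' paths. Stored as JSON.
#'
#' @param path JSON file path.
#' @return list of entries, each a list with fields `plant_id`, `treatment`,
#'   `week`, `camera_height_m`, `band_paths` (named by band).
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- raw$entries %||% raw
  lapply(entries, validate_manifest_entry)
}

#' @rdname read_manifest
#' @param entries list of manifest entries.
#' @export
write_manifest <- function(entries, path) {
  lapply(entries, validate_manifest_entry)
  jsonlite::write_json(list(entries = entries), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

validate_manifest_entry <- function(e) {
  need <- c("plant_id", "treatment", "week", "band_paths")
  if (!all(need %in% names(e)))
    stop_arg("manifest entry needs fields: ", paste(need, collapse = ", "))
  if (!e$treatment %in% c("T0", "T1", "T2", "T3"))
    stop_arg("treatment must be one of T0-T3, got ", e$treatment)
  if (!all(BANDS %in% names(e$band_paths)))
    stop_arg("manifest entry must list all four bands: ",
             paste(BANDS, collapse = ", "))
  if (as.numeric(e$week) < 0) stop_arg("week must be non-negative")
  e
}
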