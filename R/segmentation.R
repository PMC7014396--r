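## Plant extraction: NDVI-percentile histogram segmentation plus
## largest-connected-component filtering.
##
## Healthy tissue has high NIR and low red reflectance, so its NDVI stands
## well above soil, pot and floor. Rather than a fixed NDVI cut (fragile
## across backgrounds), the rule is data-driven per image: among pixels
## whose NDVI exceeds a low gate (default 0.1), keep the top fraction
## (default 92%) of the NDVI value distribution, then keep only the largest
## connected object to drop speckle.

#' Segmentation parameters
#'
#' @param min_index hard gate on the index value (NDVI units); only pixels
#'   strictly above it are candidates. Default 0.1.
#' @param keep_fraction fraction of the candidate value distribution
#'   retained, from the top. Default 0.92.
#' @param connectivity neighbour adjacency for the largest-object step
#'   (4 or 8). Default 8.
#' @export
segmentation_params <- function(min_index = 0.1, keep_fraction = 0.92,
                                connectivity = 8L) {
  if (!(keep_fraction > 0 && keep_fraction <= 1))
    stop_arg("keep_fraction must be in (0, 1]")
  if (!connectivity %in% c(4L, 8L)) stop_arg("connectivity must be 4 or 8")
  structure(list(min_index = min_index, keep_fraction = keep_fraction,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Construct a plant mask
#'
#' @param pixels logical matrix.
#' @param connectivity adjacency used to produce it.
#' @param source description of index + parameters used (provenance).
#' @export
plant_mask <- function(pixels, connectivity = 8L, source = list()) {
  if (!is.matrix(pixels)) stop_arg("pixels must be a matrix")
  pixels <- !is.na(pixels) & (pixels != 0)
  structure(list(pixels = pixels, connectivity = as.integer(connectivity),
                 source = source), class = "plant_mask")
}

#' @export
print.plant_mask <- function(x, ...) {
  cat(sprintf("<plant_mask> %d x %d px, %d foreground\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' @export
dim.plant_mask <- function(x) dim(x$pixels)

#' Percentile threshold of an index image
#'
#' Candidates are the defined pixels with value strictly above
#' `params$min_index`. The retained set is the candidates at or above the
#' `(1 - keep_fraction)` quantile of the candidate values (linear
#' interpolation of order statistics; ties at the cut are retained). With
#' no candidates an empty mask is returned with a warning, not an error.
#'
#' @param index an [index_image()] (NDVI in the standard pipeline).
#' @param params a [segmentation_params()].
#' @return logical matrix of retained pixels.
#' @export
threshold_index <- function(index, params = segmentation_params()) {
  vals <- if (inherits(index, "index_image")) index$values else index
  assert_matrix(vals, "index")
  cand <- !is.na(vals) & vals > params$min_index
  if (!any(cand)) {
    warning("no candidate pixels above the index gate; empty mask",
            call. = FALSE)
    return(matrix(FALSE, nrow(vals), ncol(vals)))
  }
  cut <- stats::quantile(vals[cand], probs = 1 - params$keep_fraction,
                         type = 7, names = FALSE)
  cand & !is.na(vals) & vals >= cut
}

#' Keep only the largest connected component
#'
#' Equal-size tie-break: the component containing the lexicographically
#' smallest (row, col) pixel wins, so the result is deterministic.
#'
#' @param binary logical matrix.
#' @param connectivity 4 or 8.
#' @param source provenance list carried into the mask.
#' @return a [plant_mask()] (empty input gives an empty mask).
#' @export
largest_component <- function(binary, connectivity = 8L, source = list()) {
  lab <- label_components(binary, connectivity)
  n <- max(lab)
  if (n == 0L)
    return(plant_mask(matrix(FALSE, nrow(binary), ncol(binary)),
                      connectivity, source))
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  ## labels are assigned in (row, col) raster order of first pixels, so the
  ## smallest label among maximal sizes is the documented tie-break
  winner <- which(sizes == max(sizes))[1]
  plant_mask(lab == winner, connectivity, source)
}

#' Segment the plant from a registered frame
#'
#' Composition of [compute_index()] (NDVI), [threshold_index()] and
#' [largest_component()]. The returned mask records the parameters used.
#' The `strategy = "nir"` alternative thresholds the raw NIR band instead
#' of NDVI; it is provided for comparison only and is not the default (it
#' does not separate plant from bright background reliably).
#'
#' @param frame an [msframe()].
#' @param params a [segmentation_params()].
#' @param strategy `"ndvi"` (default) or `"nir"`.
#' @return a [plant_mask()].
#' @export
segment_plant <- function(frame, params = segmentation_params(),
                          strategy = c("ndvi", "nir")) {
  strategy <- match.arg(strategy)
  if (strategy == "ndvi") {
    idx <- compute_index(frame, "NDVI")
    src_vals <- idx
  } else {
    src_vals <- frame$bands$nir
  }
  thr <- threshold_index(src_vals, params)
  largest_component(thr, params$connectivity,
                    source = list(strategy = strategy,
                                  min_index = params$min_index,
                                  keep_fraction = params$keep_fraction,
                                  connectivity = params$connectivity))
}

#' Restrict an index image to a mask
#'
#' Values are kept inside the mask and undefined (NA) outside, so that any
#' downstream statistic sees plant tissue only.
#'
#' @param index an [index_image()].
#' @param mask a [plant_mask()] or logical matrix of the same shape.
#' @return an [index_image()] with support exactly `mask & defined(index)`.
#' @export
apply_mask <- function(index, mask) {
  stopifnot(inherits(index, "index_image"))
  px <- if (inherits(mask, "plant_mask")) mask$pixels else mask
  if (!identical(dim(index$values), dim(px)))
    stop_arg("index and mask shapes differ")
  out <- index
  out$values[!(!is.na(px) & px != 0)] <- NA_real_
  out
}
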