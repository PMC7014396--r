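## Per-pixel vegetation indices computed from a registered four-band frame.
##
## Eleven indices are supported. Two of the commonly reprinted formulas
## circulate in typographically corrupted form: MSR printed without the
## square root collapses to a monotone transform of SR, and NLI is sometimes
## printed with the red-edge band in the denominator. The canonical
## literature forms (MSR with the square root, NLI with red in both places)
## are the default; the literal as-printed variants are available with
## `formulas = "as-printed"`.

INDEX_NAMES <- c("NDVI", "GNDVI", "RENDVI", "NLI", "OSAVI", "GRVI",
                 "MSR", "SR", "NDRER", "SPI2", "LCI")

## Each formula maps (G, R, E, N) matrices to an index matrix. Zero
## denominators are handled afterwards by .safe_div.
.index_formulas <- function(formulas = c("canonical", "as-printed")) {
  formulas <- match.arg(formulas)
  f <- list(
    NDVI   = function(G, R, E, N) .safe_div(N - R, N + R),
    GNDVI  = function(G, R, E, N) .safe_div(N - G, N + G),
    RENDVI = function(G, R, E, N) .safe_div(N - E, N + E),
    NLI    = function(G, R, E, N) .safe_div(N^2 - R, N^2 + R),
    OSAVI  = function(G, R, E, N) 1.5 * .safe_div(N - R, N + R + 0.16),
    GRVI   = function(G, R, E, N) .safe_div(N, G),
    MSR    = function(G, R, E, N) {
      sr <- .safe_div(N, R)
      .safe_div(sr - 1, sqrt(sr) + 1)
    },
    SR     = function(G, R, E, N) .safe_div(N, R),
    NDRER  = function(G, R, E, N) .safe_div(E - R, E + R),
    SPI2   = function(G, R, E, N) .safe_div(N - G, N - R),
    LCI    = function(G, R, E, N) .safe_div(N - E, N + R)
  )
  if (formulas == "as-printed") {
    f$MSR <- function(G, R, E, N) {
      sr <- .safe_div(N, R)
      .safe_div(sr - 1, sr + 1)
    }
    f$NLI <- function(G, R, E, N) .safe_div(N^2 - R, N^2 + E)
  }
  f
}

## Elementwise division with zero denominators mapped to NA (undefined),
## never infinities.
.safe_div <- function(num, den) {
  out <- num / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Construct an index image
#'
#' @param values numeric matrix; NA marks undefined pixels (zero
#'   denominators, sentinel inputs, or pixels outside a mask).
#' @param name index name.
#' @export
index_image <- function(values, name) {
  assert_matrix(values, "values")
  name <- match.arg(name, INDEX_NAMES)
  structure(list(values = values, name = name), class = "index_image")
}

#' @export
print.index_image <- function(x, ...) {
  cat(sprintf("<index_image> %s, %d x %d px, %d undefined\n", x$name,
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Compute one vegetation index over a registered frame
#'
#' Pixelwise evaluation of the index formula on the four band rasters.
#' Pixels where any input band is undefined, or where the formula's
#' denominator vanishes, are undefined (NA) in the result. The four
#' normalized-difference indices (NDVI, GNDVI, RENDVI, NDRER) lie in
#' [-1, 1] wherever defined, for non-negative reflectances.
#'
#' @param frame an [msframe()].
#' @param name one of NDVI, GNDVI, RENDVI, NLI, OSAVI, GRVI, MSR, SR,
#'   NDRER, SPI2, LCI.
#' @param formulas `"canonical"` (default) or `"as-printed"` (see file
#'   header note on MSR/NLI variants).
#' @return an [index_image()].
#' @export
compute_index <- function(frame, name, formulas = "canonical") {
  stopifnot(inherits(frame, "msframe"))
  name <- match.arg(name, INDEX_NAMES)
  f <- .index_formulas(formulas)[[name]]
  vals <- f(frame$bands$green, frame$bands$red,
            frame$bands$red_edge, frame$bands$nir)
  ## propagate undefinedness from any input band
  undef <- is.na(frame$bands$green) | is.na(frame$bands$red) |
    is.na(frame$bands$red_edge) | is.na(frame$bands$nir)
  vals[undef] <- NA_real_
  vals[!is.finite(vals)] <- NA_real_
  index_image(vals, name)
}

#' Compute all eleven vegetation indices
#'
#' @inheritParams compute_index
#' @return named list of eleven [index_image()]s in the stable order
#'   NDVI, GNDVI, RENDVI, NLI, OSAVI, GRVI, MSR, SR, NDRER, SPI2, LCI.
#' @export
compute_all_indices <- function(frame, formulas = "canonical") {
  out <- lapply(INDEX_NAMES, compute_index, frame = frame,
                formulas = formulas)
  names(out) <- INDEX_NAMES
  out
}

#' Mean index value over a plant mask
#'
#' Average of the defined index values under the mask; undefined pixels are
#' excluded from both numerator and denominator. This is the per-plant
#' summary fed to the statistics layer.
#'
#' @param index an [index_image()].
#' @param mask a [plant_mask()] or logical matrix of the same shape.
#' @return scalar mean.
#' @export
masked_mean <- function(index, mask) {
  vals <- if (inherits(index, "index_image")) index$values else index
  px <- if (inherits(mask, "plant_mask")) mask$pixels else mask
  if (!identical(dim(vals), dim(px))) stop_arg("index and mask shapes differ")
  sel <- vals[!is.na(px) & (px != 0)]
  sel <- sel[!is.na(sel)]
  if (!length(sel))
    stop_arg("masked_mean: no defined index pixels under the mask")
  mean(sel)
}
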