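## Inter-band registration by integer pixel shifts, and AOI clipping.
##
## The four Sequoia lenses are physically offset, so at close range (0.7-1.4 m
## instead of the >= 30 m the camera was designed for) the four band images
## are displaced relative to each other. The red band is the reference; the
## other three are translated onto it by fixed per-band integer shifts,
## calibrated once from a scene with a reference point. Shift convention:
## dx moves content along the x (column) axis, dy along the y (row) axis,
## i.e. the pixel at (row, col) lands at (row + dy, col + dx).

#' Per-band shift factor
#'
#' @param dx,dy signed integer displacements in pixels (columns, rows).
#' @param band band label the shift applies to.
#' @export
shift_factor <- function(dx, dy, band) {
  band <- match.arg(band, BANDS)
  structure(list(dx = as.integer(dx), dy = as.integer(dy), band = band),
            class = "shift_factor")
}

#' Calibrated shift profiles
#'
#' The default profile carries the close-range calibration used throughout:
#' green [50, 23], NIR [41, -34], red edge [68, -11] (read as [dx, dy]),
#' with red the unshifted reference. The same values are used for both
#' camera heights (0.7 m and 1.4 m) until recalibrated with
#' [estimate_shift()]. `"none"` is the all-zero profile.
#'
#' @param name `"0.7m"`, `"1.4m"` or `"none"`.
#' @return named list of [shift_factor()]s for green, red_edge and nir.
#' @export
shift_profile <- function(name = c("0.7m", "1.4m", "none")) {
  name <- match.arg(name)
  if (name == "none") {
    sf <- list(green = shift_factor(0, 0, "green"),
               red_edge = shift_factor(0, 0, "red_edge"),
               nir = shift_factor(0, 0, "nir"))
  } else {
    sf <- list(green = shift_factor(50, 23, "green"),
               red_edge = shift_factor(68, -11, "red_edge"),
               nir = shift_factor(41, -34, "nir"))
  }
  structure(sf, profile = name)
}

## Translate a matrix by (dx, dy); exposed borders become `fill`.
shift_matrix <- function(m, dx, dy, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  if (abs(dx) >= nc || abs(dy) >= nr)
    stop_arg("shift (", dx, ", ", dy, ") exceeds image size ", nr, " x ", nc)
  out <- matrix(fill, nr, nc)
  src_r <- max(1L, 1L - dy):min(nr, nr - dy)
  src_c <- max(1L, 1L - dx):min(nc, nc - dx)
  out[src_r + dy, src_c + dx] <- m[src_r, src_c]
  out
}

#' Shift a band image by an integer pixel offset
#'
#' Content is translated by (dx, dy); border pixels exposed by the
#' translation are set to NA (undefined) rather than a fabricated
#' reflectance, so they never contaminate index statistics. The default AOI
#' discards these borders anyway (all calibrated shifts are < the 200 px
#' AOI margin).
#'
#' @param img a [band_image()].
#' @param shift a [shift_factor()].
#' @return shifted [band_image()], same shape.
#' @export
shift_image <- function(img, shift) {
  stopifnot(inherits(img, "band_image"), inherits(shift, "shift_factor"))
  out <- img
  out$pixels <- shift_matrix(img$pixels, shift$dx, shift$dy)
  out
}

#' Co-register the four bands into a multispectral frame
#'
#' The red band is the unshifted reference; green, red edge and NIR are
#' translated by their profile shifts so all four line up.
#'
#' @param bands named list of four [band_image()]s
#'   (`green`, `red`, `red_edge`, `nir`), identical shapes.
#' @param shifts a [shift_profile()] (or named list of [shift_factor()]s).
#' @param metadata optional list (plant_id, treatment, week, camera_height_m).
#' @return a `msframe` object: `$bands` is a named list of pixel matrices,
#'   `$metadata` the acquisition metadata.
#' @export
align_bands <- function(bands, shifts = shift_profile("0.7m"),
                        metadata = list()) {
  if (!all(BANDS %in% names(bands)))
    stop_arg("all four bands required: ", paste(BANDS, collapse = ", "))
  dims <- lapply(bands[BANDS], function(b) dim(b$pixels))
  if (length(unique(dims)) != 1L)
    stop_arg("band images must have identical shapes")
  px <- list(red = bands$red$pixels)
  for (b in c("green", "red_edge", "nir")) {
    s <- shifts[[b]]
    if (is.null(s)) stop_arg("shift profile lacks band ", b)
    px[[b]] <- shift_matrix(bands[[b]]$pixels, s$dx, s$dy)
  }
  msframe(px[BANDS], metadata)
}

#' Construct a multispectral frame
#'
#' @param bands named list of four shape-identical numeric matrices.
#' @param metadata acquisition metadata list.
#' @export
msframe <- function(bands, metadata = list()) {
  if (!all(BANDS %in% names(bands))) stop_arg("all four bands required")
  bands <- bands[BANDS]
  dims <- lapply(bands, dim)
  if (length(unique(dims)) != 1L) stop_arg("bands must be shape-identical")
  structure(list(bands = bands, metadata = metadata), class = "msframe")
}

#' @export
print.msframe <- function(x, ...) {
  d <- dim(x$bands$red)
  cat(sprintf("<msframe> %d x %d px, bands: %s\n", d[1], d[2],
              paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

#' @export
dim.msframe <- function(x) dim(x$bands$red)

#' Estimate the displacement between two bands
#'
#' Automates the one-off manual calibration: finds the integer (dx, dy)
#' within +/- `max_shift` that maximizes the cross-correlation of the
#' mean-centred images. The search is exhaustive over the shift window; the
#' correlation surface is evaluated with an FFT, which is algebraically the
#' same zero-padded sum of products at every offset. A normalized peak below
#' `min_confidence` flags the estimate as low-confidence (warning +
#' `confidence` attribute).
#'
#' @param reference,moving [band_image()]s of identical shape.
#' @param max_shift half-width of the search window in pixels.
#' @param min_confidence floor on the normalized peak correlation.
#' @return a [shift_factor()] such that `shift_image(moving, result)` aligns
#'   onto `reference`; carries attributes `confidence` and `low_confidence`.
#' @export
estimate_shift <- function(reference, moving, max_shift = 100L,
                           min_confidence = 0.3) {
  ref <- if (inherits(reference, "band_image")) reference$pixels else reference
  mov <- if (inherits(moving, "band_image")) moving$pixels else moving
  if (!identical(dim(ref), dim(mov))) stop_arg("images must be same shape")
  ref[is.na(ref)] <- 0; mov[is.na(mov)] <- 0
  if (stats::sd(ref) == 0 || stats::sd(mov) == 0)
    stop_arg("cannot estimate shift from a constant image")
  ref <- ref - mean(ref); mov <- mov - mean(mov)
  nr <- nrow(ref); nc <- ncol(ref)
  pr <- nr + 2L * max_shift; pc <- nc + 2L * max_shift
  A <- matrix(0, pr, pc); B <- matrix(0, pr, pc)
  A[seq_len(nr), seq_len(nc)] <- ref
  B[seq_len(nr), seq_len(nc)] <- mov
  ## cross-correlation: corr(dy, dx) = sum_k ref[k + d] * mov[k]
  cc <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE)) /
    (pr * pc)
  lag <- function(i, n) ifelse(i - 1L <= n %/% 2L, i - 1L, i - 1L - n)
  dys <- lag(seq_len(pr), pr); dxs <- lag(seq_len(pc), pc)
  keep_r <- which(abs(dys) <= max_shift)
  keep_c <- which(abs(dxs) <= max_shift)
  win <- cc[keep_r, keep_c, drop = FALSE]
  best <- arrayInd(which.max(win), dim(win))
  dy <- dys[keep_r[best[1]]]; dx <- dxs[keep_c[best[2]]]
  conf <- max(win) / (sqrt(sum(ref^2)) * sqrt(sum(mov^2)))
  low <- conf < min_confidence
  if (low)
    warning("low-confidence shift estimate (normalized peak ",
            signif(conf, 3), " < ", min_confidence, ")", call. = FALSE)
  mb <- if (inherits(moving, "band_image")) moving$band else "nir"
  out <- shift_factor(dx, dy, mb)
  attr(out, "confidence") <- conf
  attr(out, "low_confidence") <- low
  out
}

#' Area of interest (rectangular crop)
#'
#' Half-open, 0-based pixel ranges: `x` indexes the first (row) dimension and
#' `y` the second (column) dimension, matching the original matrix-subscript
#' convention in which a 960 x 1280 frame clipped with x 200:900 and
#' y 200:1000 becomes 700 x 800. [parse_aoi()] converts the `"200:900"`
#' string notation.
#'
#' @param x,y integer vectors `c(from, to)`, half-open `[from, to)`.
#' @export
aoi <- function(x = c(200L, 900L), y = c(200L, 1000L)) {
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != 2L || length(y) != 2L || x[1] < 0 || y[1] < 0 ||
      x[2] <= x[1] || y[2] <= y[1])
    stop_arg("AOI ranges must be non-empty half-open intervals [from, to)")
  structure(list(x = x, y = y), class = "aoi")
}

#' @rdname aoi
#' @param x_spec,y_spec strings like `"200:900"`.
#' @export
parse_aoi <- function(x_spec, y_spec) {
  parse1 <- function(s) {
    p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
    if (length(p) != 2L || anyNA(p)) stop_arg("bad AOI range: ", s)
    p
  }
  aoi(parse1(x_spec), parse1(y_spec))
}

#' Clip a frame to an area of interest
#'
#' @param frame an [msframe()].
#' @param roi an [aoi()]; the default is the standard central crop that
#'   takes a 960 x 1280 frame to 700 x 800 and removes shift borders.
#' @return clipped [msframe()].
#' @export
clip_aoi <- function(frame, roi = aoi()) {
  stopifnot(inherits(frame, "msframe"), inherits(roi, "aoi"))
  d <- dim(frame$bands$red)
  if (roi$x[2] > d[1] || roi$y[2] > d[2])
    stop_arg("AOI [", roi$x[1], ",", roi$x[2], ") x [", roi$y[1], ",",
             roi$y[2], ") outside image ", d[1], " x ", d[2])
  rows <- (roi$x[1] + 1L):roi$x[2]
  cols <- (roi$y[1] + 1L):roi$y[2]
  frame$bands <- lapply(frame$bands, function(m) m[rows, cols, drop = FALSE])
  frame
}
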