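## Binary shape descriptors of a segmented plant mask, with the classic
## regionprops semantics: pixel-count areas, convex hull over pixel centres,
## bounding-box extent, hole-aware Euler number and filled area, equivalent
## ellipse from normalized second central moments (with the +1/12 per-pixel
## variance term, so a single pixel has positive axis lengths), and the
## 8-connected boundary chain length as perimeter.

MORPHO_VARIABLES <- c("Area", "ConvexArea", "Eccentricity", "EquivDiameter",
                      "EulerNumber", "Extent", "FilledArea", "Orientation",
                      "MajorAxisLength", "MinorAxisLength", "Perimeter",
                      "Solidity")

.mask_pixels <- function(mask) {
  px <- if (inherits(mask, "plant_mask")) mask$pixels else mask
  if (!is.matrix(px)) stop_arg("mask must be a matrix or plant_mask")
  !is.na(px) & (px != 0)
}

#' Rasterized convex hull of a mask
#'
#' Marks every pixel whose centre lies inside or on the convex hull of the
#' mask's pixel centres; always a superset of the mask. With fewer than
#' three non-collinear pixels the hull degenerates to the pixel set itself.
#'
#' @param mask a [plant_mask()] or logical matrix.
#' @return logical matrix.
#' @export
convex_hull_mask <- function(mask) {
  px <- .mask_pixels(mask)
  idx <- which(px)
  if (!length(idx)) return(px)
  pr <- row(px)[idx]; pc <- col(px)[idx]
  pts <- cbind(x = pc, y = pr)
  hull <- grDevices::chull(pts)
  if (length(hull) < 3L) return(px)
  v <- pts[hull, , drop = FALSE]
  area2 <- sum(v[, 1] * v[c(2:nrow(v), 1), 2] -
                 v[c(2:nrow(v), 1), 1] * v[, 2])
  if (abs(area2) < 1e-9) return(px)      # collinear
  if (area2 < 0) v <- v[nrow(v):1, , drop = FALSE]  # normalize to CCW
  ## test every pixel centre of the bounding box against all hull edges
  rr <- min(pr):max(pr); cc <- min(pc):max(pc)
  qx <- rep(cc, each = length(rr)); qy <- rep(rr, times = length(cc))
  inside <- rep(TRUE, length(qx))
  n <- nrow(v)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (v[j, 1] - v[i, 1]) * (qy - v[i, 2]) -
      (v[j, 2] - v[i, 2]) * (qx - v[i, 1])
    inside <- inside & (cr >= -1e-9)
  }
  out <- matrix(FALSE, nrow(px), ncol(px))
  out[cbind(qy[inside], qx[inside])] <- TRUE
  out | px
}

## Moore-neighbour boundary tracing (clockwise on screen, row axis down).
## Returns the closed boundary walk as a matrix of (row, col); a single
## isolated pixel yields a 1-row walk.
.trace_boundary <- function(px) {
  idx <- which(px)
  if (!length(idx)) stop_arg("cannot trace an empty mask")
  nr <- nrow(px); nc <- ncol(px)
  ## clockwise direction table starting east, for y (row) pointing down
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  dir_index <- matrix(NA_integer_, 3L, 3L)
  for (k in 1:8) dir_index[dr[k] + 2L, dc[k] + 2L] <- k
  rs <- (idx - 1L) %% nr + 1L; cs <- (idx - 1L) %/% nr + 1L
  o <- order(rs, cs)
  sr <- rs[o[1]]; sc <- cs[o[1]]
  at <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && px[r, c]
  d0 <- 5L                              # backtrack west of the start pixel
  p <- c(sr, sc); d <- d0
  walk <- list(p)
  first_move <- NULL
  steps <- 0L
  ## advance one Moore step from (p, d); NULL if p is isolated
  advance <- function(p, d) {
    for (s in 1:8) {
      k <- (d - 1L + s) %% 8L + 1L
      qr <- p[1] + dr[k]; qc <- p[2] + dc[k]
      if (at(qr, qc)) {
        kb <- (d - 1L + s - 1L) %% 8L + 1L   # last background checked
        br <- p[1] + dr[kb]; bc <- p[2] + dc[kb]
        return(list(q = c(qr, qc),
                    d = dir_index[br - qr + 2L, bc - qc + 2L]))
      }
    }
    NULL
  }
  repeat {
    nxt <- advance(p, d)
    if (is.null(nxt)) break             # isolated pixel
    ## Jacob's stopping criterion: back at the start pixel and about to
    ## repeat the first move
    if (!is.null(first_move) && p[1] == sr && p[2] == sc &&
        all(nxt$q == first_move)) break
    if (is.null(first_move)) first_move <- nxt$q
    p <- nxt$q; d <- nxt$d
    walk[[length(walk) + 1L]] <- p
    steps <- steps + 1L
    if (steps > 8L * length(idx) + 8L)
      stop("boundary tracing failed to terminate")  # defensive; unreachable
  }
  do.call(rbind, walk)
}

#' Boundary chain length of a mask
#'
#' Traces the closed outer boundary of the (single-component) region and
#' sums the Euclidean step lengths: 1 for 4-neighbour moves, sqrt(2) for
#' diagonal moves. A single pixel has perimeter 0 (a closed chain of one
#' pixel).
#'
#' @param mask a [plant_mask()] or logical matrix with one component.
#' @return scalar chain length in pixels.
#' @export
trace_perimeter <- function(mask) {
  px <- .mask_pixels(mask)
  walk <- .trace_boundary(px)
  if (nrow(walk) < 2L) return(0)
  closed <- rbind(walk, walk[1L, ])
  sum(sqrt(rowSums((closed[-1L, , drop = FALSE] -
                      closed[-nrow(closed), , drop = FALSE])^2)))
}

#' Compute the twelve shape descriptors of a plant mask
#'
#' Expects a single-component mask (the output of [largest_component()]).
#' Descriptors:
#' \describe{
#'   \item{Area}{foreground pixel count.}
#'   \item{ConvexArea}{pixel count of [convex_hull_mask()].}
#'   \item{Eccentricity}{of the equivalent ellipse, sqrt(major^2 -
#'     minor^2) / major, in [0, 1].}
#'   \item{EquivDiameter}{diameter of the equal-area circle,
#'     sqrt(4 * Area / pi).}
#'   \item{EulerNumber}{objects minus holes (8-connected objects,
#'     4-connected holes); 1 - holes for a single component.}
#'   \item{Extent}{Area / bounding-box area.}
#'   \item{FilledArea}{pixel count after filling holes.}
#'   \item{Orientation}{angle in degrees between the x (column) axis and the
#'     ellipse major axis, counter-clockwise positive with y up (image rows
#'     flipped), in (-90, 90].}
#'   \item{MajorAxisLength, MinorAxisLength}{axes of the ellipse with the
#'     same normalized second central moments as the region, each pixel
#'     treated as a unit square (+1/12 variance term).}
#'   \item{Perimeter}{boundary chain length, [trace_perimeter()].}
#'   \item{Solidity}{Area / ConvexArea.}
#' }
#' Ellipse moments are computed on the unfilled mask.
#'
#' @param mask a [plant_mask()] or logical matrix, non-empty, one component.
#' @return named list of class `morpho_features` with the 12 descriptors.
#' @export
compute_features <- function(mask) {
  px <- .mask_pixels(mask)
  area <- sum(px)
  if (area == 0L) stop_arg("cannot compute features of an empty mask")
  conn <- if (inherits(mask, "plant_mask")) mask$connectivity else 8L
  lab <- label_components(px, 8L)
  if (max(lab) > 1L)
    stop_arg("mask has ", max(lab),
             " components; run largest_component() first")
  rs <- row(px)[px]; cs <- col(px)[px]
  bb_area <- (diff(range(rs)) + 1L) * (diff(range(cs)) + 1L)
  hull <- convex_hull_mask(px)
  convex_area <- sum(hull)
  filled <- fill_holes(px)
  filled_area <- sum(filled)
  holes <- .count_holes(px)

  ## equivalent ellipse from normalized second central moments, y up
  x <- cs; y <- -rs
  uxx <- mean((x - mean(x))^2) + 1 / 12
  uyy <- mean((y - mean(y))^2) + 1 / 12
  uxy <- mean((x - mean(x)) * (y - mean(y)))
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major <- 2 * sqrt(2) * sqrt(uxx + uyy + common)
  minor <- 2 * sqrt(2) * sqrt(max(uxx + uyy - common, 0))
  orientation <- if (common < .Machine$double.eps) 0 else
    (180 / pi) * 0.5 * atan2(2 * uxy, uxx - uyy)

  structure(list(
    Area = as.numeric(area),
    ConvexArea = as.numeric(convex_area),
    Eccentricity = sqrt(max(major^2 - minor^2, 0)) / major,
    EquivDiameter = sqrt(4 * area / pi),
    EulerNumber = 1L - holes,
    Extent = area / bb_area,
    FilledArea = as.numeric(filled_area),
    Orientation = orientation,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    Perimeter = trace_perimeter(px),
    Solidity = area / convex_area
  ), class = "morpho_features", connectivity = conn)
}

#' @export
print.morpho_features <- function(x, ...) {
  cat("<morpho_features>\n")
  for (v in MORPHO_VARIABLES)
    cat(sprintf("  %-16s %s\n", v, format(x[[v]], digits = 6)))
  invisible(x)
}

#' @export
as.data.frame.morpho_features <- function(x, ...) {
  data.frame(variable = MORPHO_VARIABLES,
             value = vapply(MORPHO_VARIABLES, function(v) as.numeric(x[[v]]),
                            numeric(1)),
             row.names = NULL)
}
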