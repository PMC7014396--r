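## Internal helpers shared across modules. Images are plain numeric matrices
## indexed [row, col]; undefined pixels are NA. The x axis is the column axis
## and the y axis the row axis for shift operations (see registration.R).

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

assert_matrix <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_arg(what, " must be a numeric matrix")
  invisible(x)
}

## Linear-index neighbours within an nr x nc grid.
.neighbour_idx <- function(idx, nr, nc, connectivity = 8L) {
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  if (connectivity == 8L) {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  rr <- rep(r, times = length(dr)) + rep(dr, each = length(r))
  cc <- rep(c, times = length(dc)) + rep(dc, each = length(c))
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  (cc[ok] - 1L) * nr + rr[ok]
}

#' Label connected components of a binary matrix
#'
#' Breadth-first flood fill from unlabelled foreground seeds. Labels are
#' assigned in raster-scan order of each component's first pixel when pixels
#' are ordered by (row, col), so labelling is deterministic.
#'
#' @param m logical (or 0/1 numeric) matrix; NA counts as background.
#' @param connectivity 4 or 8 neighbour adjacency.
#' @return integer matrix of component labels, 0 = background.
#' @keywords internal
label_components <- function(m, connectivity = 8L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop_arg("connectivity must be 4 or 8")
  nr <- nrow(m); nc <- ncol(m)
  fg <- !is.na(m) & (m != 0)
  lab <- matrix(0L, nr, nc)
  idx_all <- which(fg)
  if (!length(idx_all)) return(lab)
  ## order seeds lexicographically by (row, col)
  rs <- (idx_all - 1L) %% nr + 1L
  cs <- (idx_all - 1L) %/% nr + 1L
  idx_all <- idx_all[order(rs, cs)]
  next_label <- 0L
  for (seed in idx_all) {
    if (lab[seed] != 0L) next
    next_label <- next_label + 1L
    lab[seed] <- next_label
    frontier <- seed
    while (length(frontier)) {
      nb <- unique(.neighbour_idx(frontier, nr, nc, connectivity))
      nb <- nb[fg[nb] & lab[nb] == 0L]
      lab[nb] <- next_label
      frontier <- nb
    }
  }
  lab
}

## Background reachable from the image border (4-connectivity by default).
## Everything background-but-unreached is a hole.
.outside_background <- function(m, connectivity = 4L) {
  nr <- nrow(m); nc <- ncol(m)
  bg <- is.na(m) | (m == 0)
  border <- unique(c(
    seq_len(nr),                       # first column
    (nc - 1L) * nr + seq_len(nr),      # last column
    (seq_len(nc) - 1L) * nr + 1L,      # first row
    (seq_len(nc) - 1L) * nr + nr       # last row
  ))
  seeds <- border[bg[border]]
  outside <- matrix(FALSE, nr, nc)
  outside[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    nb <- unique(.neighbour_idx(frontier, nr, nc, connectivity))
    nb <- nb[bg[nb] & !outside[nb]]
    outside[nb] <- TRUE
    frontier <- nb
  }
  outside
}

#' Fill holes in a binary matrix
#'
#' A hole is background not 4-connected to the image border.
#' @keywords internal
fill_holes <- function(m) {
  fg <- !is.na(m) & (m != 0)
  fg | (!fg & !.outside_background(fg))
}

## Count holes (4-connected enclosed background regions).
.count_holes <- function(m) {
  fg <- !is.na(m) & (m != 0)
  holes <- !fg & !.outside_background(fg)
  max(label_components(holes, 4L))
}

## Deterministic seed derivation: keep derived seeds in 32-bit range.
.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}
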