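## Independent brute-force oracles used to validate the implementation.
## These deliberately use different algorithms from the package internals.

## O(V * iterations) label propagation: every foreground pixel starts with
## its own label; repeatedly take the min over the neighbourhood until a
## fixpoint. Independent of the package's BFS flood fill.
oracle_label <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  fg <- !is.na(m) & (m != 0)
  lab <- matrix(0L, nr, nc)
  lab[fg] <- seq_len(sum(fg))
  offs <- if (connectivity == 8)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  pad <- function(mm, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- mm[rs - dr, cs - dc]
    out
  }
  repeat {
    new_lab <- lab
    for (o in offs) {
      nb <- pad(ifelse(fg, lab, Inf), o[1], o[2])
      new_lab <- ifelse(fg, pmin(new_lab, nb), 0L)
    }
    if (all(new_lab == lab)) break
    lab <- new_lab
  }
  ## renumber 1..k in order of first appearance by (row, col)
  ids <- unique(lab[order(row(lab), col(lab))])
  ids <- ids[ids != 0]
  out <- matrix(0L, nr, nc)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

## Point-in-convex-hull by hull-area comparison: p is inside the hull of
## pts iff adding it does not grow the hull area.
oracle_in_hull <- function(p, pts) {
  shoelace <- function(xy) {
    h <- grDevices::chull(xy)
    v <- xy[h, , drop = FALSE]
    if (nrow(v) < 3) return(0)
    j <- c(2:nrow(v), 1)
    abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
  }
  a0 <- shoelace(pts)
  a1 <- shoelace(rbind(pts, p))
  a1 <= a0 + 1e-9
}

oracle_convex_mask <- function(px) {
  idx <- which(px)
  pts <- cbind(col(px)[idx], row(px)[idx])
  out <- matrix(FALSE, nrow(px), ncol(px))
  rr <- min(row(px)[idx]):max(row(px)[idx])
  cc <- min(col(px)[idx]):max(col(px)[idx])
  for (r in rr) for (c in cc)
    out[r, c] <- oracle_in_hull(c(c, r), pts)
  out | px
}

## Hole filling by iterative dilation of border-reachable background
## (vectorized shifts until fixpoint), different mechanism from the
## package's frontier BFS.
oracle_fill <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  bg <- !px
  reach <- matrix(FALSE, nr, nc)
  reach[1, ] <- bg[1, ]; reach[nr, ] <- bg[nr, ]
  reach[, 1] <- bg[, 1]; reach[, nc] <- bg[, nc]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -nc]
    grown[, -nc] <- grown[, -nc] | reach[, -1]
    grown <- grown & bg
    if (all(grown == reach)) break
    reach <- grown
  }
  px | (bg & !reach)
}

oracle_holes <- function(px) {
  filled <- oracle_fill(px)
  holes <- filled & !px
  max(oracle_label(holes, 4))
}

## Boundary chain length via EBImage's oriented contour (independent
## implementation of the same chain convention).
oracle_chain_length <- function(px) {
  img <- EBImage::bwlabel(matrix(as.integer(px), nrow(px), ncol(px)))
  ct <- EBImage::ocontour(img)[[1]]
  if (nrow(ct) < 2) return(0)
  closed <- rbind(ct, ct[1, ])
  sum(sqrt(rowSums((closed[-1, , drop = FALSE] -
                      closed[-nrow(closed), , drop = FALSE])^2)))
}

## Exhaustive modified band depth (triple loop over pairs and time points).
oracle_mbd <- function(curves) {
  n <- nrow(curves); p <- ncol(curves)
  depth <- numeric(n)
  npair <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    npair <- npair + 1
    for (i in 1:n) {
      cnt <- 0
      for (t in 1:p) {
        lo <- min(curves[a, t], curves[b, t])
        hi <- max(curves[a, t], curves[b, t])
        if (curves[i, t] >= lo && curves[i, t] <= hi) cnt <- cnt + 1
      }
      depth[i] <- depth[i] + cnt / p
    }
  }
  depth / npair
}

## Seeded random single-component blob: union of a few random disks around
## a centre, reduced to the component containing its first-placed disk.
random_blob <- function(seed, nr = 36, nc = 36, ndisks = 6) {
  set.seed(seed)
  px <- matrix(FALSE, nr, nc)
  cr <- nr / 2 + stats::runif(1, -4, 4)
  cc <- nc / 2 + stats::runif(1, -4, 4)
  for (i in seq_len(ndisks)) {
    r0 <- cr + stats::runif(1, -nr / 5, nr / 5)
    c0 <- cc + stats::runif(1, -nc / 5, nc / 5)
    rad <- stats::runif(1, 2.5, nr / 5)
    d <- sqrt((row(px) - r0)^2 + (col(px) - c0)^2)
    px <- px | (d <= rad)
  }
  px[c(1, nr), ] <- FALSE; px[, c(1, nc)] <- FALSE
  lab <- oracle_label(px, 8)
  sizes <- tabulate(lab[lab > 0])
  px & (lab == which.max(sizes))
}

## A small registered frame with known plant support, no noise.
toy_frame <- function(dim = c(120, 160), radius = 25, seed = 1,
                      noise_sd = 0) {
  sc <- phenomspec::generate_scene(phenomspec::scene_spec(
    dim = dim, base_radius = radius, noise_sd = noise_sd, seed = seed))
  list(frame = phenomspec::align_bands(sc$bands,
                                       phenomspec::shift_profile("none")),
       truth = sc$truth)
}
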