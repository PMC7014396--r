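square_mask <- function(side = 10, pad = 3) {
  m <- matrix(FALSE, side + 2 * pad, side + 2 * pad)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  m
}

disk_mask <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  d <- sqrt((row(matrix(0, n, n)) - ctr)^2 + (col(matrix(0, n, n)) - ctr)^2)
  d <= r
}

test_that("a solid square has the textbook descriptor values", {
  f <- compute_features(square_mask(10))
  expect_equal(f$Area, 100)
  expect_equal(f$FilledArea, 100)
  expect_equal(f$Extent, 1.0)
  expect_equal(f$EulerNumber, 1L)
  expect_equal(f$Perimeter, 36)          # 4 sides of 9 unit chain steps
  expect_equal(f$EquivDiameter, sqrt(400 / pi))
  expect_equal(f$Solidity, 1.0, tolerance = 1e-12)
  expect_equal(f$ConvexArea, 100)
  expect_equal(f$Eccentricity, 0)        # symmetric: major == minor
})

test_that("a square annulus has one hole: euler 0, filled > area", {
  m <- matrix(FALSE, 18, 18)
  m[4:15, 4:15] <- TRUE                  # 12 x 12 outer
  m[7:12, 7:12] <- FALSE                 # 6 x 6 hole
  f <- compute_features(m)
  expect_equal(f$Area, 144 - 36)
  expect_equal(f$FilledArea, 144)
  expect_equal(f$EulerNumber, 0L)
})

test_that("degenerate shapes behave as documented", {
  ## single pixel: zero perimeter, positive axes from the +1/12 correction
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  f1 <- compute_features(one)
  expect_equal(f1$Area, 1)
  expect_equal(f1$Perimeter, 0)
  expect_equal(f1$MajorAxisLength, 2 * sqrt(2) * sqrt(2 / 12))  # ~1.1547
  expect_equal(f1$MajorAxisLength, f1$MinorAxisLength)
  expect_equal(f1$ConvexArea, 1)
  ## 1 x 101 horizontal line: orientation 0, near-degenerate ellipse
  line <- matrix(FALSE, 5, 105); line[3, 3:103] <- TRUE
  fl <- compute_features(line)
  expect_equal(fl$Orientation, 0)
  expect_gt(fl$Eccentricity, 0.999)
  expect_gt(fl$MajorAxisLength / fl$MinorAxisLength, 50)
  ## vertical line: orientation 90 under the y-up convention
  vert <- matrix(FALSE, 105, 5); vert[3:103, 3] <- TRUE
  expect_equal(compute_features(vert)$Orientation, 90)
  expect_error(compute_features(matrix(FALSE, 4, 4)), "empty")
})

test_that("a rasterized disk approaches the analytic circle limits", {
  f <- compute_features(disk_mask(50))
  expect_lt(f$Eccentricity, 0.05)
  expect_equal(f$EquivDiameter, 100, tolerance = 0.02)
  expect_gte(f$Orientation, -90); expect_lte(f$Orientation, 90)
  expect_equal(f$Solidity, 1, tolerance = 0.02)
  ## chain length within 5% of the circle circumference 2*pi*r (the chain
  ## convention overestimates a smooth boundary by a few percent)
  expect_equal(f$Perimeter, 2 * pi * 50, tolerance = 0.05)
})

test_that("equiv diameter follows the equal-area-circle formula", {
  for (s in c(4, 7, 10)) {
    f <- compute_features(square_mask(s))
    expect_equal(f$EquivDiameter, sqrt(4 * s^2 / pi))
  }
})

test_that("convex hull mask fills notches and matches the area oracle", {
  ## L-shape: hull fills the notch
  L <- matrix(FALSE, 14, 14)
  L[3:12, 3:6] <- TRUE; L[9:12, 3:12] <- TRUE
  hull <- convex_hull_mask(L)
  f <- compute_features(L)
  expect_gt(f$ConvexArea, f$Area)
  expect_true(all(hull[L]))              # superset of the mask
  expect_identical(hull, oracle_convex_mask(L))
  ## convex shapes are their own hull
  sq <- square_mask(6)
  expect_identical(convex_hull_mask(sq), sq)
  ## single pixel degenerates to itself
  one <- matrix(FALSE, 4, 4); one[2, 3] <- TRUE
  expect_identical(convex_hull_mask(one), one)
  ## collinear pixels degenerate to the pixel set
  seg <- matrix(FALSE, 6, 6); seg[2, 2:5] <- TRUE
  expect_identical(convex_hull_mask(seg), seg)
})

test_that("descriptors match brute-force oracles on 50 seeded blobs", {
  skip_if_not_installed("EBImage")
  for (seed in 1:50) {
    px <- random_blob(seed)
    f <- compute_features(px)
    expect_equal(f$Area, sum(px))
    expect_equal(f$ConvexArea, sum(oracle_convex_mask(px)),
                 info = paste("seed", seed))
    expect_equal(f$FilledArea, sum(oracle_fill(px)))
    expect_equal(f$EulerNumber, 1L - oracle_holes(px))
    expect_equal(f$Perimeter, oracle_chain_length(px),
                 info = paste("seed", seed))
    rs <- range(row(px)[px]); cs <- range(col(px)[px])
    expect_equal(f$Extent, sum(px) / (diff(rs) + 1) / (diff(cs) + 1))
    expect_equal(f$Solidity, f$Area / f$ConvexArea)
    ## structural invariants
    expect_lte(f$Area, f$FilledArea)
    expect_lte(f$FilledArea, f$ConvexArea)
    expect_lte(f$MinorAxisLength, f$MajorAxisLength)
    expect_equal(f$Eccentricity,
                 sqrt(f$MajorAxisLength^2 - f$MinorAxisLength^2) /
                   f$MajorAxisLength)
  }
})

test_that("ellipse moments agree with an independent implementation on a
           smooth blob", {
  skip_if_not_installed("EBImage")
  px <- disk_mask(30)
  px <- px | phenomspec:::shift_matrix(disk_mask(30), 18, 7, FALSE) > 0
  px <- phenomspec:::fill_holes(px)
  f <- compute_features(px)
  img <- matrix(as.integer(px), nrow(px), ncol(px))
  mom <- EBImage::computeFeatures.moment(EBImage::bwlabel(img))
  ## EBImage omits the +1/12 pixel term; negligible at this size
  expect_equal(f$MajorAxisLength, mom[1, "m.majoraxis"], tolerance = 0.01)
  expect_equal(f$Eccentricity, mom[1, "m.eccentricity"], tolerance = 0.02)
})

test_that("descriptors are translation invariant; rotation by 90 degrees
           preserves area and perimeter and flips orientation", {
  px <- random_blob(99)
  f0 <- compute_features(px)
  shifted <- phenomspec:::shift_matrix(px, 3, 5, FALSE) > 0
  f1 <- compute_features(shifted)
  for (v in phenomspec:::MORPHO_VARIABLES)
    expect_equal(f1[[v]], f0[[v]], info = v)
  rot <- t(px)[ncol(px):1, ]             # 90 degree rotation
  fr <- compute_features(rot)
  expect_equal(fr$Area, f0$Area)
  expect_equal(fr$Perimeter, f0$Perimeter)
  expect_equal(fr$Eccentricity, f0$Eccentricity, tolerance = 1e-9)
  delta <- (fr$Orientation - f0$Orientation) %% 180
  expect_true(abs(delta - 90) < 1e-6)
})

test_that("3x nearest-neighbour upscaling scales descriptors as expected", {
  px <- disk_mask(30) | phenomspec:::shift_matrix(disk_mask(30), 20, 8,
                                                  FALSE) > 0
  px <- phenomspec:::fill_holes(px)
  big <- px[rep(seq_len(nrow(px)), each = 3),
            rep(seq_len(ncol(px)), each = 3)]
  f1 <- compute_features(px); f3 <- compute_features(big)
  expect_equal(f3$Area, 9 * f1$Area)
  expect_equal(f3$MajorAxisLength / f1$MajorAxisLength, 3, tolerance = 0.03)
  expect_equal(f3$MinorAxisLength / f1$MinorAxisLength, 3, tolerance = 0.03)
  for (v in c("Eccentricity", "Extent", "Solidity"))
    expect_equal(f3[[v]], f1[[v]], tolerance = 0.03, info = v)
  ## chain-length perimeter is resolution dependent: upscaling turns each
  ## diagonal step into a unit-step staircase, so the ratio exceeds k by a
  ## bounded staircase factor (< ~20%) instead of equalling k
  ratio <- f3$Perimeter / f1$Perimeter
  expect_gte(ratio, 3)
  expect_lte(ratio, 3 * 1.2)
})

test_that("multi-component masks are rejected", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE; m[7:8, 7:8] <- TRUE
  expect_error(compute_features(m), "largest_component")
})
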