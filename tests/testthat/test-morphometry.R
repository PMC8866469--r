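# Space detection and morphometry: labeling, measurement, Feret diameters,
# FAZ identification, partition invariants.

test_that("labeling separates an enclosed interior from the surrounding background", {
  v <- matrix(FALSE, 32, 32)
  v[10:22, 10] <- TRUE; v[10:22, 22] <- TRUE
  v[10, 10:22] <- TRUE; v[22, 10:22] <- TRUE   # white rectangle frame
  roi <- full_roi(32)
  lab <- label_spaces(as_vessel_map(v, roi = roi), roi, 4L)
  expect_identical(lab$n, 2L)
  inner <- lab$labels[16, 16]
  outer <- lab$labels[2, 16]
  expect_true(inner > 0 && outer > 0 && inner != outer)
})

test_that("an all-black ROI yields exactly one region covering the ROI", {
  roi <- full_roi(32)
  lab <- label_spaces(as_vessel_map(matrix(FALSE, 32, 32), roi = roi), roi)
  expect_identical(lab$n, 1L)
  expect_identical(sum(lab$labels == 1L), sum(roi_mask(roi)))
})

test_that("4-connectivity makes every checkerboard black pixel its own region", {
  v <- outer(1:16, 1:16, function(i, j) (i + j) %% 2 == 0)  # TRUE = vessel
  roi <- full_roi(16)
  lab4 <- label_spaces(as_vessel_map(v, roi = roi), roi, 4L)
  n_black <- sum(!v & roi_mask(roi))
  expect_identical(lab4$n, n_black)
  lab8 <- label_spaces(as_vessel_map(v, roi = roi), roi, 8L)
  expect_identical(lab8$n, 1L)   # diagonal contact joins all black squares
  expect_error(label_spaces(as_vessel_map(v, roi = roi), roi, 6L), "connectivity")
})

test_that("labeling requires a non-empty ROI", {
  img <- enface_image(matrix(0, 32, 32), 1)
  roi <- make_circular_roi(img, 32)
  roi$radius_px <- 0.1
  expect_error(label_spaces(as_vessel_map(matrix(TRUE, 32, 32), roi = roi), roi),
               "empty ROI")
})

test_that("a solid rectangle is measured exactly", {
  pitch <- 3 / 1024
  v <- matrix(TRUE, 256, 256)
  v[100:199, 60:109] <- FALSE  # 100 x 50 black rectangle
  roi <- full_roi(256, pitch)
  tab <- measure_spaces(label_spaces(as_vessel_map(v, pitch, roi), roi))
  r <- tab$regions[which.max(tab$regions$px_count), ]
  expect_identical(r$px_count, 5000L)
  expect_equal(r$area_mm2, 5000 * pitch^2, tolerance = 1e-12)
  expect_equal(r$max_diam_mm, sqrt(100^2 + 50^2) * pitch, tolerance = 1e-12)
  expect_equal(r$min_diam_mm, 50 * pitch, tolerance = 1e-3)
  expect_equal(r$ap_ratio, r$area_mm2 / r$perimeter_mm, tolerance = 1e-12)
})

test_that("a rasterized disk has area near pi r^2 and ratio near r/2", {
  pitch <- 3 / 1024
  n <- 256
  ctr <- (n + 1) / 2
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, `+`))
  v <- d > 100   # disk of radius 100 px is space; everything else vessel
  roi <- full_roi(n, pitch)
  tab <- measure_spaces(label_spaces(as_vessel_map(v, pitch, roi), roi))
  r <- tab$regions[which.max(tab$regions$px_count), ]
  expect_lt(abs(r$px_count - pi * 100^2) / (pi * 100^2), 0.01)
  expect_lt(abs(r$ap_ratio - 50 * pitch) / (50 * pitch), 0.10)
})

test_that("region measures satisfy the geometric invariants on random images", {
  set.seed(99)
  for (rep in 1:25) {
    v <- matrix(runif(48 * 48) < 0.45, 48, 48)
    roi <- full_roi(48)
    lab <- label_spaces(as_vessel_map(v, roi = roi), roi)
    if (lab$n < 1L) next
    tab <- measure_spaces(lab)
    r <- tab$regions
    expect_true(all(r$area_mm2 > 0))
    expect_true(all(r$perimeter_mm > 0))
    expect_true(all(r$min_diam_mm <= r$max_diam_mm + 1e-12))
    expect_true(all(r$min_diam_mm > 0))
    expect_true(all(r$area_mm2 <= r$min_diam_mm * r$max_diam_mm + 1e-12))
    expect_equal(r$ap_ratio, r$area_mm2 / r$perimeter_mm, tolerance = 1e-12)
    # partition: region pixels sum to non-vessel ROI pixels
    m <- roi_mask(roi)
    expect_identical(sum(r$px_count), sum(!v & m))
    expect_identical(sum(r$px_count) + sum(v & m), sum(m))
  }
})

test_that("isoperimetric sanity holds for regions wider than the chain-code bias scale", {
  # the pixel-center chain code undercuts the outline by ~1 px per side, so
  # the isoperimetric bound can only be expected for regions at least ~8 px
  # across (a 3x3 square already violates it: area 9, chain perimeter 8)
  an <- reference_analysis()
  r <- an$table$regions
  pitch <- an$table$pitch_mm
  plump <- r[r$min_diam_mm >= 8 * pitch, ]
  expect_gt(nrow(plump), 100)
  expect_true(all(plump$ap_ratio <= plump$perimeter_mm / (4 * pi) * 1.05))
})

test_that("label gaps are rejected", {
  roi <- full_roi(16)
  lab <- label_spaces(as_vessel_map(matrix(FALSE, 16, 16), roi = roi), roi)
  lab$labels[lab$labels == 1L] <- 2L
  lab$n <- 2L
  expect_error(measure_spaces(lab), "contiguous")
})

test_that("merging two regions by deleting the separating wall conserves pixels", {
  v <- matrix(FALSE, 24, 24)
  v[, 12] <- TRUE  # vertical wall splits the square
  roi <- full_roi(24)
  lab1 <- label_spaces(as_vessel_map(v, roi = roi), roi)
  tab1 <- measure_spaces(lab1)
  wall_px <- sum(v & roi_mask(roi))
  v2 <- matrix(FALSE, 24, 24)
  lab2 <- label_spaces(as_vessel_map(v2, roi = roi), roi)
  tab2 <- measure_spaces(lab2)
  expect_identical(lab1$n, 2L)
  expect_identical(lab2$n, 1L)
  expect_identical(tab2$regions$px_count,
                   sum(tab1$regions$px_count) + wall_px)
})

test_that("feret diameters match closed forms and the fine-angle sweep oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  fd <- feret_diameters(sq)
  expect_equal(unname(fd["min"]), 1, tolerance = 1e-12)
  expect_equal(unname(fd["max"]), sqrt(2), tolerance = 1e-12)
  col <- cbind(seq(0, 5, by = 0.5), 2 * seq(0, 5, by = 0.5))
  fc <- feret_diameters(col)
  expect_equal(unname(fc["min"]), 0, tolerance = 1e-12)
  expect_equal(unname(fc["max"]), sqrt(5^2 + 10^2), tolerance = 1e-12)
  expect_error(feret_diameters(rbind(c(1, 1), c(1, 1))), "distinct")
  set.seed(4)
  for (rep in 1:5) {
    pts <- matrix(runif(40), 20, 2)
    got <- feret_diameters(pts)
    want <- feret_sweep(pts)
    expect_equal(unname(got["max"]), unname(want["max"]), tolerance = 1e-6)
    expect_equal(unname(got["min"]), unname(want["min"]), tolerance = 1e-6)
  }
})

test_that("pixel-corner ferets give side s for an s-pixel square", {
  v <- matrix(TRUE, 16, 16)
  v[5:9, 5:9] <- FALSE  # 5x5 square region
  roi <- full_roi(16)
  tab <- measure_spaces(label_spaces(as_vessel_map(v, roi = roi), roi))
  r <- tab$regions[which.max(tab$regions$px_count), ]
  expect_equal(r$min_diam_mm, 5, tolerance = 1e-12)
  expect_equal(r$max_diam_mm, 5 * sqrt(2), tolerance = 1e-12)
})

test_that("the FAZ is the region containing the center, with a nearest-region fallback", {
  v <- matrix(FALSE, 33, 33)
  v[, 17] <- TRUE
  v[17, ] <- TRUE         # cross through the center pixel
  roi <- full_roi(33)
  lab <- label_spaces(as_vessel_map(v, roi = roi), roi)
  expect_identical(lab$n, 4L)
  # center pixel (17,17) is vessel: fallback picks the region of the nearest
  # black pixel, which is (16,16)'s quadrant by scan order of equal distances
  faz <- identify_faz(lab)
  expect_identical(faz, lab$labels[16, 16])
  # direct containment: clear the vessel cross at the center
  v2 <- v
  v2[17, 17] <- FALSE
  v2[16:18, 16] <- FALSE
  lab2 <- label_spaces(as_vessel_map(v2, roi = roi), roi)
  expect_identical(identify_faz(lab2), lab2$labels[17, 17])
  # all-vessel ROI errors
  expect_error(label_spaces(as_vessel_map(matrix(TRUE, 33, 33), roi = roi),
                            roi) |> identify_faz(), "no intercapillary")
})

test_that("marking the FAZ flags exactly one row", {
  sc <- small_scene()
  an <- analyze_eye(sc$stack)
  expect_identical(sum(an$table$regions$is_faz), 1L)
  expect_error(mark_faz(an$table, max(an$table$regions$id) + 1L), "not present")
})
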