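# Per-space morphometry: connected-component detection of intercapillary
# spaces inside the ROI, area / perimeter / Feret-diameter measurement, and
# identification of the foveal avascular zone.

#' Label intercapillary spaces
#'
#' Connected components of non-vessel (black) pixels inside the circular ROI,
#' the signal-inverted "particles" of the analysis. Spaces default to
#' 4-connectivity (vessel strokes are implicitly 8-connected, so a
#' single-pixel diagonal vessel line separates spaces); 8-connectivity is
#' available for compatibility with particle tracers.
#'
#' @param binary a `binary_vessel_map`.
#' @param roi a [make_circular_roi()]; defaults to the one attached to
#'   `binary`.
#' @param connectivity 4 or 8.
#' @return object of class `space_labels`: list with `labels` (integer
#'   matrix, 0 = vessel or outside ROI), `n`, `roi`, `pitch_mm`,
#'   `connectivity`.
#' @export
label_spaces <- function(binary, roi = binary$roi, connectivity = 4L) {
  stopifnot(inherits(binary, "binary_vessel_map"))
  if (is.null(roi)) stop("no ROI supplied or attached to the vessel map")
  stopifnot(inherits(roi, "circular_roi"))
  if (!identical(dim(binary$vessel), roi$dim)) stop("binary map and ROI shape mismatch")
  inroi <- roi_mask(roi)
  if (!any(inroi)) stop("empty ROI")
  mask <- !binary$vessel & inroi
  lab <- cpp_label_mask(mask, as.integer(connectivity))
  structure(list(labels = lab, n = max(lab), roi = roi,
                 pitch_mm = binary$pitch_mm,
                 connectivity = as.integer(connectivity)),
            class = "space_labels")
}

#' Minimum and maximum Feret diameters of a point set
#'
#' Maximum Feret diameter: the largest pairwise extent over all directions
#' (the diameter of the convex hull). Minimum Feret diameter: the smallest
#' width over all directions, attained perpendicular to a hull edge
#' (rotating-calipers width).
#'
#' @param points two-column matrix of planar coordinates (at least 2 distinct
#'   points).
#' @return named numeric vector `c(min = , max = )` in the units of `points`.
#' @export
feret_diameters <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) <= 512L) points <- unique(points)  # cheap exact-dup check
  if (nrow(points) < 2L ||
      (diff(range(points[, 1])) == 0 && diff(range(points[, 2])) == 0))
    stop("need at least 2 distinct points")
  h <- grDevices::chull(points)
  hull <- points[h, , drop = FALSE]
  nh <- nrow(hull)
  dmat <- as.matrix(stats::dist(hull))
  dmax <- max(dmat)
  if (nh <= 2L) return(c(min = 0, max = dmax))   # collinear
  # width perpendicular to each hull edge
  widths <- vapply(seq_len(nh), function(i) {
    a <- hull[i, ]
    b <- hull[if (i == nh) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    max(abs((hull[, 1] - a[1]) * (-e[2]) + (hull[, 2] - a[2]) * e[1]) / len)
  }, numeric(1))
  c(min = min(widths), max = dmax)
}

#' Measure every labeled intercapillary space
#'
#' Per region: area = pixel count x pitch^2; perimeter from the
#' (1, sqrt(2))-weighted 8-directional boundary chain code (single-pixel
#' regions use the pixel-outline value of 4 pixel widths); minimum and
#' maximum Feret diameters of the convex hull of the region's pixel-corner
#' points (so an s-pixel square has side length s); area/perimeter ratio;
#' centroid; and a flag for regions touching the ROI rim (8-adjacent to a
#' pixel outside the ROI).
#'
#' @param labels a [label_spaces()] result.
#' @param min_area_px optional minimum region size in pixels; smaller regions
#'   are dropped (default 0: no size filter).
#' @return object of class `space_table`: list with `regions` (data.frame),
#'   `pitch_mm`, `roi`, `connectivity`.
#' @export
measure_spaces <- function(labels, min_area_px = 0L) {
  stopifnot(inherits(labels, "space_labels"))
  lab <- labels$labels
  n <- labels$n
  if (n < 1L) stop("no labeled regions")
  pitch <- labels$pitch_mm
  counts <- tabulate(lab[lab > 0L], nbins = n)
  if (any(counts == 0L)) stop("labels must be contiguous 1..N")
  per_px <- cpp_region_perimeters(lab, n)
  per_px[per_px == 0] <- 4  # single-pixel outline convention
  touches <- cpp_touches_outside(lab, roi_mask(labels$roi), n)
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  ord <- order(lab[idx])
  idx <- idx[ord]
  ends <- cumsum(counts)
  starts <- c(1L, ends[-n] + 1L)
  minf <- maxf <- cx <- cy <- numeric(n)
  for (l in seq_len(n)) {
    px <- idx[starts[l]:ends[l]]
    i <- ((px - 1L) %% nr) + 1L
    j <- ((px - 1L) %/% nr) + 1L
    cx[l] <- mean(j)
    cy[l] <- mean(i)
    corners <- cbind(x = c(j - 0.5, j + 0.5, j - 0.5, j + 0.5),
                     y = c(i - 0.5, i - 0.5, i + 0.5, i + 0.5))
    fd <- feret_diameters(corners)
    minf[l] <- fd["min"]
    maxf[l] <- fd["max"]
  }
  reg <- data.frame(
    id = seq_len(n),
    px_count = counts,
    area_mm2 = counts * pitch^2,
    perimeter_mm = per_px * pitch,
    min_diam_mm = minf * pitch,
    max_diam_mm = maxf * pitch,
    ap_ratio = (counts * pitch^2) / (per_px * pitch),
    centroid_x_px = cx,
    centroid_y_px = cy,
    touches_roi_boundary = as.logical(touches),
    is_faz = FALSE)
  if (min_area_px > 0L) {
    reg <- reg[reg$px_count >= min_area_px, , drop = FALSE]
    rownames(reg) <- NULL
  }
  structure(list(regions = reg, pitch_mm = pitch, roi = labels$roi,
                 connectivity = labels$connectivity),
            class = "space_table")
}

#' Identify the foveal avascular zone
#'
#' The detected intercapillary space containing the center pixel of the
#' image. When the center pixel is a vessel pixel, the region holding the
#' nearest non-vessel pixel (Euclidean distance to the image center) is
#' used as a documented fallback.
#'
#' @param labels a [label_spaces()] result.
#' @return integer region id of the FAZ.
#' @export
identify_faz <- function(labels) {
  stopifnot(inherits(labels, "space_labels"))
  lab <- labels$labels
  if (labels$n < 1L) stop("no intercapillary spaces inside the ROI")
  nr <- nrow(lab)
  nc <- ncol(lab)
  ci <- floor((nr + 1L) / 2L)
  cj <- floor((nc + 1L) / 2L)
  l <- lab[ci, cj]
  if (l > 0L) return(l)
  idx <- which(lab > 0L)
  i <- ((idx - 1L) %% nr) + 1L
  j <- ((idx - 1L) %/% nr) + 1L
  ctr <- c((nc + 1) / 2, (nr + 1) / 2)
  lab[idx[which.min((j - ctr[1])^2 + (i - ctr[2])^2)]]
}

#' Mark the FAZ row of a space table
#'
#' @param table a [measure_spaces()] result.
#' @param faz_id region id from [identify_faz()].
#' @return the `space_table` with `is_faz` set on exactly one row.
#' @export
mark_faz <- function(table, faz_id) {
  stopifnot(inherits(table, "space_table"))
  if (!faz_id %in% table$regions$id) stop("faz_id not present in table")
  table$regions$is_faz <- table$regions$id == faz_id
  table
}
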