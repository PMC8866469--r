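# Preprocessing of en face OCTA images: intensity normalization, repeat-frame
# averaging, Gaussian denoising, Phansalkar adaptive local thresholding, and
# the central circular region of interest.

#' Construct an en face image object
#'
#' @param data numeric matrix of intensities in [0, 1].
#' @param pitch_mm physical pixel pitch (mm per pixel).
#' @param provenance `"single"` or `"averaged"`.
#' @return object of class `enface_image` (list: `data`, `pitch_mm`,
#'   `provenance`).
#' @export
enface_image <- function(data, pitch_mm, provenance = "single") {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!length(data)) stop("empty image")
  if (!is.numeric(pitch_mm) || length(pitch_mm) != 1L || pitch_mm <= 0)
    stop("pitch_mm must be a positive scalar")
  rng <- range(data, finite = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("intensities must lie in [0, 1]; use normalize_intensity() first")
  structure(list(data = data, pitch_mm = pitch_mm,
                 provenance = match.arg(provenance, c("single", "averaged"))),
            class = "enface_image")
}

#' Min-max normalize a raw intensity grid to [0, 1]
#'
#' Linear rescale of any integer or real bit depth; a constant image maps to
#' all zeros (documented convention). Already-normalized images with observed
#' minimum 0 and maximum 1 pass through unchanged.
#'
#' @param image numeric matrix (any range) or an `enface_image`.
#' @param pitch_mm pixel pitch in mm; defaults to a 3 mm field over the
#'   image width.
#' @param provenance provenance tag for the result.
#' @return an `enface_image`.
#' @export
normalize_intensity <- function(image, pitch_mm = NULL, provenance = "single") {
  if (inherits(image, "enface_image")) {
    pitch_mm <- pitch_mm %||% image$pitch_mm
    provenance <- image$provenance
    image <- image$data
  }
  if (!is.matrix(image) || !length(image)) stop("empty or non-matrix image")
  storage.mode(image) <- "double"
  pitch_mm <- pitch_mm %||% (3 / ncol(image))
  rng <- range(image, finite = TRUE)
  out <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
  else array(0, dim(image))
  enface_image(matrix(out, nrow(image), ncol(image)), pitch_mm, provenance)
}

#' Average co-registered repeat frames
#'
#' Pixel-wise arithmetic mean of at least two frames of the same eye, used to
#' recover vessels with transient flow-signal loss. Frames are assumed
#' co-registered.
#'
#' @param stack a `frame_stack` from [render_frames()], or a list of
#'   matrices / `enface_image`s of identical shape.
#' @param pitch_mm pixel pitch, required when `stack` is a list of bare
#'   matrices.
#' @return an `enface_image` with provenance `"averaged"`.
#' @export
average_frames <- function(stack, pitch_mm = NULL) {
  if (inherits(stack, "frame_stack")) {
    pitch_mm <- pitch_mm %||% stack$pitch_mm
    frames <- stack$frames
  } else {
    frames <- lapply(stack, function(f)
      if (inherits(f, "enface_image")) f$data else f)
    if (is.null(pitch_mm)) {
      p <- vapply(stack, function(f)
        if (inherits(f, "enface_image")) f$pitch_mm else NA_real_, numeric(1))
      pitch_mm <- p[!is.na(p)][1]
    }
  }
  if (length(frames) < 2L) stop("need at least 2 frames to average")
  d <- dim(frames[[1L]])
  for (f in frames) if (!identical(dim(f), d)) stop("frame shape mismatch")
  acc <- Reduce(`+`, frames) / length(frames)
  enface_image(acc, pitch_mm %||% (3 / d[2]), provenance = "averaged")
}

#' Gaussian blur for speckle-noise reduction
#'
#' Separable convolution with a normalized Gaussian kernel; `radius_px` is
#' the Gaussian sigma in pixels (the convention of the common image-analysis
#' tools, whose blur dialog takes "Sigma (Radius)"), truncated at 3 sigma.
#' Border windows are clipped and renormalized, so a constant image is
#' preserved exactly (DC gain 1).
#'
#' @param image an `enface_image` (or numeric matrix).
#' @param radius_px Gaussian sigma in pixels; 0 returns the input unchanged.
#' @return an `enface_image`.
#' @export
gaussian_blur <- function(image, radius_px = 2) {
  img <- if (inherits(image, "enface_image")) image else normalize_intensity(image)
  if (!is.numeric(radius_px) || length(radius_px) != 1L || radius_px < 0)
    stop("radius_px must be non-negative")
  if (radius_px == 0) return(img)
  K <- max(1L, as.integer(ceiling(3 * radius_px)))
  kern <- stats::dnorm(-K:K, sd = radius_px)
  kern <- kern / sum(kern)
  out <- cpp_sepconv_clip(img$data, kern)
  out[out < 0] <- 0
  out[out > 1] <- 1
  enface_image(out, img$pitch_mm, img$provenance)
}

#' Phansalkar threshold parameters
#'
#' Constants of the Phansalkar local threshold
#' t = m * (1 + p * exp(-q * m) + k * (s / r - 1)) with m, s the local mean
#' and standard deviation over a circular window. Defaults follow the common
#' reference implementation of the method; all are exposed because published
#' descriptions of the pipeline leave them unstated.
#'
#' @param window_radius_px radius of the circular window (pixels).
#' @param k,r,p,q dimensionless Phansalkar constants.
#' @return object of class `threshold_params`.
#' @export
threshold_params <- function(window_radius_px = 15L, k = 0.25, r = 0.5,
                             p = 2, q = 10) {
  if (window_radius_px < 1L) stop("window_radius_px must be >= 1")
  if (r <= 0) stop("r must be positive")
  structure(list(window_radius_px = as.integer(window_radius_px),
                 k = k, r = r, p = p, q = q),
            class = "threshold_params")
}

#' Phansalkar adaptive local thresholding
#'
#' Binarizes a normalized en face image: a pixel is vessel (white) when its
#' intensity exceeds t = m * (1 + p * exp(-q * m) + k * (s / r - 1)), with m
#' and s the mean and population standard deviation over the circular window
#' of `window_radius_px` centered on the pixel, clipped at image borders.
#'
#' @param image an `enface_image` normalized to [0, 1].
#' @param params a [threshold_params()].
#' @param roi optional [make_circular_roi()] to attach to the result.
#' @return object of class `binary_vessel_map`: list with `vessel` (logical
#'   matrix, TRUE = flow signal), `roi`, `pitch_mm`, `params`.
#' @export
phansalkar_threshold <- function(image, params = threshold_params(), roi = NULL) {
  stopifnot(inherits(image, "enface_image"), inherits(params, "threshold_params"))
  d <- dim(image$data)
  if (2L * params$window_radius_px + 1L > min(d))
    stop("threshold window larger than image")
  st <- cpp_disk_stats(image$data, params$window_radius_px)
  t <- st$mean * (1 + params$p * exp(-params$q * st$mean) +
                    params$k * (st$sd / params$r - 1))
  structure(list(vessel = image$data > t, roi = roi,
                 pitch_mm = image$pitch_mm, params = params),
            class = "binary_vessel_map")
}

#' Central circular region of interest
#'
#' The analysis circle centered on the image (the paper's pipeline restricts
#' morphometry to the central 2 mm of the 3 x 3 mm field). Pixel membership
#' uses the center-of-pixel rule.
#'
#' @param image an `enface_image` (square).
#' @param diameter_mm ROI diameter in mm.
#' @return object of class `circular_roi`: list with `center_px` (x, y in
#'   pixel units), `radius_px`, `diameter_mm`, `pitch_mm`, `dim`.
#' @export
make_circular_roi <- function(image, diameter_mm = 2.0) {
  stopifnot(inherits(image, "enface_image"))
  d <- dim(image$data)
  if (d[1] != d[2]) stop("image must be square")
  fov <- d[2] * image$pitch_mm
  if (diameter_mm > fov + 1e-9) stop("ROI diameter exceeds the field of view")
  radius_px <- diameter_mm / (2 * image$pitch_mm)
  structure(list(center_px = c((d[2] + 1) / 2, (d[1] + 1) / 2),
                 radius_px = radius_px, diameter_mm = diameter_mm,
                 pitch_mm = image$pitch_mm, dim = d),
            class = "circular_roi")
}

#' Logical mask of ROI pixel membership
#'
#' @param roi a [make_circular_roi()].
#' @return logical matrix; TRUE where the pixel center lies inside the circle.
#' @export
roi_mask <- function(roi) {
  stopifnot(inherits(roi, "circular_roi"))
  nr <- roi$dim[1]
  nc <- roi$dim[2]
  jx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  iy <- matrix(seq_len(nr), nr, nc)
  (jx - roi$center_px[1])^2 + (iy - roi$center_px[2])^2 <= roi$radius_px^2
}

#' Integer-shift frame alignment by maximal cross-correlation
#'
#' Optional rigid pre-alignment of repeat frames to the first frame: each
#' frame is shifted by the integer offset (within `max_shift_px`) maximizing
#' its cross-correlation with the first frame, with replicated borders. Off
#' by default in the pipeline: repeat frames are assumed co-registered.
#'
#' @param frames list of numeric matrices or `enface_image`s.
#' @param max_shift_px maximum absolute shift searched per axis.
#' @return list of matrices, aligned to the first frame.
#' @export
align_frames <- function(frames, max_shift_px = 5L) {
  mats <- lapply(frames, function(f)
    if (inherits(f, "enface_image")) f$data else f)
  ref <- mats[[1L]]
  shift_mat <- function(m, di, dj) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- pmin(pmax(seq_len(nr) - di, 1L), nr)
    cj <- pmin(pmax(seq_len(nc) - dj, 1L), nc)
    m[ri, cj, drop = FALSE]
  }
  out <- mats
  for (f in seq_along(mats)[-1L]) {
    best <- c(0L, 0L); bestcc <- -Inf
    for (di in -max_shift_px:max_shift_px) {
      for (dj in -max_shift_px:max_shift_px) {
        cc <- sum(ref * shift_mat(mats[[f]], di, dj))
        if (cc > bestcc) { bestcc <- cc; best <- c(di, dj) }
      }
    }
    out[[f]] <- shift_mat(mats[[f]], best[1], best[2])
  }
  out
}

#' Map of transient flow-signal loss
#'
#' Pixels that are vessel in the averaged-image binarization but not in the
#' single-frame binarization: flow present across repeat frames yet absent
#' from the raw frame, the signature of transient capillary plugging.
#'
#' @param single,averaged `binary_vessel_map`s of identical shape and ROI.
#' @return logical matrix of flagged pixels.
#' @export
transient_loss_map <- function(single, averaged) {
  stopifnot(inherits(single, "binary_vessel_map"),
            inherits(averaged, "binary_vessel_map"))
  if (!identical(dim(single$vessel), dim(averaged$vessel)))
    stop("shape mismatch between single and averaged maps")
  rs <- single$roi
  ra <- averaged$roi
  if (!identical(rs[c("center_px", "radius_px", "dim")],
                 ra[c("center_px", "radius_px", "dim")]))
    stop("ROI mismatch between single and averaged maps")
  averaged$vessel & !single$vessel
}
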