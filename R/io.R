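# End-to-end pipeline drivers and file interchange: image reading/writing,
# run configuration, whole-eye analysis, and synthetic eye/cohort simulation.

#' Run configuration for the quantification pipeline
#'
#' Collects every tunable of the analysis chain so a run can be reproduced
#' from its serialized configuration.
#'
#' @param fov_mm physical field of view of the input image (mm).
#' @param roi_diameter_mm diameter of the central analysis circle (mm).
#' @param blur_radius_px Gaussian sigma for speckle reduction (pixels).
#' @param threshold a [threshold_params()].
#' @param connectivity space connectivity, 4 or 8.
#' @param include_edge_regions keep regions touching the ROI rim (flagged).
#' @param min_area_px minimum region size in pixels (0 = no filter).
#' @param area_thresholds_mm2 area cut-points for thresholded counts.
#' @param ap_threshold area/perimeter-ratio cut-point.
#' @return object of class `run_config`.
#' @export
run_config <- function(fov_mm = 3.0, roi_diameter_mm = 2.0, blur_radius_px = 2,
                       threshold = threshold_params(), connectivity = 4L,
                       include_edge_regions = TRUE, min_area_px = 0L,
                       area_thresholds_mm2 = c(0.01, 0.02, 0.03, 0.04, 0.05),
                       ap_threshold = 0.025) {
  stopifnot(fov_mm > 0, roi_diameter_mm > 0, blur_radius_px >= 0,
            inherits(threshold, "threshold_params"),
            connectivity %in% c(4L, 8L), min_area_px >= 0,
            all(area_thresholds_mm2 > 0), ap_threshold > 0)
  structure(list(fov_mm = fov_mm, roi_diameter_mm = roi_diameter_mm,
                 blur_radius_px = blur_radius_px, threshold = threshold,
                 connectivity = as.integer(connectivity),
                 include_edge_regions = isTRUE(include_edge_regions),
                 min_area_px = as.integer(min_area_px),
                 area_thresholds_mm2 = area_thresholds_mm2,
                 ap_threshold = ap_threshold),
            class = "run_config")
}

#' Read a grayscale en face image (TIFF or PNG)
#'
#' @param path file path; multi-page TIFFs return the page list.
#' @param fov_mm physical field width used to derive the pixel pitch.
#' @return an `enface_image`, or a list of them for a multi-page TIFF.
#' @export
read_enface <- function(path, fov_mm = 3.0) {
  ext <- tolower(tools::file_ext(path))
  as_gray <- function(a) {
    if (length(dim(a)) == 3L) {
      if (dim(a)[3] >= 3L &&
          max(abs(a[, , 1] - a[, , 2]), abs(a[, , 1] - a[, , 3])) > 1e-9)
        stop("input image is not grayscale")
      a <- a[, , 1]
    }
    a
  }
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    imgs <- lapply(pages, function(p)
      normalize_intensity(as_gray(p), pitch_mm = fov_mm / ncol(as_gray(p))))
    if (length(imgs) == 1L) imgs[[1L]] else imgs
  } else if (ext == "png") {
    a <- as_gray(png::readPNG(path))
    normalize_intensity(a, pitch_mm = fov_mm / ncol(a))
  } else stop("unsupported image format: ", ext)
}

#' Write a frame stack as a multi-page 16-bit grayscale TIFF
#'
#' @param stack a `frame_stack`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_frames_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  tiff::writeTIFF(stack$frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Serialize ground truth to JSON (polygons, mm) and CSV (face metrics)
#'
#' @param gt a [ground_truth()].
#' @param json_path,csv_path output paths (either may be NULL to skip).
#' @param roi,pitch_mm passed to [true_face_metrics()] for the CSV.
#' @return invisibly, the face-metric data.frame.
#' @export
write_ground_truth <- function(gt, json_path = NULL, csv_path = NULL,
                               roi = NULL, pitch_mm = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  met <- true_face_metrics(gt, roi = roi, pitch_mm = pitch_mm)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      fov_mm = gt$fov_mm,
      faz_face_id = gt$faz_face_id,
      polygons = lapply(gt$polygons, function(p)
        list(x = p[, 1], y = p[, 2]))), json_path,
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) utils::write.csv(met, csv_path, row.names = FALSE)
  invisible(met)
}

#' Simulate one synthetic eye
#'
#' Chains [generate_capillary_graph()], [apply_dropout()] (at
#' `config$dropout_rate`) and [render_frames()]; the returned ground truth
#' reflects the post-dropout graph (the structures a perfect reader of the
#' rendered frames could recover).
#'
#' @param config a [scene_config()].
#' @return list with `graph`, `truth` (post-dropout), `stack`.
#' @export
simulate_eye <- function(config) {
  gen <- generate_capillary_graph(config)
  graph <- apply_dropout(gen$graph, config$dropout_rate,
                         rng_seed = config$rng_seed + 1L)
  truth <- if (config$dropout_rate > 0) ground_truth(graph) else gen$truth
  stack <- render_frames(graph, config)
  list(graph = graph, truth = truth, stack = stack)
}

#' Quantify the intercapillary spaces of one eye
#'
#' The full measurement chain of the paper-style pipeline: normalize, select
#' the single measured frame (transient and permanent signal loss are both
#' of interest, so measurement always uses a raw frame, not the average),
#' Gaussian blur, Phansalkar binarization of the full rectangular image, ROI
#' restriction, signal inversion and connected-component labeling, per-space
#' morphometry, FAZ identification and exclusion, and the per-eye spectrum
#' summary.
#'
#' @param image an `enface_image`, a numeric matrix, a `frame_stack`, or a
#'   list of frames (the first frame is measured).
#' @param config a [run_config()].
#' @param eye_id,grade carried into the spectrum row.
#' @return list of class `eye_analysis`: `spectrum` (one-row data.frame),
#'   `table` (a `space_table` with FAZ marked), `labels`, `binary`, `roi`,
#'   `averaged` (an averaged `binary_vessel_map`, when >= 2 frames were
#'   supplied, else NULL), `transient_map` (ditto), `config`.
#' @export
analyze_eye <- function(image, config = run_config(), eye_id = "eye",
                        grade = NA_character_) {
  stopifnot(inherits(config, "run_config"))
  frames <- NULL
  if (inherits(image, "frame_stack")) {
    frames <- lapply(image$frames, function(f)
      enface_image(f, image$pitch_mm))
  } else if (is.list(image) && !inherits(image, "enface_image")) {
    frames <- lapply(image, function(f)
      if (inherits(f, "enface_image")) f else
        normalize_intensity(f, pitch_mm = config$fov_mm / ncol(f)))
  } else {
    one <- if (inherits(image, "enface_image")) image else
      normalize_intensity(image, pitch_mm = config$fov_mm / ncol(image))
    frames <- list(one)
  }
  d <- dim(frames[[1L]]$data)
  if (d[1] != d[2]) stop("input image must be square")
  single <- frames[[1L]]
  prep <- function(img) {
    img <- gaussian_blur(img, config$blur_radius_px)
    phansalkar_threshold(img, config$threshold)
  }
  bin <- prep(single)
  roi <- make_circular_roi(single, config$roi_diameter_mm)
  bin$roi <- roi
  labels <- label_spaces(bin, roi, config$connectivity)
  if (labels$n < 1L)
    stop("no intercapillary spaces detected inside the ROI (all-vessel image?)")
  tab <- measure_spaces(labels, min_area_px = config$min_area_px)
  if (!config$include_edge_regions) {
    tab$regions <- tab$regions[!tab$regions$touches_roi_boundary, , drop = FALSE]
  }
  faz <- identify_faz(labels)
  if (faz %in% tab$regions$id) tab <- mark_faz(tab, faz)
  spectrum <- summarize_eye(tab, eye_id = eye_id, grade = grade,
                            area_thresholds_mm2 = config$area_thresholds_mm2,
                            ap_threshold = config$ap_threshold)
  averaged_bin <- NULL
  tmap <- NULL
  if (length(frames) >= 2L) {
    avg <- average_frames(frames)
    averaged_bin <- prep(avg)
    averaged_bin$roi <- roi
    tmap <- transient_loss_map(bin, averaged_bin)
  }
  structure(list(spectrum = spectrum, table = tab, labels = labels,
                 binary = bin, roi = roi, averaged = averaged_bin,
                 transient_map = tmap, config = config),
            class = "eye_analysis")
}

#' Write a space table to CSV
#'
#' One row per detected region with all morphometric measures.
#'
#' @param table a `space_table`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_space_table <- function(table, path) {
  stopifnot(inherits(table, "space_table"))
  utils::write.csv(table$regions, path, row.names = FALSE)
  invisible(path)
}

#' Simulate and quantify a synthetic DR cohort
#'
#' Generates one synthetic eye per row of the design (grade, per-eye
#' dropout and transient rates), runs the measurement pipeline on the first
#' rendered frame of each, and returns the cohort table of eye spectra.
#' Default grade effect sizes follow the study design the generator
#' emulates: capillary dropout and transient signal loss both increase with
#' DR severity, with 50% eye-to-eye jitter around the grade means.
#'
#' @param n_per_grade integer vector of eyes per grade, in [dr_grades()]
#'   order.
#' @param dropout_by_grade,transient_by_grade mean rates per grade.
#' @param jitter relative half-width of the per-eye uniform jitter on both
#'   rates.
#' @param scene base [scene_config()] shared by all eyes.
#' @param config a [run_config()].
#' @param seed master seed; per-eye seeds derive from it.
#' @param n_frames frames rendered per eye (1 is enough for measurement).
#' @return data.frame of eye spectrum rows with a `grade` column.
#' @export
simulate_cohort <- function(n_per_grade = c(22L, 14L, 10L, 17L, 16L, 18L),
                            dropout_by_grade = c(0, 0.03, 0.08, 0.18, 0.28, 0.38),
                            transient_by_grade = c(0.02, 0.06, 0.08, 0.10, 0.12, 0.15),
                            jitter = 0.5,
                            scene = scene_config(),
                            config = run_config(),
                            seed = 1L, n_frames = 1L) {
  stopifnot(length(n_per_grade) == 6L, length(dropout_by_grade) == 6L,
            length(transient_by_grade) == 6L)
  grades <- rep(dr_grades(), n_per_grade)
  n_eyes <- length(grades)
  jit <- with_seed(seed, stats::runif(2L * n_eyes, 1 - jitter, 1 + jitter))
  rows <- vector("list", n_eyes)
  for (i in seq_len(n_eyes)) {
    gi <- match(grades[i], dr_grades())
    cfg <- scene
    cfg$dropout_rate <- min(1, dropout_by_grade[gi] * jit[2 * i - 1])
    cfg$transient_rate <- min(1, transient_by_grade[gi] * jit[2 * i])
    cfg$n_frames <- as.integer(n_frames)
    cfg$rng_seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    eye <- simulate_eye(cfg)
    rows[[i]] <- analyze_eye(eye$stack, config,
                             eye_id = sprintf("eye%03d", i),
                             grade = grades[i])$spectrum
  }
  do.call(rbind, rows)
}

#' Ground-truth recovery report for a synthetic eye
#'
#' Compares a measured eye against its generator ground truth: the number of
#' faces intersecting the ROI vs the number of detected regions, and the
#' detected pixel-count area of each interior region (matched to the face
#' containing its centroid, restricted to faces fully inside the ROI)
#' against the face's open area (the face polygon minus vessel strokes,
#' evaluated at the render-grid pixel centers).
#'
#' @param eye a [simulate_eye()] result.
#' @param analysis an [analyze_eye()] result for the same eye.
#' @return list with `truth_count`, `detected_count`, and `matched`
#'   (data.frame, one row per truth face fully inside the ROI that received
#'   at least one detected region: face id, number of matched regions,
#'   detected and true areas in mm^2).
#' @export
recovery_report <- function(eye, analysis) {
  pitch <- analysis$table$pitch_mm
  tm <- true_face_metrics(eye$truth, roi = analysis$roi, pitch_mm = pitch)
  reg <- analysis$table$regions
  lab <- analysis$labels$labels
  # representative pixel per region (first occurrence, column-major): it lies
  # strictly inside exactly one face polygon
  occ <- which(lab > 0L)
  first <- occ[!duplicated(lab[occ])]
  rep_lab <- lab[first]
  nr <- nrow(lab)
  rx <- (((first - 1L) %/% nr) + 1L - 0.5) * pitch
  ry <- (((first - 1L) %% nr) + 1L - 0.5) * pitch
  rx <- rx[order(rep_lab)][reg$id]   # align to (possibly filtered) table rows
  ry <- ry[order(rep_lab)][reg$id]
  fid <- rep(NA_integer_, nrow(reg))
  for (i in seq_along(eye$truth$polygons)) {
    p <- eye$truth$polygons[[i]]
    inb <- which(rx >= min(p[, 1]) & rx <= max(p[, 1]) &
                   ry >= min(p[, 2]) & ry <= max(p[, 2]))
    if (length(inb)) {
      hit <- inb[points_in_polygon(rx[inb], ry[inb], p[, 1], p[, 2])]
      fid[hit] <- i
    }
  }
  # per-face detected area: all detected space pixels falling in the face
  # (a face pinched into several components contributes their sum); only
  # faces fully inside the ROI are compared
  usable <- !is.na(fid) & !reg$touches_roi_boundary
  agg <- stats::aggregate(cbind(area = reg$area_mm2[usable],
                                n = rep(1L, sum(usable))),
                          by = list(face_id = fid[usable]), FUN = sum)
  idx <- match(agg$face_id, tm$face_id)
  fully_in <- tm$open_px_in_roi[idx] == tm$open_px[idx]
  matched <- data.frame(
    face_id = agg$face_id[fully_in],
    n_regions = agg$n[fully_in],
    detected_area_mm2 = agg$area[fully_in],
    true_open_area_mm2 = tm$open_area_mm2[idx][fully_in])
  list(truth_count = sum(tm$intersects_roi),
       detected_count = nrow(reg),
       matched = matched)
}

#' Dropout sweep: quantify eyes over a grid of capillary-obstruction rates
#'
#' Simulates `eyes_per_level` eyes at each dropout rate (all other scene
#' parameters at their defaults) and measures each with the standard
#' pipeline. This is the controlled experiment behind the directional
#' findings: as permanent capillary loss increases, total space counts fall
#' while mean areas and high-ratio counts rise.
#'
#' @param dropout_levels numeric vector of dropout rates.
#' @param eyes_per_level eyes simulated per rate.
#' @param scene base [scene_config()].
#' @param config a [run_config()].
#' @param seed master seed; per-eye seeds derive from it.
#' @return data.frame of eye spectrum rows with a `dropout_rate` column.
#' @export
dropout_sweep <- function(dropout_levels = c(0, 0.1, 0.2, 0.3, 0.4),
                          eyes_per_level = 20L,
                          scene = scene_config(),
                          config = run_config(),
                          seed = 1L) {
  rows <- list()
  k <- 0L
  for (dr in dropout_levels) {
    for (e in seq_len(eyes_per_level)) {
      k <- k + 1L
      cfg <- scene
      cfg$dropout_rate <- dr
      cfg$n_frames <- 1L
      cfg$rng_seed <- as.integer((seed * 7919L + k * 131L) %% .Machine$integer.max)
      eye <- simulate_eye(cfg)
      sp <- analyze_eye(eye$stack, config, eye_id = sprintf("sweep%03d", k))$spectrum
      sp$dropout_rate <- dr
      rows[[k]] <- sp
    }
  }
  do.call(rbind, rows)
}

#' Serialize a severity report to JSON
#'
#' @param report a [severity_report()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_severity_report <- function(report, path) {
  stopifnot(inherits(report, "severity_report"))
  out <- list(
    medians = report$medians,
    tests = lapply(report$tests, function(t) list(
      omnibus = t$omnibus, pairwise = t$pairwise, summary = t$summary)),
    roc = lapply(report$roc, function(by_scheme)
      lapply(by_scheme, function(r) list(
        auc = r$auc, se = r$se, ci = r$ci,
        orientation = r$orientation,
        n_case = r$n_case, n_control = r$n_control))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
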