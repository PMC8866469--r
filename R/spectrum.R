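# Per-eye spectrum summaries: total space count, mean morphometrics, and
# thresholded counts, always after exclusion of the FAZ.

#' Count intercapillary spaces above an area threshold
#'
#' Strict inequality ("larger than"), FAZ excluded.
#'
#' @param table a `space_table`.
#' @param threshold_mm2 positive area threshold (mm^2).
#' @return integer count.
#' @export
count_above_area <- function(table, threshold_mm2) {
  stopifnot(inherits(table, "space_table"))
  if (!is.numeric(threshold_mm2) || length(threshold_mm2) != 1L ||
      is.na(threshold_mm2) || threshold_mm2 <= 0)
    stop("threshold must be positive")
  r <- table$regions
  sum(!r$is_faz & r$area_mm2 > threshold_mm2)
}

#' Count intercapillary spaces above an area/perimeter-ratio threshold
#'
#' Strict inequality, FAZ excluded. The ratio carries units of mm but is
#' conventionally reported as A.U.; the clinical cut-point is 0.025.
#'
#' @param table a `space_table`.
#' @param threshold positive ratio threshold.
#' @return integer count.
#' @export
count_ap_above <- function(table, threshold = 0.025) {
  stopifnot(inherits(table, "space_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0)
    stop("threshold must be positive")
  r <- table$regions
  sum(!r$is_faz & r$ap_ratio > threshold)
}

#' Reduce a space table to the per-eye spectrum summary
#'
#' Excludes the FAZ row from every statistic, then reports the total count,
#' arithmetic means of area, perimeter and minimum/maximum Feret diameters,
#' the counts above each area threshold and above the area/perimeter-ratio
#' threshold (all strict inequalities), and the FAZ area. An empty table (or
#' one containing only the FAZ) yields count 0 with missing means.
#'
#' @param table a `space_table` with the FAZ marked (or absent).
#' @param eye_id identifier carried into the output row.
#' @param grade DR severity grade (see [dr_grades()]), or NA.
#' @param area_thresholds_mm2 area cut-points (mm^2).
#' @param ap_threshold area/perimeter ratio cut-point.
#' @return one-row data.frame (an "eye spectrum" row).
#' @export
summarize_eye <- function(table, eye_id = "eye", grade = NA_character_,
                          area_thresholds_mm2 = c(0.01, 0.02, 0.03, 0.04, 0.05),
                          ap_threshold = 0.025) {
  stopifnot(inherits(table, "space_table"))
  r <- table$regions
  faz_area <- if (any(r$is_faz)) r$area_mm2[r$is_faz][1] else NA_real_
  r <- r[!r$is_faz, , drop = FALSE]
  n <- nrow(r)
  mn <- function(x) if (n > 0L) mean(x) else NA_real_
  out <- data.frame(
    eye_id = eye_id,
    grade = as.character(grade),
    total_count = n,
    mean_area_mm2 = mn(r$area_mm2),
    mean_perimeter_mm = mn(r$perimeter_mm),
    mean_min_diam_mm = mn(r$min_diam_mm),
    mean_max_diam_mm = mn(r$max_diam_mm),
    faz_area_mm2 = faz_area,
    stringsAsFactors = FALSE)
  for (th in area_thresholds_mm2)
    out[[sprintf("count_area_gt_%g", th)]] <- sum(r$area_mm2 > th)
  out[[sprintf("count_ap_gt_%g", ap_threshold)]] <- sum(r$ap_ratio > ap_threshold)
  out
}
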