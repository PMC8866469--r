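#!/usr/bin/env Rscript

# Step 1 of the workflow: simulate one exemplar eye per DR severity grade and
# write its repeat frames (multi-page TIFF), ground-truth face polygons
# (JSON) and face metrics (CSV) under results/synthetic_eyes/. These files
# are the raster inputs for step 2, standing in for exported en face OCTA
# slabs of the superficial plexus.
#
# Grade effect sizes follow the cohort design: permanent capillary dropout
# and per-frame transient flow-signal loss both increase with severity.

suppressPackageStartupMessages(library(icspectra))

out_dir <- file.path("results", "synthetic_eyes")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

grades <- dr_grades()
dropout <- c(0, 0.03, 0.08, 0.18, 0.28, 0.38)
transient <- c(0.02, 0.06, 0.08, 0.10, 0.12, 0.15)

manifest <- data.frame(eye_id = character(0), grade = character(0),
                       dropout = numeric(0), transient = numeric(0),
                       frames = character(0), truth_csv = character(0))

for (i in seq_along(grades)) {
  cfg <- scene_config(dropout_rate = dropout[i], transient_rate = transient[i],
                      n_frames = 3L, rng_seed = 500L + i)
  eye <- simulate_eye(cfg)
  id <- sprintf("%02d_%s", i, grades[i])
  tif <- file.path(out_dir, paste0(id, ".tif"))
  write_frames_tiff(eye$stack, tif)
  img <- enface_image(eye$stack$frames[[1]], eye$stack$pitch_mm)
  roi <- make_circular_roi(img, 2)
  met <- write_ground_truth(eye$truth,
                            json_path = file.path(out_dir, paste0(id, "_truth.json")),
                            csv_path = file.path(out_dir, paste0(id, "_truth.csv")),
                            roi = roi)
  manifest <- rbind(manifest, data.frame(
    eye_id = id, grade = grades[i], dropout = dropout[i],
    transient = transient[i], frames = tif,
    truth_csv = file.path(out_dir, paste0(id, "_truth.csv"))))
  message(sprintf("%s: %d ground-truth faces, %d frames", id,
                  nrow(eye$truth$faces), cfg$n_frames))
}

write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
jsonlite::write_json(unclass(scene_config()), file.path(out_dir, "scene_defaults.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", file.path(out_dir, "manifest.csv"))
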