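# Synthetic OCTA generator: mesh construction, ground-truth faces, dropout,
# transient loss, rendering.

test_that("generation is deterministic given the seed", {
  cfg <- scene_config(grid_px = 128L, rng_seed = 3L)
  g1 <- generate_capillary_graph(cfg)
  g2 <- generate_capillary_graph(cfg)
  expect_identical(g1$graph$nodes, g2$graph$nodes)
  expect_identical(g1$graph$edges, g2$graph$edges)
  expect_identical(g1$truth$faces, g2$truth$faces)
})

test_that("the FAZ face contains the center and covers the avascular disk", {
  sc <- small_scene()
  gt <- sc$truth
  expect_false(is.na(gt$faz_face_id))
  faz <- gt$faces[gt$faz_face_id, ]
  expect_true(faz$contains_center)
  expect_gte(faz$area_mm2, pi * 0.30^2)
  expect_identical(sum(gt$faces$contains_center), 1L)
})

test_that("degenerate density raises the no-interior-faces error", {
  expect_error(generate_capillary_graph(scene_config(seed_point_density = 0)),
               "no interior faces")
})

test_that("scene configuration invariants are enforced", {
  expect_error(scene_config(dropout_rate = 1.2), "probability")
  expect_error(scene_config(faz_radius_mm = 2), "faz_radius_mm")
  expect_error(scene_config(grid_px = 32), "grid_px")
  expect_error(scene_config(n_frames = 0), "n_frames")
})

test_that("dropout at rate 0 is the identity and rate 1 kills all unprotected edges", {
  g <- small_scene()$graph
  expect_identical(apply_dropout(g, 0), g)
  g1 <- apply_dropout(g, 1, rng_seed = 5L)
  expect_true(all(g1$edges$alive == g1$edges$protected))
  # survivors are the FAZ ring (one cycle) plus acyclic trunk paths
  expect_identical(count_faces(g1), 1L)
  expect_error(apply_dropout(g, -0.1), "probability")
  expect_error(apply_dropout(g, 1.5), "probability")
})

test_that("face counts from the embedding match the cyclomatic number and drop by one per separating edge", {
  sc <- small_scene()
  g <- sc$graph
  n_trav <- nrow(sc$truth$faces)
  expect_identical(n_trav, as.integer(count_faces(g)))
  # find an edge shared by two bounded faces, remove it, recount by traversal
  ed <- g$edges
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  walk_keys <- function(w) paste(pmin(w, c(w[-1], w[1])), pmax(w, c(w[-1], w[1])))
  E <- icspectra:::prune_dangling_edges(cbind(ed$from, ed$to), nrow(g$nodes))
  faces <- icspectra:::planar_faces(g$nodes, E)
  tab <- table(unlist(lapply(faces, walk_keys)))
  shared <- names(tab)[tab == 2L]
  shared <- setdiff(shared, key[ed$protected])
  expect_gt(length(shared), 0)
  victim <- match(shared[1], key)
  g2 <- g
  g2$edges$alive[victim] <- FALSE
  gt2 <- ground_truth(g2)
  expect_identical(nrow(gt2$faces), n_trav - 1L)
  expect_identical(as.integer(count_faces(g2)), n_trav - 1L)
})

test_that("face count is monotone non-increasing under nested dropout", {
  g <- small_scene()$graph
  counts <- vapply(c(0, 0.1, 0.3, 0.6, 1), function(r)
    count_faces(apply_dropout(g, r, rng_seed = 9L)), numeric(1))
  # same seed: larger rate kills a superset of edges, so counts nest
  expect_true(all(diff(counts) <= 0))
})

test_that("rendering without noise or transient loss is reproducible across frames", {
  cfg <- scene_config(grid_px = 128L, rng_seed = 21L, noise_sd = 0,
                      transient_rate = 0, n_frames = 3L)
  g <- generate_capillary_graph(cfg)$graph
  st <- render_frames(g, cfg)
  expect_identical(st$frames[[1]], st$frames[[2]])
  expect_identical(st$frames[[1]], st$frames[[3]])
  expect_true(all(st$frames[[1]] %in% c(0, 1)))
  expect_identical(unname(dim(st$frames[[1]])), c(128L, 128L))
})

test_that("per-frame blanked-edge counts follow the transient-rate binomial", {
  cfg <- scene_config(grid_px = 128L, rng_seed = 33L, noise_sd = 0,
                      transient_rate = 0.2, n_frames = 8L)
  g <- generate_capillary_graph(cfg)$graph
  st <- render_frames(g, cfg)
  n_edges <- sum(g$edges$alive)
  lo <- qbinom(0.005, n_edges, 0.2)
  hi <- qbinom(0.995, n_edges, 0.2)
  for (bl in st$blanked) {
    expect_gte(length(bl), lo)
    expect_lte(length(bl), hi)
  }
})

test_that("averaging recovers 2/3 intensity at a pixel blanked in one of three frames", {
  sc <- small_scene()
  full <- sc$stack$frames[[1]]
  # blank one non-protected edge by rendering the graph with it removed
  g2 <- sc$graph
  victim <- which(!g2$edges$protected)[10]
  g2$edges$alive[victim] <- FALSE
  part <- render_frames(g2, sc$cfg)$frames[[1]]
  avg <- average_frames(list(full, full, part), pitch_mm = sc$stack$pitch_mm)
  px <- which(full == 1 & part == 0)
  expect_gt(length(px), 0)
  expect_equal(unique(avg$data[px]), 2 / 3, tolerance = 1e-12)
})

test_that("ground-truth metrics are exact on a hand-built square face", {
  # a 0.1 mm square face: area 0.01 mm^2, perimeter 0.4 mm, ratio 0.025 --
  # exactly the clinical area/perimeter cut-point
  nodes <- rbind(c(1.0, 1.0), c(1.1, 1.0), c(1.1, 1.1), c(1.0, 1.1))
  graph <- structure(list(
    nodes = nodes,
    edges = data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1),
                       width_um = 6, protected = FALSE, alive = TRUE),
    n_ring = 0L, fov_mm = 3, faz_radius_mm = 0, ring_radius_mm = 0,
    config = scene_config(faz_radius_mm = 0)), class = "capillary_graph")
  gt <- ground_truth(graph)
  met <- true_face_metrics(gt)
  expect_identical(nrow(met), 1L)
  expect_equal(met$area_mm2, 0.01, tolerance = 1e-12)
  expect_equal(met$perimeter_mm, 0.4, tolerance = 1e-12)
  expect_equal(met$ap_ratio_mm, 0.025, tolerance = 1e-12)
})

test_that("a fine polygonal disk face has area/perimeter ratio near r/2", {
  r <- 0.2
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  nodes <- cbind(1.5 + r * cos(th), 1.5 + r * sin(th))
  graph <- structure(list(
    nodes = nodes,
    edges = data.frame(from = seq_len(200), to = c(2:200, 1), width_um = 6,
                       protected = FALSE, alive = TRUE),
    n_ring = 0L, fov_mm = 3, faz_radius_mm = 0, ring_radius_mm = 0,
    config = scene_config(faz_radius_mm = 0)), class = "capillary_graph")
  met <- true_face_metrics(ground_truth(graph))
  expect_equal(met$ap_ratio_mm, r / 2, tolerance = 1e-3)
})

test_that("face areas plus vessel strokes tile the ROI within 1%", {
  eye <- reference_eye()
  pitch <- eye$stack$pitch_mm
  img <- enface_image(eye$stack$frames[[1]], pitch)
  roi <- make_circular_roi(img, 2)
  tm <- true_face_metrics(eye$truth, roi = roi, pitch_mm = pitch)
  m <- roi_mask(roi)
  stroke_px <- sum(eye$stack$stroke_mask & m)
  total <- sum(tm$open_px_in_roi) + stroke_px
  expect_lt(abs(total - sum(m)) / sum(m), 0.01)
})
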