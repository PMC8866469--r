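# Synthetic en face OCTA generator: a planar capillary mesh of the
# superficial vascular plexus with a foveal avascular zone (FAZ), optional
# trunk (arcade) vessels, permanent capillary dropout and per-frame transient
# flow-signal loss, rendered as bright strokes on a dark background. Ground
# truth is the set of planar faces (polygons enclosed by surviving vessels).

#' Scene configuration for the synthetic OCTA generator
#'
#' Bundles the physical and stochastic parameters of one synthetic eye.
#' Defaults emulate a 3 x 3 mm macular scan digitized to 1024 x 1024 pixels
#' with a 0.3 mm foveal avascular zone and a capillary mesh dense enough to
#' carry roughly 500-550 intercapillary spaces inside the central 2 mm
#' circle of a healthy eye.
#'
#' @param fov_mm field of view width (mm).
#' @param grid_px raster size in pixels (square image).
#' @param faz_radius_mm radius of the central avascular disk (mm).
#' @param seed_point_density capillary mesh nodes per mm^2.
#' @param vessel_width_um stroke width of rasterized capillaries (micrometers).
#' @param dropout_rate probability in [0, 1] that a non-protected capillary
#'   edge is permanently removed (capillary obstruction / nonperfusion).
#' @param transient_rate per-frame probability in [0, 1] that a surviving
#'   edge is blanked (transient flow-signal loss).
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   [0, 1] intensity scale.
#' @param n_frames number of repeat frames rendered per eye.
#' @param rng_seed integer seed; all generator randomness derives from it.
#' @param mesh_prune fraction of mesh edges removed during construction so
#'   that intercapillary spaces become lobular polygons rather than
#'   triangles.
#' @param trunk_vessels logical; add two wider, protected arcade vessels.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(fov_mm = 3.0, grid_px = 1024L, faz_radius_mm = 0.30,
                         seed_point_density = 125, vessel_width_um = 12,
                         dropout_rate = 0, transient_rate = 0.02,
                         noise_sd = 0.05, n_frames = 3L, rng_seed = 1L,
                         mesh_prune = 0.15, trunk_vessels = TRUE) {
  cfg <- list(fov_mm = fov_mm, grid_px = as.integer(grid_px),
              faz_radius_mm = faz_radius_mm,
              seed_point_density = seed_point_density,
              vessel_width_um = vessel_width_um,
              dropout_rate = dropout_rate, transient_rate = transient_rate,
              noise_sd = noise_sd, n_frames = as.integer(n_frames),
              rng_seed = as.integer(rng_seed), mesh_prune = mesh_prune,
              trunk_vessels = isTRUE(trunk_vessels))
  validate_scene_config(cfg)
  class(cfg) <- "scene_config"
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(is.numeric(cfg$fov_mm), length(cfg$fov_mm) == 1L)
  if (!(cfg$fov_mm > 0)) stop("fov_mm must be positive")
  if (cfg$grid_px < 64L) stop("grid_px must be at least 64")
  if (!(cfg$faz_radius_mm >= 0 && cfg$faz_radius_mm < cfg$fov_mm / 2))
    stop("faz_radius_mm must lie in [0, fov_mm/2)")
  for (nm in c("dropout_rate", "transient_rate", "mesh_prune")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("%s must be a probability in [0, 1]", nm))
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$n_frames < 1L) stop("n_frames must be at least 1")
  if (cfg$seed_point_density < 0) stop("seed_point_density must be non-negative")
  if (cfg$vessel_width_um <= 0) stop("vessel_width_um must be positive")
  invisible(cfg)
}

#' Generate a synthetic capillary graph and its ground truth
#'
#' Samples blue-noise (Poisson-disc) mesh nodes, triangulates them
#' (Bowyer-Watson Delaunay), prunes a fraction of edges to form lobular
#' faces, carves out the FAZ as a protected vessel ring, and optionally
#' threads two wider protected trunk vessels through the mesh. Fully
#' deterministic given `config$rng_seed`.
#'
#' @param config a [scene_config()].
#' @return a list with elements `graph` (class `capillary_graph`) and
#'   `truth` (class `ground_truth`, see [ground_truth()]).
#' @export
generate_capillary_graph <- function(config) {
  validate_scene_config(config)
  with_seed(config$rng_seed, {
    fov <- config$fov_mm
    dens <- config$seed_point_density
    rmin <- if (dens > 0) sqrt(0.7 / dens) else Inf
    cx <- fov / 2
    cy <- fov / 2
    pts <- if (is.finite(rmin)) poisson_disc_sample(fov, fov, rmin) else
      matrix(numeric(0), 0, 2)
    ring <- NULL
    if (config$faz_radius_mm > 0) {
      # circumscribed polygon so the FAZ face contains the full disk
      nring <- max(12L, ceiling(2 * pi * config$faz_radius_mm /
                                  (0.8 * min(rmin, 0.1))))
      rring <- config$faz_radius_mm / cos(pi / nring)
      th <- seq(0, 2 * pi, length.out = nring + 1L)[-(nring + 1L)]
      ring <- cbind(cx + rring * cos(th), cy + rring * sin(th))
      if (nrow(pts)) {
        keep <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) >
          rring + 0.5 * min(rmin, 0.1)
        pts <- pts[keep, , drop = FALSE]
      }
    } else {
      rring <- 0
    }
    nodes <- rbind(ring, pts)
    n_ring <- if (is.null(ring)) 0L else nrow(ring)
    if (nrow(nodes) < 3L)
      stop("no interior faces: seed_point_density too low")
    tri <- delaunay_triangulate(nodes)
    edges <- triangles_to_edges(tri)
    # drop chords crossing the FAZ disk interior (consecutive ring edges have
    # their midpoints exactly on the faz_radius circle and are kept)
    if (n_ring > 0L) {
      mx <- (nodes[edges[, 1], 1] + nodes[edges[, 2], 1]) / 2
      my <- (nodes[edges[, 1], 2] + nodes[edges[, 2], 2]) / 2
      middist <- sqrt((mx - cx)^2 + (my - cy)^2)
      edges <- edges[middist >= config$faz_radius_mm * (1 - 1e-9), , drop = FALSE]
      ringpairs <- cbind(seq_len(n_ring), c(2:n_ring, 1L))
      ringpairs <- cbind(pmin(ringpairs[, 1], ringpairs[, 2]),
                         pmax(ringpairs[, 1], ringpairs[, 2]))
      have <- paste(edges[, 1], edges[, 2]) # ring edges usually already present
      miss <- !(paste(ringpairs[, 1], ringpairs[, 2]) %in% have)
      if (any(miss)) edges <- rbind(edges, ringpairs[miss, , drop = FALSE])
    }
    is_ring_edge <- edges[, 1] <= n_ring & edges[, 2] <= n_ring
    protected <- is_ring_edge
    width_um <- rep(config$vessel_width_um, nrow(edges))
    # trunk (arcade) vessels: two wider, protected shortest paths across the
    # field, one above and one below the macula
    if (config$trunk_vessels && nrow(nodes) >= 20L) {
      g <- igraph::graph_from_edgelist(edges, directed = FALSE)
      elen <- sqrt((nodes[edges[, 1], 1] - nodes[edges[, 2], 1])^2 +
                     (nodes[edges[, 1], 2] - nodes[edges[, 2], 2])^2)
      for (yfrac in c(0.24, 0.76)) {
        a <- which.min((nodes[, 1] - 0.03 * fov)^2 + (nodes[, 2] - yfrac * fov)^2)
        b <- which.min((nodes[, 1] - 0.97 * fov)^2 + (nodes[, 2] - yfrac * fov)^2)
        sp <- suppressWarnings(igraph::shortest_paths(g, from = a, to = b,
                                                      weights = elen,
                                                      output = "epath"))
        eids <- as.integer(sp$epath[[1]])
        if (length(eids)) {
          protected[eids] <- TRUE
          width_um[eids] <- config$vessel_width_um * 2.2
        }
      }
    }
    # prune a fraction of ordinary edges to create lobular polygonal faces
    if (config$mesh_prune > 0 && nrow(edges)) {
      kill <- stats::runif(nrow(edges)) < config$mesh_prune & !protected
      edges <- edges[!kill, , drop = FALSE]
      protected <- protected[!kill]
      width_um <- width_um[!kill]
    }
    # remove dangling stubs left by pruning so faces are clean at baseline
    keep <- rep(TRUE, nrow(edges))
    pruned <- prune_dangling_edges(edges, nrow(nodes))
    keep <- paste(edges[, 1], edges[, 2]) %in% paste(pruned[, 1], pruned[, 2])
    edges <- edges[keep, , drop = FALSE]
    protected <- protected[keep]
    width_um <- width_um[keep]
    graph <- structure(list(
      nodes = nodes,
      edges = data.frame(from = edges[, 1], to = edges[, 2],
                         width_um = width_um, protected = protected,
                         alive = TRUE),
      n_ring = n_ring,
      fov_mm = fov,
      faz_radius_mm = config$faz_radius_mm,
      ring_radius_mm = rring,
      config = config), class = "capillary_graph")
    truth <- ground_truth(graph)
    if (nrow(truth$faces) < 2L && config$faz_radius_mm > 0)
      stop("no interior faces: seed_point_density too low")
    if (nrow(truth$faces) < 1L)
      stop("no interior faces: seed_point_density too low")
    list(graph = graph, truth = truth)
  })
}

#' Compute ground-truth faces of a capillary graph
#'
#' Extracts the bounded faces of the planar embedding of all alive edges
#' (dangling stubs are ignored: they bound no face) and measures each face
#' polygon exactly: shoelace area, perimeter, and whether it contains the
#' image center (the true FAZ).
#'
#' @param graph a `capillary_graph`.
#' @return an object of class `ground_truth`: list with `faces` (data.frame:
#'   `face_id`, `area_mm2`, `perimeter_mm`, `contains_center`), `polygons`
#'   (list of coordinate matrices in mm), `edges_mm` (alive-edge segment
#'   table used for vessel-stroke accounting), `faz_face_id`, `fov_mm`.
#' @export
ground_truth <- function(graph) {
  stopifnot(inherits(graph, "capillary_graph"))
  ed <- graph$edges[graph$edges$alive, , drop = FALSE]
  E <- prune_dangling_edges(cbind(ed$from, ed$to), nrow(graph$nodes))
  faces <- planar_faces(graph$nodes, E)
  cx <- graph$fov_mm / 2
  cy <- graph$fov_mm / 2
  polys <- lapply(faces, function(w) graph$nodes[w, , drop = FALSE])
  area <- vapply(polys, function(p) polygon_area(p[, 1], p[, 2]), numeric(1))
  perim <- vapply(polys, function(p) polygon_perimeter(p[, 1], p[, 2]), numeric(1))
  ctr <- vapply(polys, function(p)
    points_in_polygon(cx, cy, p[, 1], p[, 2]), logical(1))
  ok <- area > 1e-12
  if (any(!ok)) {
    warning(sprintf("excluded %d degenerate zero-area face(s)", sum(!ok)))
    polys <- polys[ok]
    area <- area[ok]
    perim <- perim[ok]
    ctr <- ctr[ok]
  }
  edall <- graph$edges[graph$edges$alive, , drop = FALSE]
  edges_mm <- data.frame(
    x0 = graph$nodes[edall$from, 1], y0 = graph$nodes[edall$from, 2],
    x1 = graph$nodes[edall$to, 1], y1 = graph$nodes[edall$to, 2],
    halfwidth_mm = edall$width_um / 2000)
  structure(list(
    faces = data.frame(face_id = seq_along(area), area_mm2 = area,
                       perimeter_mm = perim, contains_center = ctr),
    polygons = polys,
    edges_mm = edges_mm,
    faz_face_id = if (any(ctr)) which(ctr)[1] else NA_integer_,
    fov_mm = graph$fov_mm), class = "ground_truth")
}

#' Permanently remove capillary edges (capillary obstruction)
#'
#' Each alive, non-protected edge is independently marked dead with the
#' given probability. Protected edges (the FAZ ring and trunk vessels) are
#' never removed. Returns a new graph; ground truth can be recomputed with
#' [ground_truth()].
#'
#' @param graph a `capillary_graph`.
#' @param rate dropout probability in [0, 1].
#' @param rng_seed integer seed.
#' @return the modified `capillary_graph`.
#' @export
apply_dropout <- function(graph, rate, rng_seed = graph$config$rng_seed + 1L) {
  stopifnot(inherits(graph, "capillary_graph"))
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0 || rate > 1)
    stop("dropout rate must be a probability in [0, 1]")
  if (rate == 0) return(graph)
  with_seed(rng_seed, {
    cand <- graph$edges$alive & !graph$edges$protected
    kill <- cand & stats::runif(nrow(graph$edges)) < rate
    graph$edges$alive[kill] <- FALSE
  })
  graph
}

#' Number of bounded faces of the alive-edge graph
#'
#' Computed from the cyclomatic number E - V + C of the subgraph of alive
#' edges (V counts only nodes incident to an alive edge, C its connected
#' components), which equals the bounded-face count of any planar embedding.
#'
#' @param graph a `capillary_graph`.
#' @return integer face count.
#' @export
count_faces <- function(graph) {
  ed <- graph$edges[graph$edges$alive, c("from", "to")]
  if (!nrow(ed)) return(0L)
  g <- igraph::graph_from_edgelist(as.matrix(ed), directed = FALSE)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  as.integer(nrow(ed) - igraph::vcount(g) + igraph::components(g)$no)
}

#' Render repeat frames of a synthetic eye
#'
#' Rasterizes alive edges as bright strokes (intensity 1) on a dark
#' background, independently blanking each alive edge per frame with
#' probability `config$transient_rate`, then adds clipped Gaussian noise.
#' No anti-aliasing: a pixel is vessel when its center lies within half the
#' stroke width of an edge segment.
#'
#' @param graph a `capillary_graph` with at least one alive edge.
#' @param config a [scene_config()]; `grid_px`, `transient_rate`,
#'   `noise_sd`, `n_frames` and `rng_seed` are used.
#' @return a `frame_stack`: list with `frames` (list of [0,1] matrices),
#'   `pitch_mm`, `blanked` (per-frame integer vectors of blanked edge row
#'   indices), `stroke_mask` (noise-free logical vessel mask of all alive
#'   edges) and `config`.
#' @export
render_frames <- function(graph, config = graph$config) {
  stopifnot(inherits(graph, "capillary_graph"))
  validate_scene_config(config)
  alive_idx <- which(graph$edges$alive)
  if (!length(alive_idx)) stop("graph has no alive edges")
  n <- config$grid_px
  pitch <- config$fov_mm / n
  ed <- graph$edges[alive_idx, , drop = FALSE]
  # mm -> pixel-center coordinates: pixel j has center (j - 0.5) * pitch
  x0 <- graph$nodes[ed$from, 1] / pitch + 0.5
  y0 <- graph$nodes[ed$from, 2] / pitch + 0.5
  x1 <- graph$nodes[ed$to, 1] / pitch + 0.5
  y1 <- graph$nodes[ed$to, 2] / pitch + 0.5
  hw <- (ed$width_um / 2000) / pitch
  pix <- cpp_raster_segments(n, n, x0, y0, x1, y1, hw)
  allpix <- unique(unlist(pix, use.names = FALSE))
  stroke <- matrix(FALSE, n, n)
  stroke[allpix] <- TRUE
  frames <- vector("list", config$n_frames)
  blanked <- vector("list", config$n_frames)
  with_seed(config$rng_seed + 1000L, {
    for (f in seq_len(config$n_frames)) {
      bl <- which(stats::runif(length(alive_idx)) < config$transient_rate)
      img <- numeric(n * n)
      keep <- if (length(bl)) pix[-bl] else pix
      if (length(keep)) img[unique(unlist(keep, use.names = FALSE))] <- 1
      if (config$noise_sd > 0) {
        img <- img + stats::rnorm(n * n, 0, config$noise_sd)
        img[img < 0] <- 0
        img[img > 1] <- 1
      }
      frames[[f]] <- matrix(img, n, n)
      blanked[[f]] <- alive_idx[bl]
    }
  })
  structure(list(frames = frames, pitch_mm = pitch, blanked = blanked,
                 stroke_mask = stroke, config = config),
            class = "frame_stack")
}

#' Measure ground-truth faces against an analysis ROI
#'
#' Per face: exact shoelace polygon area (mm^2), polygon perimeter (mm),
#' their ratio, and whether the face intersects the circular ROI. With a
#' pixel pitch supplied, also the "open" area - the part of the face not
#' covered by rendered vessel strokes, evaluated at the pixel centers of the
#' render grid. The open area is what an ideal binarization of a noise-free
#' rendering recovers, and is the reference for pipeline recovery checks.
#'
#' @param gt a [ground_truth()].
#' @param roi optional [make_circular_roi()] result (or NULL).
#' @param pitch_mm optional pixel pitch; enables the `open_area_mm2` column.
#' @return data.frame with one row per face: `face_id`, `area_mm2`,
#'   `perimeter_mm`, `ap_ratio_mm`, `intersects_roi`, `is_faz`, and
#'   optionally `open_area_mm2`, `open_px`.
#' @export
true_face_metrics <- function(gt, roi = NULL, pitch_mm = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!nrow(gt$faces)) stop("ground truth has no faces")
  fx <- gt$faces
  out <- data.frame(face_id = fx$face_id,
                    area_mm2 = fx$area_mm2,
                    perimeter_mm = fx$perimeter_mm,
                    ap_ratio_mm = fx$area_mm2 / fx$perimeter_mm,
                    intersects_roi = TRUE,
                    is_faz = fx$face_id == (gt$faz_face_id %||% -1L))
  roi_cx <- roi_cy <- roi_r <- NULL
  if (!is.null(roi)) {
    roi_cx <- roi$center_px[1] * roi$pitch_mm - roi$pitch_mm / 2
    roi_cy <- roi$center_px[2] * roi$pitch_mm - roi$pitch_mm / 2
    roi_r <- roi$radius_px * roi$pitch_mm
    out$intersects_roi <- vapply(seq_along(gt$polygons), function(i) {
      p <- gt$polygons[[i]]
      if (points_in_polygon(roi_cx, roi_cy, p[, 1], p[, 2])) return(TRUE)
      dmin <- min(dist_point_segment(roi_cx, roi_cy,
                                     p[, 1], p[, 2],
                                     c(p[-1, 1], p[1, 1]), c(p[-1, 2], p[1, 2])))
      dmin <= roi_r
    }, logical(1))
  }
  if (!is.null(pitch_mm)) {
    seg <- gt$edges_mm
    open_px <- integer(nrow(fx))
    open_in_roi_px <- integer(nrow(fx))
    for (i in seq_len(nrow(fx))) {
      p <- gt$polygons[[i]]
      hwmax <- max(seg$halfwidth_mm)
      jlo <- max(1, floor((min(p[, 1]) - hwmax) / pitch_mm))
      jhi <- ceiling((max(p[, 1]) + hwmax) / pitch_mm)
      ilo <- max(1, floor((min(p[, 2]) - hwmax) / pitch_mm))
      ihi <- ceiling((max(p[, 2]) + hwmax) / pitch_mm)
      gxy <- expand.grid(x = (jlo:jhi - 0.5) * pitch_mm,
                         y = (ilo:ihi - 0.5) * pitch_mm)
      inside <- points_in_polygon(gxy$x, gxy$y, p[, 1], p[, 2])
      if (!any(inside)) { open_px[i] <- 0L; next }
      gx <- gxy$x[inside]
      gy <- gxy$y[inside]
      # exclude pixels covered by any vessel stroke near this face's bbox
      bb <- which(pmin(seg$x0, seg$x1) <= max(p[, 1]) + hwmax &
                    pmax(seg$x0, seg$x1) >= min(p[, 1]) - hwmax &
                    pmin(seg$y0, seg$y1) <= max(p[, 2]) + hwmax &
                    pmax(seg$y0, seg$y1) >= min(p[, 2]) - hwmax)
      free <- rep(TRUE, length(gx))
      for (s in bb) {
        if (!any(free)) break
        d <- dist_point_segment(gx[free], gy[free], seg$x0[s], seg$y0[s],
                                seg$x1[s], seg$y1[s])
        free[free] <- d > seg$halfwidth_mm[s]
      }
      open_px[i] <- sum(free)
      if (!is.null(roi_r)) {
        inroi <- (gx[free] - roi_cx)^2 + (gy[free] - roi_cy)^2 <= roi_r^2
        open_in_roi_px[i] <- sum(inroi)
      }
    }
    out$open_px <- open_px
    out$open_area_mm2 <- open_px * pitch_mm^2
    if (!is.null(roi_r)) {
      out$open_px_in_roi <- open_in_roi_px
      out$open_area_in_roi_mm2 <- open_in_roi_px * pitch_mm^2
      out$intersects_roi <- out$intersects_roi & (open_in_roi_px > 0L)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
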