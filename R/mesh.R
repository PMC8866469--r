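# Internal computational geometry for the synthetic capillary-plexus
# generator: blue-noise point sampling, Delaunay triangulation and planar
# face extraction. All coordinates are in mm within [0, fov] x [0, fov].

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Bridson's Poisson-disc sampling on [0, width] x [0, height] with minimum
# point separation rmin. Returns an n x 2 matrix of (x, y).
poisson_disc_sample <- function(width, height, rmin, k = 30L) {
  cell <- rmin / sqrt(2)
  gw <- max(1L, as.integer(ceiling(width / cell)))
  gh <- max(1L, as.integer(ceiling(height / cell)))
  grid <- matrix(0L, gh, gw)
  cap <- gw * gh + 16L
  px <- numeric(cap)
  py <- numeric(cap)
  act <- integer(cap)
  r2 <- rmin * rmin
  x0 <- stats::runif(1, 0, width)
  y0 <- stats::runif(1, 0, height)
  np <- 1L
  px[1L] <- x0
  py[1L] <- y0
  grid[floor(y0 / cell) + 1L, floor(x0 / cell) + 1L] <- 1L
  na <- 1L
  act[1L] <- 1L
  while (na > 0L) {
    ai <- if (na == 1L) 1L else sample.int(na, 1L)
    p <- act[ai]
    placed <- FALSE
    for (trial in seq_len(k)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- rmin * sqrt(stats::runif(1, 1, 4))
      x <- px[p] + rad * cos(ang)
      y <- py[p] + rad * sin(ang)
      if (x < 0 || x >= width || y < 0 || y >= height) next
      gi <- floor(y / cell) + 1L
      gj <- floor(x / cell) + 1L
      nb <- grid[max(1L, gi - 2L):min(gh, gi + 2L),
                 max(1L, gj - 2L):min(gw, gj + 2L)]
      nb <- nb[nb > 0L]
      ok <- TRUE
      if (length(nb)) {
        dx <- px[nb] - x
        dy <- py[nb] - y
        ok <- all(dx * dx + dy * dy >= r2)
      }
      if (ok) {
        np <- np + 1L
        px[np] <- x
        py[np] <- y
        grid[gi, gj] <- np
        na <- na + 1L
        act[na] <- np
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      act[ai] <- act[na]
      na <- na - 1L
    }
  }
  cbind(x = px[seq_len(np)], y = py[seq_len(np)])
}

circumcircles <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax * ax + ay * ay
  b2 <- bx * bx + by * by
  c2 <- cx * cx + cy * cy
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  list(x = ux, y = uy, r2 = (ux - ax)^2 + (uy - ay)^2)
}

# Incremental Bowyer-Watson Delaunay triangulation. Returns an m x 3 matrix
# of point indices into `pts`. Intended for generic (jittered) point sets.
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points to triangulate")
  cx0 <- mean(range(pts[, 1]))
  cy0 <- mean(range(pts[, 2]))
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-6) * 16 + 1
  P <- rbind(pts[, 1:2, drop = FALSE],
             c(cx0 - 2 * span, cy0 - span),
             c(cx0 + 2 * span, cy0 - span),
             c(cx0, cy0 + 2 * span))
  cap <- 6L * n + 32L
  tri <- matrix(0L, cap, 3)
  ccx <- numeric(cap)
  ccy <- numeric(cap)
  cr2 <- numeric(cap)
  alive <- logical(cap)
  tri[1L, ] <- c(n + 1L, n + 2L, n + 3L)
  cc <- circumcircles(P[n + 1L, 1], P[n + 1L, 2], P[n + 2L, 1], P[n + 2L, 2],
                      P[n + 3L, 1], P[n + 3L, 2])
  ccx[1L] <- cc$x; ccy[1L] <- cc$y; cr2[1L] <- cc$r2
  alive[1L] <- TRUE
  ntri <- 1L
  for (ip in seq_len(n)) {
    x <- P[ip, 1]
    y <- P[ip, 2]
    sl <- seq_len(ntri)
    bad <- sl[alive[sl] &
                ((ccx[sl] - x)^2 + (ccy[sl] - y)^2 <= cr2[sl] * (1 + 1e-12))]
    if (!length(bad)) stop("triangulation failed: point outside all circumcircles")
    # cavity boundary: edges of bad triangles seen exactly once
    e1 <- tri[bad, c(1L, 2L), drop = FALSE]
    e2 <- tri[bad, c(2L, 3L), drop = FALSE]
    e3 <- tri[bad, c(3L, 1L), drop = FALSE]
    E <- rbind(e1, e2, e3)
    key <- pmin(E[, 1], E[, 2]) * (n + 4) + pmax(E[, 1], E[, 2])
    cnt <- table(key)
    single <- names(cnt)[cnt == 1L]
    keep <- key %in% as.numeric(single)
    B <- E[keep, , drop = FALSE]
    alive[bad] <- FALSE
    nb <- nrow(B)
    if (ntri + nb > cap) {
      grow <- cap
      tri <- rbind(tri, matrix(0L, grow, 3))
      ccx <- c(ccx, numeric(grow)); ccy <- c(ccy, numeric(grow))
      cr2 <- c(cr2, numeric(grow)); alive <- c(alive, logical(grow))
      cap <- cap + grow
    }
    idx <- ntri + seq_len(nb)
    tri[idx, 1L] <- B[, 1]
    tri[idx, 2L] <- B[, 2]
    tri[idx, 3L] <- ip
    cc <- circumcircles(P[B[, 1], 1], P[B[, 1], 2], P[B[, 2], 1], P[B[, 2], 2],
                        rep(x, nb), rep(y, nb))
    ccx[idx] <- cc$x; ccy[idx] <- cc$y; cr2[idx] <- cc$r2
    alive[idx] <- TRUE
    ntri <- ntri + nb
  }
  sl <- seq_len(ntri)
  out <- tri[sl[alive[sl]], , drop = FALSE]
  out[rowSums(out > n) == 0L, , drop = FALSE]
}

# Unique undirected edges (u < v) of a triangle set.
triangles_to_edges <- function(tri) {
  E <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  u <- pmin(E[, 1], E[, 2])
  v <- pmax(E[, 1], E[, 2])
  unique(cbind(from = u, to = v))
}

# Iteratively drop edges with an endpoint of degree 1 (dangling capillary
# stubs bound no face).
prune_dangling_edges <- function(edges, n_nodes) {
  if (!nrow(edges)) return(edges)
  repeat {
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n_nodes)
    drop <- deg[edges[, 1]] <= 1L | deg[edges[, 2]] <= 1L
    if (!any(drop)) break
    edges <- edges[!drop, , drop = FALSE]
    if (!nrow(edges)) break
  }
  edges
}

# Bounded faces of a straight-line planar embedding. `nodes` is n x 2 (mm),
# `edges` an m x 2 matrix of node indices (assumed planar, no dangling
# edges). Returns a list of faces; each face is an integer vector of node
# ids forming a closed counterclockwise walk (first vertex not repeated).
planar_faces <- function(nodes, edges) {
  m <- nrow(edges)
  if (!m) return(list())
  de_from <- c(edges[, 1], edges[, 2])
  de_to <- c(edges[, 2], edges[, 1])
  twin <- c((m + 1L):(2L * m), seq_len(m))
  ang <- atan2(nodes[de_to, 2] - nodes[de_from, 2],
               nodes[de_to, 1] - nodes[de_from, 1])
  ord <- order(de_from, ang)           # directed edges grouped by origin, CCW
  grp <- de_from[ord]
  first <- which(!duplicated(grp))     # group start positions in ord
  gsize <- diff(c(first, length(ord) + 1L))
  gstart <- integer(max(grp))
  glen <- integer(max(grp))
  gstart[grp[first]] <- first
  glen[grp[first]] <- gsize
  pos <- integer(2L * m)               # angular rank of each directed edge
  pos[ord] <- sequence(gsize)
  # successor of directed edge d = (u -> v): at v, take the twin (v -> u) and
  # step to the previous outgoing edge in CCW order (cyclic), which walks the
  # face lying to the left of d.
  tw <- twin
  tpos <- pos[tw]
  torig <- de_from[tw]
  plen <- glen[torig]
  prev <- tpos - 1L
  prev[prev == 0L] <- plen[prev == 0L]
  nxt <- ord[gstart[torig] + prev - 1L]
  visited <- logical(2L * m)
  faces <- list()
  nf <- 0L
  for (d0 in seq_len(2L * m)) {
    if (visited[d0]) next
    walk <- integer(0)
    d <- d0
    repeat {
      visited[d] <- TRUE
      walk <- c(walk, de_from[d])
      d <- nxt[d]
      if (d == d0) break
    }
    x <- nodes[walk, 1]
    y <- nodes[walk, 2]
    a <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
    if (a > 1e-12) {
      nf <- nf + 1L
      faces[[nf]] <- walk
    }
  }
  faces
}

polygon_area <- function(x, y) {
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

polygon_perimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# Even-odd point-in-polygon test (polygon given as coordinate vectors,
# closed implicitly). Vectorized over test points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Distance from points to segments (vectorized with the usual recycling,
# so it works point-wise or segment-wise).
dist_point_segment <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  l2 <- dx * dx + dy * dy
  t <- ((px - x0) * dx + (py - y0) * dy) / pmax(l2, 1e-300) * (l2 > 0)
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
}
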