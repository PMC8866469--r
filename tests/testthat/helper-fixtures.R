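# Shared fixtures, built once per test run and memoized. All synthetic; no
# files on disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small clean scene (256 px grid) used across modules.
small_scene <- function() fixture("small_scene", function() {
  cfg <- scene_config(grid_px = 256L, rng_seed = 11L, noise_sd = 0,
                      transient_rate = 0, dropout_rate = 0, n_frames = 1L)
  gen <- generate_capillary_graph(cfg)
  stack <- render_frames(gen$graph, cfg)
  list(cfg = cfg, graph = gen$graph, truth = gen$truth, stack = stack)
})

# The full-resolution, noise-free reference eye for recovery checks.
reference_eye <- function() fixture("reference_eye", function() {
  cfg <- scene_config(rng_seed = 7L, noise_sd = 0, transient_rate = 0,
                      dropout_rate = 0, n_frames = 1L)
  simulate_eye(cfg)
})

# The reference eye measured with the validation configuration (no blur on a
# noise-free scene), memoized for the recovery and invariant tests.
reference_analysis <- function() fixture("reference_analysis", function() {
  analyze_eye(reference_eye()$stack, run_config(blur_radius_px = 0),
              eye_id = "reference")
})

# Brute-force oracles -------------------------------------------------------

phansalkar_brute <- function(img, wr, k, r, p, q) {
  n <- nrow(img)
  m <- ncol(img)
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      ii <- max(1, i - wr):min(n, i + wr)
      jj <- max(1, j - wr):min(m, j + wr)
      sel <- outer((ii - i)^2, (jj - j)^2, `+`) <= wr^2
      v <- img[ii, jj][sel]
      mu <- mean(v)
      s <- sqrt(mean((v - mu)^2))
      t <- mu * (1 + p * exp(-q * mu) + k * (s / r - 1))
      out[i, j] <- img[i, j] > t
    }
  }
  out
}

blur_brute <- function(img, sigma) {
  K <- ceiling(3 * sigma)
  kern <- stats::dnorm(-K:K, sd = sigma)
  kern <- kern / sum(kern)
  k2 <- outer(kern, kern)
  n <- nrow(img)
  m <- ncol(img)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      ii <- max(1, i - K):min(n, i + K)
      jj <- max(1, j - K):min(m, j + K)
      kw <- k2[ii - i + K + 1, jj - j + K + 1, drop = FALSE]
      out[i, j] <- sum(kw * img[ii, jj]) / sum(kw)
    }
  }
  out
}

auc_allpairs <- function(scores, labels) {
  s1 <- scores[labels]
  s0 <- scores[!labels]
  pairs <- outer(s1, s0, `-`)
  (sum(pairs > 0) + 0.5 * sum(pairs == 0)) / (length(s1) * length(s0))
}

feret_sweep <- function(points, ndir = 3600) {
  extent <- function(a) {
    proj <- points[, 1] * cos(a) + points[, 2] * sin(a)
    max(proj) - min(proj)
  }
  th <- (seq_len(ndir) - 1) / ndir * pi
  ext <- vapply(th, extent, numeric(1))
  # refine around the coarse grid optima (the width minimum sits on a kink,
  # so the raw grid is only good to ~1e-4 relative)
  step <- pi / ndir
  refine <- function(i, what) {
    stats::optimize(extent, interval = c(th[i] - step, th[i] + step),
                    maximum = (what == "max"), tol = 1e-12)
  }
  mn <- refine(which.min(ext), "min")$objective
  mx <- refine(which.max(ext), "max")$maximum
  mx <- extent(mx)
  c(min = mn, max = max(mx, max(ext)))
}

fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  lf <- lfactorial
  logp <- function(x) lf(m) + lf(n) + lf(k) + lf(m + n - k) - lf(m + n) -
    (lf(x) + lf(m - x) + lf(k - x) + lf(n - k + x))
  support <- max(0, k - n):min(k, m)
  pr <- exp(vapply(support, logp, numeric(1)))
  min(1, sum(pr[pr <= exp(logp(a)) * (1 + 1e-7)]))
}

# Wrap a plain logical matrix as a binary vessel map for morphometry tests.
as_vessel_map <- function(vessel, pitch_mm = 1, roi = NULL) {
  structure(list(vessel = vessel, roi = roi, pitch_mm = pitch_mm,
                 params = threshold_params()),
            class = "binary_vessel_map")
}

# ROI covering (almost) a whole small square image.
full_roi <- function(n, pitch_mm = 1) {
  img <- enface_image(matrix(0, n, n), pitch_mm)
  make_circular_roi(img, diameter_mm = n * pitch_mm)
}
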