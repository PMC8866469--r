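#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pixel-center convention used throughout: pixel (i, j) of an R matrix
// (i = row, j = column, both 1-based on the R side) has its center at
// (x, y) = (j, i) in pixel units; rows grow downwards.

// Rasterize line segments as strokes: a pixel belongs to a segment's stroke
// when its center lies within halfwidth (px) of the segment. Returns, for
// each segment, the 1-based column-major linear indices of its pixels.
// [[Rcpp::export]]
List cpp_raster_segments(int nr, int nc,
                         NumericVector x0, NumericVector y0,
                         NumericVector x1, NumericVector y1,
                         NumericVector halfwidth) {
  int ns = x0.size();
  List out(ns);
  for (int s = 0; s < ns; ++s) {
    double ax = x0[s], ay = y0[s], bx = x1[s], by = y1[s], hw = halfwidth[s];
    double dx = bx - ax, dy = by - ay;
    double len2 = dx * dx + dy * dy;
    int jlo = std::max(1, (int)std::floor(std::min(ax, bx) - hw));
    int jhi = std::min(nc, (int)std::ceil(std::max(ax, bx) + hw));
    int ilo = std::max(1, (int)std::floor(std::min(ay, by) - hw));
    int ihi = std::min(nr, (int)std::ceil(std::max(ay, by) + hw));
    std::vector<int> idx;
    double hw2 = hw * hw;
    for (int j = jlo; j <= jhi; ++j) {
      for (int i = ilo; i <= ihi; ++i) {
        double px = (double)j - ax, py = (double)i - ay;
        double t = len2 > 0 ? (px * dx + py * dy) / len2 : 0.0;
        if (t < 0) t = 0; else if (t > 1) t = 1;
        double ex = px - t * dx, ey = py - t * dy;
        if (ex * ex + ey * ey <= hw2)
          idx.push_back(i + (j - 1) * nr);
      }
    }
    out[s] = IntegerVector(idx.begin(), idx.end());
  }
  return out;
}

// Local mean and (population) standard deviation over a circular window of
// the given radius (pixels with di^2 + dj^2 <= radius^2), windows clipped at
// the image border (statistics over the in-image part only).
// [[Rcpp::export]]
List cpp_disk_stats(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  if (2 * radius + 1 > nr || 2 * radius + 1 > nc)
    stop("window diameter exceeds image size");
  // row-wise prefix sums: P(i, j) = sum of img[i, 1..j]
  std::vector<double> P((size_t)nr * (nc + 1), 0.0), Q((size_t)nr * (nc + 1), 0.0);
  for (int i = 0; i < nr; ++i) {
    double s = 0.0, sq = 0.0;
    for (int j = 0; j < nc; ++j) {
      s += img(i, j);
      sq += img(i, j) * img(i, j);
      P[(size_t)i * (nc + 1) + j + 1] = s;
      Q[(size_t)i * (nc + 1) + j + 1] = sq;
    }
  }
  std::vector<int> hx(2 * radius + 1);
  for (int dy = -radius; dy <= radius; ++dy)
    hx[dy + radius] = (int)std::floor(std::sqrt((double)radius * radius - (double)dy * dy));
  NumericMatrix mu(nr, nc), sd(nr, nc);
  std::vector<double> sum(nc), sumsq(nc);
  std::vector<int> cnt(nc);
  for (int i = 0; i < nr; ++i) {
    std::fill(sum.begin(), sum.end(), 0.0);
    std::fill(sumsq.begin(), sumsq.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int dy = -radius; dy <= radius; ++dy) {
      int ii = i + dy;
      if (ii < 0 || ii >= nr) continue;
      int h = hx[dy + radius];
      const double *Pr = &P[(size_t)ii * (nc + 1)];
      const double *Qr = &Q[(size_t)ii * (nc + 1)];
      for (int j = 0; j < nc; ++j) {
        int lo = j - h; if (lo < 0) lo = 0;
        int hi = j + h; if (hi > nc - 1) hi = nc - 1;
        sum[j] += Pr[hi + 1] - Pr[lo];
        sumsq[j] += Qr[hi + 1] - Qr[lo];
        cnt[j] += hi - lo + 1;
      }
    }
    for (int j = 0; j < nc; ++j) {
      double m = sum[j] / cnt[j];
      double v = sumsq[j] / cnt[j] - m * m;
      mu(i, j) = m;
      sd(i, j) = v > 0 ? std::sqrt(v) : 0.0;
    }
  }
  return List::create(_["mean"] = mu, _["sd"] = sd);
}

// Separable convolution with a centered 1D kernel applied along rows then
// columns; at borders the kernel is clipped and renormalized to the in-image
// kernel mass (so a constant image is exactly preserved).
// [[Rcpp::export]]
NumericMatrix cpp_sepconv_clip(NumericMatrix img, NumericVector kernel) {
  int nr = img.nrow(), nc = img.ncol();
  int K = (kernel.size() - 1) / 2;
  if (kernel.size() % 2 != 1) stop("kernel length must be odd");
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double acc = 0.0, w = 0.0;
      int tlo = std::max(-K, -j), thi = std::min(K, nc - 1 - j);
      for (int t = tlo; t <= thi; ++t) {
        acc += kernel[t + K] * img(i, j + t);
        w += kernel[t + K];
      }
      tmp(i, j) = acc / w;
    }
  }
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0, w = 0.0;
      int tlo = std::max(-K, -i), thi = std::min(K, nr - 1 - i);
      for (int t = tlo; t <= thi; ++t) {
        acc += kernel[t + K] * tmp(i + t, j);
        w += kernel[t + K];
      }
      out(i, j) = acc / w;
    }
  }
  return out;
}

// Connected-component labeling of a logical mask (union-find, two passes).
// connectivity is 4 or 8; labels are 1..N in column-major scan order of the
// first pixel of each component; background stays 0.
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label_mask(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0); // dummy so labels start at 1
  // first pass, column-major (R storage order)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      int neigh[4][2] = {{i - 1, j}, {i, j - 1}, {i - 1, j - 1}, {i + 1, j - 1}};
      int nn = connectivity == 4 ? 2 : 4;
      int roots[4]; int nroots = 0;
      for (int k = 0; k < nn; ++k) {
        int ni = neigh[k][0], nj = neigh[k][1];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        int l = lab(ni, nj);
        if (l > 0) {
          int r = uf_find(parent, l);
          roots[nroots++] = r;
          if (best == 0 || r < best) best = r;
        }
      }
      if (best == 0) {
        int nl = (int)parent.size();
        parent.push_back(nl);
        lab(i, j) = nl;
      } else {
        lab(i, j) = best;
        for (int k = 0; k < nroots; ++k) parent[roots[k]] = best;
      }
    }
  }
  // second pass: compress and renumber in scan order of first occurrence
  std::vector<int> newlab(parent.size(), 0);
  int nextl = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = uf_find(parent, l);
      if (newlab[r] == 0) newlab[r] = ++nextl;
      lab(i, j) = newlab[r];
    }
  }
  return lab;
}

// Chain-code perimeter per labeled region: Moore boundary tracing of the
// outer boundary, steps weighted 1 (axis) and sqrt(2) (diagonal). Regions
// with no traceable boundary (single pixels) return 0; callers apply the
// single-pixel outline convention.
// [[Rcpp::export]]
NumericVector cpp_region_perimeters(IntegerMatrix lab, int nlab) {
  int nr = lab.nrow(), nc = lab.ncol();
  // start pixel per label: topmost, then leftmost (row-major first occurrence)
  std::vector<int> si(nlab + 1, -1), sj(nlab + 1, -1);
  std::vector<long> npx(nlab + 1, 0);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int l = lab(i, j);
      if (l > 0) {
        if (si[l] < 0) { si[l] = i; sj[l] = j; }
        ++npx[l];
      }
    }
  }
  // clockwise neighbor order (rows grow downwards): E SE S SW W NW N NE
  const int di[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int dj[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  const double w[8] = {1, M_SQRT2, 1, M_SQRT2, 1, M_SQRT2, 1, M_SQRT2};
  // direction lookup from (di+1, dj+1)
  int dirof[3][3];
  dirof[1][1] = -1;
  for (int d = 0; d < 8; ++d) dirof[di[d] + 1][dj[d] + 1] = d;
  NumericVector per(nlab);
  for (int l = 1; l <= nlab; ++l) {
    int bi = si[l], bj = sj[l];
    if (bi < 0) { per[l - 1] = NA_REAL; continue; }
    // backtrack starts at the pixel above the start (background by scan order)
    int ci = bi - 1, cj = bj;
    int b0i = bi, b0j = bj;
    // the walk settles onto the outer-boundary cycle, which passes through
    // the topmost-leftmost pixel b0; detect the cycle by the backtrack state
    // observed at b0 and report the chain length of exactly one full cycle
    bool seen[8];
    double chain_at[8];
    for (int d = 0; d < 8; ++d) { seen[d] = false; chain_at[d] = 0.0; }
    int d0 = dirof[ci - bi + 1][cj - bj + 1];
    seen[d0] = true;
    double chain = 0.0, result = -1.0;
    bool moved = false;
    long maxsteps = 8 * npx[l] + 32;
    long steps = 0;
    while (steps++ < maxsteps) {
      int back = dirof[ci - bi + 1][cj - bj + 1];
      int found = -1;
      int lasti = ci, lastj = cj;
      for (int k = 1; k <= 8; ++k) {
        int d = (back + k) % 8;
        int ni = bi + di[d], nj = bj + dj[d];
        bool in = ni >= 0 && ni < nr && nj >= 0 && nj < nc && lab(ni, nj) == l;
        if (in) { found = d; break; }
        lasti = ni; lastj = nj;
      }
      if (found < 0) break; // isolated pixel
      chain += w[found];
      ci = lasti; cj = lastj;
      bi += di[found]; bj += dj[found];
      moved = true;
      if (bi == b0i && bj == b0j) {
        int dc = dirof[ci - bi + 1][cj - bj + 1];
        if (seen[dc]) { result = chain - chain_at[dc]; break; }
        seen[dc] = true;
        chain_at[dc] = chain;
      }
    }
    per[l - 1] = result >= 0 ? result : (moved ? chain : 0.0);
  }
  return per;
}

// Per-label pixel counts and boundary flags in one pass: a region pixel is a
// boundary pixel when any 8-neighbour is outside the supplied domain mask
// (used for ROI-rim contact flags).
// [[Rcpp::export]]
LogicalVector cpp_touches_outside(IntegerMatrix lab, LogicalMatrix domain, int nlab) {
  int nr = lab.nrow(), nc = lab.ncol();
  LogicalVector touch(nlab);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      bool t = false;
      for (int di = -1; di <= 1 && !t; ++di) {
        for (int dj = -1; dj <= 1 && !t; ++dj) {
          if (di == 0 && dj == 0) continue;
          int ni = i + di, nj = j + dj;
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc || !domain(ni, nj)) t = true;
        }
      }
      if (t) touch[l - 1] = true;
    }
  }
  return touch;
}
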