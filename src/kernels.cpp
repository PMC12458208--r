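#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Separable Gaussian convolution with reflected boundaries.
// sigma in pixels; kernel truncated at 3 sigma.
// [[Rcpp::export(name = ".c_gauss_blur")]]
NumericMatrix c_gauss_blur(const NumericMatrix& x, double sigma) {
  int nr = x.nrow(), nc = x.ncol();
  if (sigma <= 0) return clone(x);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (first dimension), contiguous within each column
  for (int j = 0; j < nc; ++j) {
    const double* col = &x(0, j);
    double* tcol = &tmp(0, j);
    int lo = std::min(r, nr), hi = std::max(0, nr - r);
    for (int i = 0; i < lo; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) {
        int ii = i + d;
        if (ii < 0) ii = -ii - 1;
        if (ii >= nr) ii = 2 * nr - ii - 1;
        acc += k[d + r] * col[ii];
      }
      tcol[i] = acc;
    }
    for (int i = lo; i < hi; ++i) {  // interior: no boundary checks
      double acc = 0.0;
      const double* p = col + i - r;
      for (int d = 0; d <= 2 * r; ++d) acc += k[d] * p[d];
      tcol[i] = acc;
    }
    for (int i = hi; i < nr; ++i) {
      if (i < lo) continue;
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) {
        int ii = i + d;
        if (ii < 0) ii = -ii - 1;
        if (ii >= nr) ii = 2 * nr - ii - 1;
        acc += k[d + r] * col[ii];
      }
      tcol[i] = acc;
    }
  }
  // along columns: accumulate neighbour columns (contiguous axpy per tap)
  for (int j = 0; j < nc; ++j) {
    double* ocol = &out(0, j);
    for (int i = 0; i < nr; ++i) ocol[i] = 0.0;
    for (int d = -r; d <= r; ++d) {
      int jj = j + d;
      if (jj < 0) jj = -jj - 1;
      if (jj >= nc) jj = 2 * nc - jj - 1;
      const double* tcol = &tmp(0, jj);
      double w = k[d + r];
      for (int i = 0; i < nr; ++i) ocol[i] += w * tcol[i];
    }
  }
  return out;
}

// Danielsson-style vector distance transform with nearest-seed labels.
// seeds: integer matrix, 0 = free space, >0 = seed label.
// Returns Euclidean distance (pixels, pixel-centre to pixel-centre) to the
// nearest seed pixel and that seed's label. Exact up to the classic 8SED
// corner cases (< 0.1 px error).
// [[Rcpp::export(name = ".c_nearest_seed")]]
List c_nearest_seed(const IntegerMatrix& seeds, double maxDist = -1.0,
                    bool returnDist = true) {
  const int nr = seeds.nrow(), nc = seeds.ncol();
  const int n = nr * nc;
  const int32_t BIG = 1 << 29;
  std::vector<int32_t> dx(n), dy(n);
  IntegerMatrix lab(nr, nc);
  const int* sp = &seeds(0, 0);
  int* lp = &lab(0, 0);
  for (int i = 0; i < n; ++i) {
    if (sp[i] > 0) { dx[i] = 0; dy[i] = 0; lp[i] = sp[i]; }
    else { dx[i] = BIG; dy[i] = BIG; lp[i] = 0; }
  }
  const int64_t cap2 = (maxDist > 0)
    ? (int64_t)std::floor(maxDist * maxDist + 1e-9) : INT64_MAX / 8;
  auto d2 = [&](int idx) -> int64_t {
    if (dx[idx] >= BIG) return INT64_MAX / 4;
    return (int64_t)dx[idx] * dx[idx] + (int64_t)dy[idx] * dy[idx];
  };
  // relax pixel idx from neighbour at offset (oi, oj): oi along rows, oj cols
  auto relax = [&](int idx, int nidx, int oi, int oj) {
    if (dx[nidx] >= BIG) return;
    int64_t cand_x = (int64_t)dx[nidx] + oi;
    int64_t cand_y = (int64_t)dy[nidx] + oj;
    int64_t cd = cand_x * cand_x + cand_y * cand_y;
    if (cd > cap2) return;
    if (cd < d2(idx)) {
      dx[idx] = (int32_t)cand_x; dy[idx] = (int32_t)cand_y; lp[idx] = lp[nidx];
    }
  };
  // column-major layout: idx = i + j*nr (i = row, j = col)
  // Pass 1: columns left->right; within column rows top->bottom, then bottom pass for row dir
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int idx = i + j * nr;
      if (i > 0) relax(idx, idx - 1, 1, 0);
      if (j > 0) relax(idx, idx - nr, 0, 1);
      if (i > 0 && j > 0) relax(idx, idx - nr - 1, 1, 1);
      if (i < nr - 1 && j > 0) relax(idx, idx - nr + 1, -1, 1);
    }
    for (int i = nr - 1; i >= 0; --i) {
      int idx = i + j * nr;
      if (i < nr - 1) relax(idx, idx + 1, -1, 0);
    }
  }
  // Pass 2: columns right->left
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      int idx = i + j * nr;
      if (i < nr - 1) relax(idx, idx + 1, -1, 0);
      if (j < nc - 1) relax(idx, idx + nr, 0, -1);
      if (i < nr - 1 && j < nc - 1) relax(idx, idx + nr + 1, -1, -1);
      if (i > 0 && j < nc - 1) relax(idx, idx + nr - 1, 1, -1);
    }
    for (int i = 0; i < nr; ++i) {
      int idx = i + j * nr;
      if (i > 0) relax(idx, idx - 1, 1, 0);
    }
  }
  if (!returnDist) return List::create(_["label"] = lab);
  NumericMatrix dist(nr, nc);
  double* dp = &dist(0, 0);
  for (int i = 0; i < n; ++i)
    dp[i] = (dx[i] >= BIG) ? R_PosInf : std::sqrt((double)dx[i] * dx[i] + (double)dy[i] * dy[i]);
  return List::create(_["dist"] = dist, _["label"] = lab);
}

// Max-blend soft-edged filled ellipses (cell/marker blobs) into an image.
// Coordinates and radii in pixel units (1-based centres as from R).
// soft = width of the linear soft edge in pixels.
// [[Rcpp::export(name = ".c_render_blobs")]]
void c_render_blobs(NumericMatrix img, const NumericVector& cx, const NumericVector& cy,
                    const NumericVector& rx, const NumericVector& ry,
                    const NumericVector& theta, const NumericVector& value, double soft) {
  int nr = img.nrow(), nc = img.ncol();
  int ncell = cx.size();
  for (int c = 0; c < ncell; ++c) {
    double rmax = std::max(rx[c], ry[c]) + soft + 1.0;
    int i0 = std::max(0, (int)std::floor(cy[c] - 1 - rmax));
    int i1 = std::min(nr - 1, (int)std::ceil(cy[c] - 1 + rmax));
    int j0 = std::max(0, (int)std::floor(cx[c] - 1 - rmax));
    int j1 = std::min(nc - 1, (int)std::ceil(cx[c] - 1 + rmax));
    double ct = std::cos(theta[c]), st = std::sin(theta[c]);
    for (int j = j0; j <= j1; ++j) {
      double px = j + 1 - cx[c];
      for (int i = i0; i <= i1; ++i) {
        double py = i + 1 - cy[c];
        double u = (ct * px + st * py) / rx[c];
        double v = (-st * px + ct * py) / ry[c];
        double rho = std::sqrt(u * u + v * v);
        // signed distance to the ellipse edge, approx in pixels
        double rdir = std::sqrt(std::pow(ct * px + st * py, 2) + std::pow(-st * px + ct * py, 2));
        double edge = (rho > 0) ? rdir * (1.0 - 1.0 / rho) : -std::min(rx[c], ry[c]);
        double w;
        if (soft <= 0) w = (rho <= 1.0) ? 1.0 : 0.0;
        else w = std::min(1.0, std::max(0.0, 0.5 - edge / soft));
        if (w > 0) {
          double val = w * value[c];
          if (val > img(i, j)) img(i, j) = val;
        }
      }
    }
  }
}

// Greedy sequential hard-core thinning: keep points at least rmin apart,
// in input order, using a bucket grid. Coordinates arbitrary units.
// [[Rcpp::export(name = ".c_hardcore_filter")]]
LogicalVector c_hardcore_filter(const NumericVector& x, const NumericVector& y, double rmin) {
  int n = x.size();
  LogicalVector keep(n);
  if (n == 0) return keep;
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  double cell = std::max(rmin, 1e-9);
  int gx = (int)((xmax - xmin) / cell) + 1;
  int gy = (int)((ymax - ymin) / cell) + 1;
  std::vector<std::vector<int>> grid((size_t)gx * gy);
  double r2 = rmin * rmin;
  for (int i = 0; i < n; ++i) {
    int cxi = (int)((x[i] - xmin) / cell);
    int cyi = (int)((y[i] - ymin) / cell);
    bool ok = true;
    for (int a = std::max(0, cxi - 1); a <= std::min(gx - 1, cxi + 1) && ok; ++a)
      for (int b = std::max(0, cyi - 1); b <= std::min(gy - 1, cyi + 1) && ok; ++b)
        for (int idx : grid[(size_t)a * gy + b]) {
          double ddx = x[i] - x[idx], ddy = y[i] - y[idx];
          if (ddx * ddx + ddy * ddy < r2) { ok = false; break; }
        }
    keep[i] = ok;
    if (ok) grid[(size_t)cxi * gy + cyi].push_back(i);
  }
  return keep;
}

// Finalize a rendered channel: add N(bgMean, bgSd) noise (R's RNG stream),
// round and clamp to 0..255, returning an integer matrix in one pass.
// [[Rcpp::export(name = ".c_finalize_channel")]]
IntegerMatrix c_finalize_channel(const NumericMatrix& img, double bgMean, double bgSd) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(nr, nc);
  const double* ip = &img(0, 0);
  int* op = &out(0, 0);
  const int n = nr * nc;
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double v = ip[i] + bgMean + bgSd * norm_rand();
    v = std::round(v);
    if (v < 0) v = 0;
    if (v > 255) v = 255;
    op[i] = (int)v;
  }
  return out;
}

// Separable square max filter (window = 2r+1), O(w) per pixel.
// [[Rcpp::export(name = ".c_max_filter")]]
NumericMatrix c_max_filter(const NumericMatrix& x, int r) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double* col = &x(0, j);
    double* tcol = &tmp(0, j);
    for (int i = 0; i < nr; ++i) {
      int a = std::max(0, i - r), b = std::min(nr - 1, i + r);
      double m = col[a];
      for (int q = a + 1; q <= b; ++q) m = std::max(m, col[q]);
      tcol[i] = m;
    }
  }
  for (int j = 0; j < nc; ++j) {
    int a = std::max(0, j - r), b = std::min(nc - 1, j + r);
    double* ocol = &out(0, j);
    const double* c0 = &tmp(0, a);
    for (int i = 0; i < nr; ++i) ocol[i] = c0[i];
    for (int q = a + 1; q <= b; ++q) {
      const double* cq = &tmp(0, q);
      for (int i = 0; i < nr; ++i) if (cq[i] > ocol[i]) ocol[i] = cq[i];
    }
  }
  return out;
}

// Joint (label, band) pixel counts: for pixels with label in 1..nlab and
// band in 1..nband, counts[label-1, band-1]++.
// [[Rcpp::export(name = ".c_label_band_counts")]]
IntegerMatrix c_label_band_counts(const IntegerMatrix& lab,
                                  const IntegerMatrix& band,
                                  int nlab, int nband) {
  IntegerMatrix counts(nlab, nband);
  const int n = lab.nrow() * lab.ncol();
  const int* lp = &lab(0, 0);
  const int* bp = &band(0, 0);
  for (int i = 0; i < n; ++i) {
    int l = lp[i], b = bp[i];
    if (l > 0 && l <= nlab && b > 0 && b <= nband) counts(l - 1, b - 1)++;
  }
  return counts;
}

// Per-label sums and counts of an image over an integer label mask.
// Accepts integer or double image storage without copying.
// [[Rcpp::export(name = ".c_label_stats")]]
List c_label_stats(const IntegerMatrix& lab, SEXP img, int nlab) {
  NumericVector sums(nlab);
  IntegerVector counts(nlab);
  const int n = lab.nrow() * lab.ncol();
  const int* lp = &lab(0, 0);
  if (TYPEOF(img) == INTSXP) {
    const int* ip = INTEGER(img);
    for (int i = 0; i < n; ++i) {
      int l = lp[i];
      if (l > 0 && l <= nlab) { sums[l - 1] += ip[i]; counts[l - 1]++; }
    }
  } else {
    const double* ip = REAL(img);
    for (int i = 0; i < n; ++i) {
      int l = lp[i];
      if (l > 0 && l <= nlab) { sums[l - 1] += ip[i]; counts[l - 1]++; }
    }
  }
  return List::create(_["sum"] = sums, _["n"] = counts);
}

// Per-label centroid accumulators: sums of row and column indices (1-based).
// [[Rcpp::export(name = ".c_label_centroids")]]
List c_label_centroids(const IntegerMatrix& lab, int nlab) {
  NumericVector si(nlab), sj(nlab);
  IntegerVector counts(nlab);
  int nr = lab.nrow(), nc = lab.ncol();
  const int* lp = &lab(0, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = *lp++;
      if (l > 0 && l <= nlab) {
        si[l - 1] += i + 1; sj[l - 1] += j + 1; counts[l - 1]++;
      }
    }
  return List::create(_["si"] = si, _["sj"] = sj, _["n"] = counts);
}

// Per-label pixel counts only.
// [[Rcpp::export(name = ".c_label_counts")]]
IntegerVector c_label_counts(const IntegerMatrix& lab, int nlab) {
  IntegerVector counts(nlab);
  const int n = lab.nrow() * lab.ncol();
  const int* lp = &lab(0, 0);
  for (int i = 0; i < n; ++i) {
    int l = lp[i];
    if (l > 0 && l <= nlab) counts[l - 1]++;
  }
  return counts;
}
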