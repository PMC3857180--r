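// Low-level image primitives for colonyspot.
//
// All matrices are R numeric/logical/integer matrices indexed (row, col);
// offsets are given as (dx, dy) = (column, row) displacements to match the
// package-wide x = column, y = row convention.  Out-of-bounds handling is
// stated per function.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline bool inside(int r, int c, int nr, int nc) {
  return r >= 0 && r < nr && c >= 0 && c < nc;
}

// ---------------------------------------------------------------------------
// Grayscale morphology with an arbitrary (possibly non-flat) structuring
// element.  Offsets falling outside the image are ignored ("restricted"
// convention), which keeps the opening of a constant image exactly constant.

// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(NumericMatrix img, IntegerVector dx,
                             IntegerVector dy, NumericVector h) {
  int nr = img.nrow(), nc = img.ncol(), K = dx.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        int rr = r + dy[k], cc = c + dx[k];
        if (!inside(rr, cc, nr, nc)) continue;
        double v = img(rr, cc) - h[k];
        if (v < m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(NumericMatrix img, IntegerVector dx,
                              IntegerVector dy, NumericVector h) {
  int nr = img.nrow(), nc = img.ncol(), K = dx.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = -std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        // reflected SE for dilation so erode/dilate form an adjunction
        int rr = r - dy[k], cc = c - dx[k];
        if (!inside(rr, cc, nr, nc)) continue;
        double v = img(rr, cc) + h[k];
        if (v > m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// CLAHE.  Intensities are binned to 0..255; `clip` is a multiple of the mean
// bin count (clip <= 0 or non-finite means no clipping).  Per-tile mappings
// m(v) = round(255 * (cdf(v) - cdf_min) / (N - cdf_min)) are blended with
// bilinear interpolation between tile centers (clamped at the borders).

// [[Rcpp::export]]
NumericMatrix cpp_clahe(NumericMatrix img, int tiles_r, int tiles_c,
                        double clip) {
  int nr = img.nrow(), nc = img.ncol();
  const int NB = 256;
  std::vector< std::vector<double> > map(tiles_r * tiles_c,
                                         std::vector<double>(NB, 0.0));
  std::vector<int> r0(tiles_r), r1(tiles_r), c0(tiles_c), c1(tiles_c);
  for (int t = 0; t < tiles_r; ++t) {
    r0[t] = (int)std::floor((double)t * nr / tiles_r);
    r1[t] = (int)std::floor((double)(t + 1) * nr / tiles_r);
  }
  for (int t = 0; t < tiles_c; ++t) {
    c0[t] = (int)std::floor((double)t * nc / tiles_c);
    c1[t] = (int)std::floor((double)(t + 1) * nc / tiles_c);
  }
  IntegerMatrix bin(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int b = (int)std::lround(img(r, c));
      if (b < 0) b = 0;
      if (b > 255) b = 255;
      bin(r, c) = b;
    }
  for (int tr = 0; tr < tiles_r; ++tr) {
    for (int tc = 0; tc < tiles_c; ++tc) {
      std::vector<double> hist(NB, 0.0);
      double n = 0.0;
      for (int c = c0[tc]; c < c1[tc]; ++c)
        for (int r = r0[tr]; r < r1[tr]; ++r) {
          hist[bin(r, c)] += 1.0;
          n += 1.0;
        }
      if (n == 0) continue;
      if (R_finite(clip) && clip > 0) {
        double lim = clip * n / NB;
        if (lim < 1.0) lim = 1.0;
        double excess = 0.0;
        for (int b = 0; b < NB; ++b)
          if (hist[b] > lim) { excess += hist[b] - lim; hist[b] = lim; }
        double add = excess / NB;
        for (int b = 0; b < NB; ++b) hist[b] += add;
      }
      std::vector<double> cdf(NB);
      double acc = 0.0;
      for (int b = 0; b < NB; ++b) { acc += hist[b]; cdf[b] = acc; }
      double cdfmin = 0.0;
      for (int b = 0; b < NB; ++b)
        if (cdf[b] > 0) { cdfmin = cdf[b]; break; }
      double denom = acc - cdfmin;
      std::vector<double> &m = map[tr * tiles_c + tc];
      for (int b = 0; b < NB; ++b) {
        if (denom <= 0) m[b] = (double)b;  // degenerate single-level tile
        else {
          double v = 255.0 * (cdf[b] - cdfmin) / denom;
          m[b] = std::round(v);
        }
      }
    }
  }
  // tile centers
  std::vector<double> rc(tiles_r), cc_(tiles_c);
  for (int t = 0; t < tiles_r; ++t) rc[t] = 0.5 * (r0[t] + r1[t] - 1);
  for (int t = 0; t < tiles_c; ++t) cc_[t] = 0.5 * (c0[t] + c1[t] - 1);
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    int tc1 = 0;
    while (tc1 < tiles_c - 1 && cc_[tc1 + 1] < c) ++tc1;
    int tc2 = tc1;
    if (c > cc_[tc1] && tc1 < tiles_c - 1) tc2 = tc1 + 1;
    double wc = (tc2 == tc1) ? 0.0
      : (c - cc_[tc1]) / (cc_[tc2] - cc_[tc1]);
    if (wc < 0) wc = 0;
    if (wc > 1) wc = 1;
    for (int r = 0; r < nr; ++r) {
      int tr1 = 0;
      while (tr1 < tiles_r - 1 && rc[tr1 + 1] < r) ++tr1;
      int tr2 = tr1;
      if (r > rc[tr1] && tr1 < tiles_r - 1) tr2 = tr1 + 1;
      double wr = (tr2 == tr1) ? 0.0
        : (r - rc[tr1]) / (rc[tr2] - rc[tr1]);
      if (wr < 0) wr = 0;
      if (wr > 1) wr = 1;
      int b = bin(r, c);
      double v11 = map[tr1 * tiles_c + tc1][b];
      double v12 = map[tr1 * tiles_c + tc2][b];
      double v21 = map[tr2 * tiles_c + tc1][b];
      double v22 = map[tr2 * tiles_c + tc2][b];
      out(r, c) = (1 - wr) * ((1 - wc) * v11 + wc * v12)
                +      wr  * ((1 - wc) * v21 + wc * v22);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Perona-Malik anisotropic diffusion, exponential conductance
// g(d) = exp(-(d/kappa)^2), explicit 4-neighbour flux scheme with zero-flux
// (Neumann) boundaries.  Pairwise-antisymmetric fluxes conserve the global
// sum exactly (up to floating point).

// [[Rcpp::export]]
NumericMatrix cpp_perona_malik(NumericMatrix img, int iters, double kappa,
                               double dt) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix cur = clone(img);
  NumericMatrix nxt(nr, nc);
  double k2 = kappa * kappa;
  for (int it = 0; it < iters; ++it) {
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        double v = cur(r, c), flux = 0.0;
        if (r > 0)      { double d = cur(r - 1, c) - v; flux += std::exp(-d * d / k2) * d; }
        if (r < nr - 1) { double d = cur(r + 1, c) - v; flux += std::exp(-d * d / k2) * d; }
        if (c > 0)      { double d = cur(r, c - 1) - v; flux += std::exp(-d * d / k2) * d; }
        if (c < nc - 1) { double d = cur(r, c + 1) - v; flux += std::exp(-d * d / k2) * d; }
        nxt(r, c) = v + dt * flux;
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// ---------------------------------------------------------------------------
// Two-phase region-competition level-set evolution (arctan-regularized
// Heaviside/Dirac).  phi < 0 inside.  Update:
//   phi += dt * delta_eps(phi) * [ l_in (I-c1)^2 - l_out (I-c2)^2 + mu * curv ]
// with (c1, c2) recomputed each iteration and phi clipped to [-50, 50].

// [[Rcpp::export]]
NumericMatrix cpp_evolve_level_set(NumericMatrix img, NumericMatrix phi0,
                                   double lambda_in, double lambda_out,
                                   double mu, double eps, double dt,
                                   int n_iter) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix phi = clone(phi0);
  const double PI = 3.14159265358979323846;
  NumericMatrix nx(nr, nc), ny(nr, nc);
  for (int it = 0; it < n_iter; ++it) {
    // region means under the regularized Heaviside
    double s_in = 0, s_out = 0, w_in = 0, w_out = 0;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double H = 0.5 * (1.0 + (2.0 / PI) * std::atan(phi(r, c) / eps));
        double I = img(r, c);
        w_out += H;      s_out += H * I;
        w_in  += 1 - H;  s_in  += (1 - H) * I;
      }
    if (w_in <= 1e-12)
      stop("level-set inside region has zero weight at iteration %d", it + 1);
    if (w_out <= 1e-12)
      stop("level-set outside region has zero weight at iteration %d", it + 1);
    double c1 = s_in / w_in, c2 = s_out / w_out;
    // normalized gradient (replicate borders)
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        int cp = c + 1 < nc ? c + 1 : c, cm = c > 0 ? c - 1 : c;
        int rp = r + 1 < nr ? r + 1 : r, rm = r > 0 ? r - 1 : r;
        double px = (phi(r, cp) - phi(r, cm)) / (cp - cm > 0 ? cp - cm : 1);
        double py = (phi(rp, c) - phi(rm, c)) / (rp - rm > 0 ? rp - rm : 1);
        double g = std::sqrt(px * px + py * py);
        if (g < 1e-8) g = 1e-8;
        nx(r, c) = px / g;
        ny(r, c) = py / g;
      }
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        int cp = c + 1 < nc ? c + 1 : c, cm = c > 0 ? c - 1 : c;
        int rp = r + 1 < nr ? r + 1 : r, rm = r > 0 ? r - 1 : r;
        double curv = (nx(r, cp) - nx(r, cm)) / (cp - cm > 0 ? cp - cm : 1)
                    + (ny(rp, c) - ny(rm, c)) / (rp - rm > 0 ? rp - rm : 1);
        double p = phi(r, c);
        double del = eps / (PI * (eps * eps + p * p));
        double I = img(r, c);
        double F = lambda_in * (I - c1) * (I - c1)
                 - lambda_out * (I - c2) * (I - c2)
                 + mu * curv;
        p += dt * del * F;
        if (!std::isfinite(p)) {
          stop("non-finite level-set value at iteration %d", it + 1);
        }
        if (p > 50.0) p = 50.0;
        if (p < -50.0) p = -50.0;
        phi(r, c) = p;
      }
  }
  return phi;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// distance to the nearest TRUE pixel.  Pixels where no TRUE pixel exists get
// a large finite sentinel (nr*nr + nc*nc).

static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sq_edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  double big = (double)nr * nr + (double)nc * nc + 1.0;
  NumericMatrix g(nr, nc);
  // columns first
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? 0.0 : big;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = std::min(d[c], big);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Grayscale reconstruction by dilation: iterate J = min(dilate3x3(J), mask)
// until stable.  marker must be <= mask everywhere.

// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J = clone(marker);
  bool changed = true;
  int guard = 0, guard_max = 4 * (nr + nc) + 16;
  while (changed && guard++ < guard_max) {
    changed = false;
    // forward raster pass
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double m = J(r, c);
        for (int k = 0; k < 4; ++k) {
          static const int drf[4] = {-1, -1, -1, 0};
          static const int dcf[4] = {-1, 0, 1, -1};
          int rr = r + drf[k], cc = c + dcf[k];
          if (inside(rr, cc, nr, nc) && J(rr, cc) > m) m = J(rr, cc);
        }
        if (m > mask(r, c)) m = mask(r, c);
        if (m > J(r, c)) { J(r, c) = m; changed = true; }
      }
    // backward raster pass
    for (int c = nc - 1; c >= 0; --c)
      for (int r = nr - 1; r >= 0; --r) {
        double m = J(r, c);
        for (int k = 0; k < 4; ++k) {
          static const int drb[4] = {1, 1, 1, 0};
          static const int dcb[4] = {1, 0, -1, 1};
          int rr = r + drb[k], cc = c + dcb[k];
          if (inside(rr, cc, nr, nc) && J(rr, cc) > m) m = J(rr, cc);
        }
        if (m > mask(r, c)) m = mask(r, c);
        if (m > J(r, c)) { J(r, c) = m; changed = true; }
      }
  }
  return J;
}

// ---------------------------------------------------------------------------
// Connected-component labeling (8- or 4-connectivity), BFS.

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int n_nb = (conn == 4) ? 4 : 8;
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = {0, 0, -1, 1};
  const int *dr = (conn == 4) ? dr4 : dr8;
  const int *dc = (conn == 4) ? dc4 : dc8;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr0 = idx % nr, cc0 = idx / nr;
        for (int k = 0; k < n_nb; ++k) {
          int rr = rr0 + dr[k], cc = cc0 + dc[k];
          if (inside(rr, cc, nr, nc) && mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  return lab;
}

// ---------------------------------------------------------------------------
// Hole filling: a hole is background (4-connected) not reachable from the
// image border.

// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix reach(nr, nc);
  std::fill(reach.begin(), reach.end(), false);
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    if (!mask(0, c) && !reach(0, c)) { reach(0, c) = true; stack.push_back(0 + c * nr); }
    if (!mask(nr - 1, c) && !reach(nr - 1, c)) { reach(nr - 1, c) = true; stack.push_back(nr - 1 + c * nr); }
  }
  for (int r = 0; r < nr; ++r) {
    if (!mask(r, 0) && !reach(r, 0)) { reach(r, 0) = true; stack.push_back(r); }
    if (!mask(r, nc - 1) && !reach(r, nc - 1)) { reach(r, nc - 1) = true; stack.push_back(r + (nc - 1) * nr); }
  }
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr4[k], cc = c + dc4[k];
      if (inside(rr, cc, nr, nc) && !mask(rr, cc) && !reach(rr, cc)) {
        reach(rr, cc) = true;
        stack.push_back(rr + cc * nr);
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = mask(r, c) || !reach(r, c);
  return out;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed by priority flooding of `priority` (higher
// floods first; pass the distance transform to split touching blobs along
// the ridge of -EDT).  Labels grow from `markers` (> 0) within `mask`,
// 8-connected; first-arrival wins, FIFO tie-break for equal priority.

struct QItem {
  double pr;
  long long order;
  int idx;
  int label;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.pr != b.pr) return a.pr < b.pr;     // max-heap on priority
    return a.order > b.order;                 // FIFO on ties
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix priority, IntegerMatrix markers,
                            LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> q;
  long long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        q.push(QItem{priority(r, c), order++, r + c * nr, markers(r, c)});
      }
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!q.empty()) {
    QItem it = q.top(); q.pop();
    int r = it.idx % nr, c = it.idx / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], cc = c + dc8[k];
      if (inside(rr, cc, nr, nc) && mask(rr, cc) && lab(rr, cc) == 0) {
        lab(rr, cc) = it.label;
        q.push(QItem{priority(rr, cc), order++, rr + cc * nr, it.label});
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Regional maxima of img restricted to mask: connected plateaus (8-conn,
// equal value) with no strictly higher neighbour inside the mask.

// [[Rcpp::export]]
LogicalMatrix cpp_regional_maxima(NumericMatrix img, LogicalMatrix mask) {
  int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix out(nr, nc);
  IntegerMatrix seen(nr, nc);
  std::fill(out.begin(), out.end(), false);
  std::fill(seen.begin(), seen.end(), 0);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::vector<int> stack, plateau;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || seen(r, c)) continue;
      double v = img(r, c);
      bool is_max = true;
      plateau.clear();
      stack.push_back(r + c * nr);
      seen(r, c) = 1;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        plateau.push_back(idx);
        int r0 = idx % nr, c0 = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int rr = r0 + dr8[k], cc = c0 + dc8[k];
          if (!inside(rr, cc, nr, nc) || !mask(rr, cc)) continue;
          double w = img(rr, cc);
          if (w > v) is_max = false;
          else if (w == v && !seen(rr, cc)) {
            seen(rr, cc) = 1;
            stack.push_back(rr + cc * nr);
          }
        }
      }
      if (is_max)
        for (size_t i = 0; i < plateau.size(); ++i)
          out[plateau[i]] = true;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Orientation-matching response: sum over template offsets of the dot
// product between the normalized image gradient at p + offset and the
// radial template weight.  Out-of-bounds samples contribute zero.

// [[Rcpp::export]]
NumericMatrix cpp_om_response(NumericMatrix nx, NumericMatrix ny,
                              IntegerVector dx, IntegerVector dy,
                              NumericVector wx, NumericVector wy) {
  int nr = nx.nrow(), nc = nx.ncol(), K = dx.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), 0.0);
  for (int k = 0; k < K; ++k) {
    int ox = dx[k], oy = dy[k];
    double ax = wx[k], ay = wy[k];
    int r_lo = std::max(0, -oy), r_hi = std::min(nr, nr - oy);
    int c_lo = std::max(0, -ox), c_hi = std::min(nc, nc - ox);
    for (int c = c_lo; c < c_hi; ++c)
      for (int r = r_lo; r < r_hi; ++r)
        out(r, c) += nx(r + oy, c + ox) * ax + ny(r + oy, c + ox) * ay;
  }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_local_maxima(NumericMatrix score, double threshold) {
  int nr = score.nrow(), nc = score.ncol();
  LogicalMatrix out(nr, nc);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = score(r, c);
      bool ok = v >= threshold;
      for (int k = 0; k < 8 && ok; ++k) {
        int rr = r + dr8[k], cc = c + dc8[k];
        if (inside(rr, cc, nr, nc) && score(rr, cc) > v) ok = false;
      }
      out(r, c) = ok;
    }
  return out;
}
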