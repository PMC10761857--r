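// Low-level raster kernels for pore-space analysis: exact Euclidean distance
// transform with feature (nearest-site) output, connected-component labelling
// with selectable connectivity, Zhang-Suen thinning, geodesic (within-region)
// distance, and the segregation-index annulus scan.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>
#include <set>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher), with
// argmin tracking; f may contain +Inf (columns holding no site).
static void dt1d(const std::vector<double>& f, int n,
                 std::vector<double>& d, std::vector<int>& arg) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = 0.0;
    while (k >= 0) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k == -1) {
    for (int q = 0; q < n; ++q) { d[q] = INF; arg[q] = -1; }
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    d[q] = (double)(q - v[j]) * (q - v[j]) + f[v[j]];
    arg[q] = v[j];
  }
}

// Exact squared Euclidean distance (in pixels^2) from every pixel to the
// nearest TRUE pixel of `sites`, plus the 1-based linear index of that pixel.
// [[Rcpp::export]]
List cpp_edt(LogicalMatrix sites) {
  int nr = sites.nrow(), nc = sites.ncol();
  NumericMatrix d2(nr, nc);
  IntegerMatrix nearest(nr, nc);
  // pass 1: per column, nearest site row (1D scan)
  IntegerMatrix grow(nr, nc);
  NumericMatrix g(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int last = -1;
    for (int i = 0; i < nr; ++i) {
      if (sites(i, j)) last = i;
      grow(i, j) = last;
      g(i, j) = (last < 0) ? INF : (double)(i - last) * (i - last);
    }
    last = -1;
    for (int i = nr - 1; i >= 0; --i) {
      if (sites(i, j)) last = i;
      if (last >= 0) {
        double dd = (double)(last - i) * (last - i);
        if (dd < g(i, j)) { g(i, j) = dd; grow(i, j) = last; }
      }
    }
  }
  // pass 2: per row, lower envelope over columns
  std::vector<double> f(nc), dd(nc);
  std::vector<int> arg(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = g(i, j);
    dt1d(f, nc, dd, arg);
    for (int j = 0; j < nc; ++j) {
      d2(i, j) = dd[j];
      if (arg[j] < 0) {
        nearest(i, j) = NA_INTEGER;
      } else {
        int jstar = arg[j];
        int istar = grow(i, jstar);
        nearest(i, j) = istar + jstar * nr + 1; // 1-based linear index
      }
    }
  }
  return List::create(_["dist2"] = d2, _["nearest"] = nearest);
}

// Connected components of non-zero pixels; connectivity 4 or 8.
// Labels are dense 1..n in scan order of first encounter.
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  int cur = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++cur;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = cur;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nn; ++k) {
          int qi = pi + di8[k], qj = pj + dj8[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = cur;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  lab.attr("n") = cur;
  return lab;
}

static inline int getpx(const LogicalMatrix& m, int i, int j) {
  if (i < 0 || i >= m.nrow() || j < 0 || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Zhang-Suen thinning to a 1-pixel-wide, connectivity-preserving skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix m = clone(img);
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!m(i, j)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = getpx(m, i - 1, j),     p3 = getpx(m, i - 1, j + 1);
          int p4 = getpx(m, i, j + 1),     p5 = getpx(m, i + 1, j + 1);
          int p6 = getpx(m, i + 1, j),     p7 = getpx(m, i + 1, j - 1);
          int p8 = getpx(m, i, j - 1),     p9 = getpx(m, i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(i + j * nr);
        }
      }
      for (size_t k = 0; k < kill.size(); ++k) {
        m[kill[k]] = false;
        changed = true;
      }
    }
  }
  return m;
}

// Geodesic distance (pixels, 8-connected, diagonal = sqrt(2)) from the seed
// pixels through the TRUE pixels of `domain`. +Inf where unreachable/outside.
// [[Rcpp::export]]
NumericMatrix cpp_geodesic(LogicalMatrix domain, IntegerVector seeds) {
  int nr = domain.nrow(), nc = domain.ncol();
  NumericMatrix d(nr, nc);
  std::fill(d.begin(), d.end(), INF);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int k = 0; k < seeds.size(); ++k) {
    int p = seeds[k] - 1;
    if (p < 0 || p >= nr * nc) stop("seed index out of range");
    if (!domain[p]) continue;
    if (d[p] > 0) { d[p] = 0.0; pq.push(Node(0.0, p)); }
  }
  int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  double w8[8] = {1, 1, 1, 1, M_SQRT2, M_SQRT2, M_SQRT2, M_SQRT2};
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int p = nd.second;
    if (nd.first > d[p]) continue;
    int pi = p % nr, pj = p / nr;
    for (int k = 0; k < 8; ++k) {
      int qi = pi + di8[k], qj = pj + dj8[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (!domain(qi, qj)) continue;
      int q = qi + qj * nr;
      double nd2 = nd.first + w8[k];
      if (nd2 < d[q]) { d[q] = nd2; pq.push(Node(nd2, q)); }
    }
  }
  return d;
}

// Segregation index: for each skeleton point (si, sj; 0-based) with inscribed
// radius r_px, count distinct grain ids among solid pixels whose centre lies
// within `band` pixels of the inscribed-disk boundary.
// [[Rcpp::export]]
IntegerVector cpp_seg_index(IntegerMatrix grains, IntegerVector si,
                            IntegerVector sj, NumericVector r_px, double band) {
  int nr = grains.nrow(), nc = grains.ncol();
  int n = si.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    int ci = si[k], cj = sj[k];
    double r = r_px[k];
    int w = (int)std::ceil(r + band) + 1;
    std::set<int> ids;
    for (int dj = -w; dj <= w; ++dj) {
      int j = cj + dj;
      if (j < 0 || j >= nc) continue;
      for (int di = -w; di <= w; ++di) {
        int i = ci + di;
        if (i < 0 || i >= nr) continue;
        int g = grains(i, j);
        if (g == 0) continue;
        double dist = std::sqrt((double)di * di + (double)dj * dj);
        if (std::fabs(dist - r) <= band) ids.insert(g);
      }
    }
    out[k] = (int)ids.size();
  }
  return out;
}

// 3x3 median smoothing (window clamped at borders); used to stabilise
// regional-maximum detection before intensity thresholding.
// [[Rcpp::export]]
NumericMatrix cpp_median3(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> w;
  w.reserve(9);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      w.clear();
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int qi = i + di, qj = j + dj;
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          w.push_back(img(qi, qj));
        }
      size_t m = w.size() / 2;
      std::nth_element(w.begin(), w.begin() + m, w.end());
      double med = w[m];
      if (w.size() % 2 == 0) {
        std::nth_element(w.begin(), w.begin() + m - 1, w.end());
        med = (med + w[m - 1]) / 2.0;
      }
      out(i, j) = med;
    }
  return out;
}
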