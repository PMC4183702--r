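#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Grid convention (used consistently across the package):
//   n x n square pixels of side h (cm), physical origin at the grid center,
//   x rightward, y upward, row 0 at the top.
//   Pixel (r, c), 0-based, covers x in [xmin + c h, xmin + (c+1) h],
//   y in [ymax - (r+1) h, ymax - r h], with xmin = -n h / 2, ymax = n h / 2.
//   Row-major pixel index j = r * n + c.

// Trace one ray segment through the grid; appends (pixel index, intersection
// length in cm) pairs. Parametric Siddon-style traversal: clip the segment to
// the grid bounding box (Liang-Barsky), merge the sorted crossing parameters
// with vertical and horizontal grid lines, and read off one pixel per
// interval. Exact up to floating round-off; zero-length corner intervals are
// dropped.
static void trace_ray(double x0, double y0, double x1, double y1,
                      int n, double h,
                      std::vector<int> &jout, std::vector<double> &lout) {
  const double dx = x1 - x0, dy = y1 - y0;
  const double L = std::sqrt(dx * dx + dy * dy);
  if (L <= 0.0) return;
  const double xmin = -0.5 * n * h, ymax = 0.5 * n * h;
  const double xmax = -xmin, ymin = -ymax;

  // Liang-Barsky clip of t in [0, 1] to the box
  double t0 = 0.0, t1 = 1.0;
  const double p[4] = {-dx, dx, -dy, dy};
  const double q[4] = {x0 - xmin, xmax - x0, y0 - ymin, ymax - y0};
  for (int k = 0; k < 4; ++k) {
    if (p[k] == 0.0) {
      if (q[k] < 0.0) return; // parallel and outside
    } else {
      double r = q[k] / p[k];
      if (p[k] < 0.0) {
        if (r > t1) return;
        if (r > t0) t0 = r;
      } else {
        if (r < t0) return;
        if (r < t1) t1 = r;
      }
    }
  }
  if (t1 <= t0) return;

  // crossing parameters with the grid lines, each list ascending in t
  std::vector<double> ax, ay;
  ax.reserve(n + 1);
  ay.reserve(n + 1);
  if (dx != 0.0) {
    for (int i = 0; i <= n; ++i) {
      double t = ((xmin + i * h) - x0) / dx;
      if (t > t0 && t < t1) ax.push_back(t);
    }
    if (dx < 0.0) std::reverse(ax.begin(), ax.end());
  }
  if (dy != 0.0) {
    for (int i = 0; i <= n; ++i) {
      double t = ((ymin + i * h) - y0) / dy;
      if (t > t0 && t < t1) ay.push_back(t);
    }
    if (dy < 0.0) std::reverse(ay.begin(), ay.end());
  }
  std::vector<double> alpha;
  alpha.reserve(ax.size() + ay.size() + 2);
  alpha.push_back(t0);
  std::merge(ax.begin(), ax.end(), ay.begin(), ay.end(),
             std::back_inserter(alpha));
  alpha.push_back(t1);

  const double tol = 1e-14;
  for (size_t k = 0; k + 1 < alpha.size(); ++k) {
    double a = alpha[k], b = alpha[k + 1];
    if (b - a <= tol) continue;
    double tm = 0.5 * (a + b);
    double px = x0 + tm * dx, py = y0 + tm * dy;
    int c = (int)std::floor((px - xmin) / h);
    int r = (int)std::floor((ymax - py) / h);
    if (c < 0) c = 0; else if (c >= n) c = n - 1;
    if (r < 0) r = 0; else if (r >= n) r = n - 1;
    jout.push_back(r * n + c);
    lout.push_back((b - a) * L);
  }
}

// [[Rcpp::export]]
List cpp_siddon_trace(double x0, double y0, double x1, double y1,
                      int n, double h) {
  std::vector<int> j;
  std::vector<double> len;
  trace_ray(x0, y0, x1, y1, n, h, j, len);
  return List::create(_["index"] = wrap(j), _["length"] = wrap(len));
}

// Build the full fan-beam system matrix in CSR layout, rows ordered
// view-major / bin-minor. Source at angle theta: (R cos theta, R sin theta);
// virtual equi-distance detector on the line through the rotation axis with
// direction (-sin theta, cos theta); bin k center offset (k - (B-1)/2) * ap.
// Rays that miss the grid keep their (empty) row so M stays views x bins.
// [[Rcpp::export]]
List cpp_build_system_matrix(NumericVector angles, int bins, double aperture,
                             double sad, int n, double h) {
  const int V = angles.size();
  const R_xlen_t M = (R_xlen_t)V * bins;
  const int N = n * n;
  std::vector<int> col;
  std::vector<double> val;
  // rough nnz estimate: each ray crosses at most 2n pixels
  col.reserve((size_t)M * (size_t)(1.2 * n) + 1024);
  val.reserve(col.capacity());
  IntegerVector row_ptr(M + 1);
  NumericVector row_sums(M);
  NumericVector col_sums(N);
  NumericMatrix view_col_sums(N, V);

  const double half = 0.5 * (bins - 1);
  const double reach = sad + n * h; // beyond-grid extension of each ray
  row_ptr[0] = 0;
  R_xlen_t i = 0;
  for (int v = 0; v < V; ++v) {
    const double ct = std::cos(angles[v]), st = std::sin(angles[v]);
    const double sx = sad * ct, sy = sad * st;
    double *vcs = &view_col_sums(0, v);
    for (int b = 0; b < bins; ++b, ++i) {
      const double t = (b - half) * aperture;
      const double dxp = -t * st - sx, dyp = t * ct - sy;
      const double dl = std::sqrt(dxp * dxp + dyp * dyp);
      const double ex = sx + dxp / dl * (dl + reach);
      const double ey = sy + dyp / dl * (dl + reach);
      size_t before = col.size();
      trace_ray(sx, sy, ex, ey, n, h, col, val);
      double rs = 0.0;
      for (size_t k = before; k < col.size(); ++k) {
        rs += val[k];
        col_sums[col[k]] += val[k];
        vcs[col[k]] += val[k];
      }
      row_sums[i] = rs;
      row_ptr[i + 1] = (int)col.size();
    }
  }
  return List::create(_["row_ptr"] = row_ptr, _["col_ind"] = wrap(col),
                      _["val"] = wrap(val), _["row_sums"] = row_sums,
                      _["col_sums"] = col_sums,
                      _["view_col_sums"] = view_col_sums);
}

// [[Rcpp::export]]
NumericVector cpp_forward(IntegerVector row_ptr, IntegerVector col_ind,
                          NumericVector val, NumericVector f) {
  const R_xlen_t M = row_ptr.size() - 1;
  NumericVector p(M);
  for (R_xlen_t i = 0; i < M; ++i) {
    double s = 0.0;
    for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
      s += val[k] * f[col_ind[k]];
    p[i] = s;
  }
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_back(IntegerVector row_ptr, IntegerVector col_ind,
                       NumericVector val, NumericVector p, int N) {
  const R_xlen_t M = row_ptr.size() - 1;
  NumericVector f(N);
  for (R_xlen_t i = 0; i < M; ++i) {
    const double pi = p[i];
    if (pi == 0.0) continue;
    for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
      f[col_ind[k]] += val[k] * pi;
  }
  return f;
}

// One SART pass. mode 0: sequential view-by-view sweep in angle order;
// mode 1: simultaneous (all views in one normalized correction).
// For each view: f_j += lambda * [sum_{i in view} a_ij (p_i - <a_i, f>) /
// row_sum_i] / view_col_sum_j, skipping zero-sum rays and pixels.
// Returns the updated image and the squared residual accumulated as each
// ray was visited (i.e. against the image current at that moment).
// [[Rcpp::export]]
List cpp_sart_sweep(IntegerVector row_ptr, IntegerVector col_ind,
                    NumericVector val, NumericVector p, NumericVector f_in,
                    double lambda, int bins, int views,
                    NumericVector row_sums, NumericMatrix view_col_sums,
                    NumericVector col_sums, int mode) {
  const int N = f_in.size();
  NumericVector f = clone(f_in);
  std::vector<double> num((size_t)N);
  double res2 = 0.0;
  if (mode == 1) {
    // simultaneous: single correction normalized by total column sums
    std::fill(num.begin(), num.end(), 0.0);
    const R_xlen_t M = (R_xlen_t)views * bins;
    for (R_xlen_t i = 0; i < M; ++i) {
      if (row_sums[i] <= 0.0) continue;
      double s = 0.0;
      for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
        s += val[k] * f[col_ind[k]];
      double d = p[i] - s;
      res2 += d * d;
      d /= row_sums[i];
      for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
        num[col_ind[k]] += val[k] * d;
    }
    for (int j = 0; j < N; ++j)
      if (col_sums[j] > 0.0) f[j] += lambda * num[j] / col_sums[j];
  } else {
    for (int v = 0; v < views; ++v) {
      std::fill(num.begin(), num.end(), 0.0);
      const R_xlen_t lo = (R_xlen_t)v * bins, hi = lo + bins;
      for (R_xlen_t i = lo; i < hi; ++i) {
        if (row_sums[i] <= 0.0) continue;
        double s = 0.0;
        for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
          s += val[k] * f[col_ind[k]];
        double d = p[i] - s;
        res2 += d * d;
        d /= row_sums[i];
        for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
          num[col_ind[k]] += val[k] * d;
      }
      const double *vcs = &view_col_sums(0, v);
      for (int j = 0; j < N; ++j)
        if (vcs[j] > 0.0) f[j] += lambda * num[j] / vcs[j];
    }
  }
  return List::create(_["f"] = f, _["residual"] = std::sqrt(res2));
}

// Soft-threshold filtering step reducing the weighted total difference.
// For pixel (r,c) and each in-grid neighbor n (4 axial, weight 1; 4
// diagonal, weight alpha): candidate g_n = f_n + S_w(f - f_n) with
// S_w(x) = sign(x) max(|x| - w, 0); output = weighted mean of candidates,
// normalized by the weights of the neighbors actually present.
// [[Rcpp::export]]
NumericMatrix cpp_stf_filter(NumericMatrix img, double w, double alpha) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const int dr[8] = {0, 0, -1, 1, -1, -1, 1, 1};
  const int dc[8] = {-1, 1, 0, 0, -1, 1, -1, 1};
  const double wt[8] = {1, 1, 1, 1, alpha, alpha, alpha, alpha};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double fij = img(r, c);
      double acc = 0.0, wsum = 0.0;
      for (int k = 0; k < 8; ++k) {
        if (wt[k] == 0.0) continue;
        const int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const double fn = img(rr, cc);
        double d = fij - fn;
        double s = (d > w) ? (d - w) : ((d < -w) ? (d + w) : 0.0);
        acc += wt[k] * (fn + s);
        wsum += wt[k];
      }
      out(r, c) = (wsum > 0.0) ? acc / wsum : fij;
    }
  }
  return out;
}
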