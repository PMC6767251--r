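// Siddon ray-driven projector for 2D parallel/fan-beam CT.
//
// Grid convention: n_rows x n_cols pixels of size h, centred on the origin.
// Column c (0-based) spans x in [xmin + c*h, xmin + (c+1)*h], xmin = -n_cols*h/2.
// Row r (0-based, top row first) spans y in [ymax - (r+1)*h, ymax - r*h],
// ymax = +n_rows*h/2. Images are R matrices (n_rows x n_cols, column-major).
//
// View angles theta (radians): detector axis v = (cos t, sin t), ray
// direction u = (-sin t, cos t). Parallel rays pass through s*v; fan rays run
// from the source at -SOD*u to detector element S + SDD*u + s*v. Bin offsets
// s are centred: s_b = (b - (n_bins-1)/2) * bin_size, b 0-based.
//
// Forward and back projection walk rays with the identical traversal, so the
// back-projector is the exact adjoint of the forward projector.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static void trace_ray(double x0, double y0, double x1, double y1,
                      int nr, int nc, double h,
                      std::vector<int>& idx, std::vector<double>& len) {
  idx.clear(); len.clear();
  const double dx = x1 - x0, dy = y1 - y0;
  const double L = std::sqrt(dx * dx + dy * dy);
  if (L <= 0.0) return;
  const double xmin = -0.5 * nc * h, xmax = 0.5 * nc * h;
  const double ymin = -0.5 * nr * h, ymax = 0.5 * nr * h;
  double tmin = 0.0, tmax = 1.0;
  if (dx != 0.0) {
    double t1 = (xmin - x0) / dx, t2 = (xmax - x0) / dx;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
  } else if (x0 <= xmin || x0 >= xmax) return;
  if (dy != 0.0) {
    double t1 = (ymin - y0) / dy, t2 = (ymax - y0) / dy;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
  } else if (y0 <= ymin || y0 >= ymax) return;
  if (tmax <= tmin) return;

  std::vector<double> ts;
  ts.reserve((size_t)(nr + nc + 4));
  ts.push_back(tmin); ts.push_back(tmax);
  if (dx != 0.0) {
    for (int i = 0; i <= nc; ++i) {
      double t = (xmin + i * h - x0) / dx;
      if (t > tmin && t < tmax) ts.push_back(t);
    }
  }
  if (dy != 0.0) {
    for (int j = 0; j <= nr; ++j) {
      double t = (ymin + j * h - y0) / dy;
      if (t > tmin && t < tmax) ts.push_back(t);
    }
  }
  std::sort(ts.begin(), ts.end());
  for (size_t m = 0; m + 1 < ts.size(); ++m) {
    const double ta = ts[m], tb = ts[m + 1];
    if (tb - ta <= 1e-12) continue;  // duplicate crossing
    const double xm = x0 + 0.5 * (ta + tb) * dx;
    const double ym = y0 + 0.5 * (ta + tb) * dy;
    int c = (int)std::floor((xm - xmin) / h);
    int r = (int)std::floor((ymax - ym) / h);
    if (c < 0 || c >= nc || r < 0 || r >= nr) continue;
    idx.push_back(c * nr + r);
    len.push_back((tb - ta) * L);
  }
}

static inline void ray_endpoints(double theta, double s, int mode,
                                 double sod, double sdd, double reach,
                                 double& x0, double& y0,
                                 double& x1, double& y1) {
  const double ct = std::cos(theta), st = std::sin(theta);
  if (mode == 0) {  // parallel: through s*v, direction u = (-st, ct)
    const double px = s * ct, py = s * st;
    x0 = px + reach * st; y0 = py - reach * ct;
    x1 = px - reach * st; y1 = py + reach * ct;
  } else {          // fan: source -SOD*u to detector element
    x0 = sod * st;  y0 = -sod * ct;
    x1 = x0 - sdd * st + s * ct;
    y1 = y0 + sdd * ct + s * st;
  }
}

// [[Rcpp::export]]
List cpp_siddon_trace(int n_rows, int n_cols, double pixel_size,
                      double x0, double y0, double x1, double y1) {
  std::vector<int> idx; std::vector<double> len;
  trace_ray(x0, y0, x1, y1, n_rows, n_cols, pixel_size, idx, len);
  const int n = (int)idx.size();
  IntegerVector rows(n), cols(n);
  NumericVector lengths(n);
  for (int i = 0; i < n; ++i) {
    rows[i] = idx[i] % n_rows + 1;       // 1-based
    cols[i] = idx[i] / n_rows + 1;
    lengths[i] = len[i];
  }
  return List::create(_["rows"] = rows, _["cols"] = cols,
                      _["lengths"] = lengths);
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(const NumericMatrix& image, int mode,
                                  const NumericVector& angles_rad,
                                  int n_bins, double bin_size,
                                  double sod, double sdd, double pixel_size) {
  const int nr = image.nrow(), nc = image.ncol();
  const int nv = angles_rad.size();
  const double reach =
      0.5 * std::sqrt((double)nr * nr + (double)nc * nc) * pixel_size +
      pixel_size;
  NumericMatrix sino(nv, n_bins);
  std::vector<int> idx; std::vector<double> len;
  const double* img = REAL(image);
  for (int v = 0; v < nv; ++v) {
    for (int b = 0; b < n_bins; ++b) {
      const double s = (b - 0.5 * (n_bins - 1)) * bin_size;
      double x0, y0, x1, y1;
      ray_endpoints(angles_rad[v], s, mode, sod, sdd, reach, x0, y0, x1, y1);
      trace_ray(x0, y0, x1, y1, nr, nc, pixel_size, idx, len);
      double acc = 0.0;
      for (size_t m = 0; m < idx.size(); ++m) acc += len[m] * img[idx[m]];
      sino(v, b) = acc;
    }
  }
  return sino;
}

// [[Rcpp::export]]
NumericMatrix cpp_back_project(const NumericMatrix& sino, int mode,
                               const NumericVector& angles_rad,
                               double bin_size, double sod, double sdd,
                               int n_rows, int n_cols, double pixel_size) {
  const int nv = sino.nrow(), nb = sino.ncol();
  const double reach =
      0.5 * std::sqrt((double)n_rows * n_rows + (double)n_cols * n_cols) *
          pixel_size + pixel_size;
  NumericMatrix image(n_rows, n_cols);
  double* img = REAL(image);
  std::vector<int> idx; std::vector<double> len;
  for (int v = 0; v < nv; ++v) {
    for (int b = 0; b < nb; ++b) {
      const double w = sino(v, b);
      if (w == 0.0) continue;
      const double s = (b - 0.5 * (nb - 1)) * bin_size;
      double x0, y0, x1, y1;
      ray_endpoints(angles_rad[v], s, mode, sod, sdd, reach, x0, y0, x1, y1);
      trace_ray(x0, y0, x1, y1, n_rows, n_cols, pixel_size, idx, len);
      for (size_t m = 0; m < idx.size(); ++m) img[idx[m]] += len[m] * w;
    }
  }
  return image;
}

// One SART sweep: the classic view-sequential update. For each valid view
// (in ascending order), the row-normalised residuals of all its rays are
// accumulated with intersection-length weights, divided by the per-pixel sum
// of weights, and applied to the image immediately before the next view is
// visited. An image satisfying A u = g on the valid views is a fixed point.
// [[Rcpp::export]]
NumericMatrix cpp_sart_sweep(const NumericMatrix& image,
                             const NumericMatrix& sino,
                             const LogicalVector& valid, int mode,
                             const NumericVector& angles_rad,
                             double bin_size, double sod, double sdd,
                             double pixel_size, double relaxation) {
  const int nr = image.nrow(), nc = image.ncol();
  const int nv = sino.nrow(), nb = sino.ncol();
  const double reach =
      0.5 * std::sqrt((double)nr * nr + (double)nc * nc) * pixel_size +
      pixel_size;
  NumericMatrix out(clone(image));
  double* img = REAL(out);
  std::vector<double> num((size_t)nr * nc), den((size_t)nr * nc);
  std::vector<int> idx; std::vector<double> len;
  for (int v = 0; v < nv; ++v) {
    if (!valid[v]) continue;
    std::fill(num.begin(), num.end(), 0.0);
    std::fill(den.begin(), den.end(), 0.0);
    for (int b = 0; b < nb; ++b) {
      const double s = (b - 0.5 * (nb - 1)) * bin_size;
      double x0, y0, x1, y1;
      ray_endpoints(angles_rad[v], s, mode, sod, sdd, reach, x0, y0, x1, y1);
      trace_ray(x0, y0, x1, y1, nr, nc, pixel_size, idx, len);
      double proj = 0.0, rowsum = 0.0;
      for (size_t m = 0; m < idx.size(); ++m) {
        proj += len[m] * img[idx[m]];
        rowsum += len[m];
      }
      if (rowsum <= 1e-12) continue;  // ray misses the grid
      const double resid = (sino(v, b) - proj) / rowsum;
      for (size_t m = 0; m < idx.size(); ++m) {
        num[idx[m]] += len[m] * resid;
        den[idx[m]] += len[m];
      }
    }
    for (size_t p = 0; p < num.size(); ++p)
      if (den[p] > 1e-12) img[p] += relaxation * num[p] / den[p];
  }
  return out;
}
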