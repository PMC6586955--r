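#include <Rcpp.h>
using namespace Rcpp;

// Squared distance from point (px,py) to segment (x0,y0)-(x1,y1).
// On return *tt holds the clamped projection parameter in [0,1].
static inline double seg_dist2(double px, double py,
                               double x0, double y0, double x1, double y1,
                               double *tt) {
  double dx = x1 - x0, dy = y1 - y0;
  double l2 = dx * dx + dy * dy;
  double t = 0.0;
  if (l2 > 0.0) {
    t = ((px - x0) * dx + (py - y0) * dy) / l2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  *tt = t;
  double qx = x0 + t * dx, qy = y0 + t * dy;
  return (px - qx) * (px - qx) + (py - qy) * (py - qy);
}

// Minimum distance from each query point to the segments of each feature
// type. Exact minimum over all member segments (no index approximation);
// columns with no segments return Inf.
// [[Rcpp::export(name = ".min_dist_by_type_cpp")]]
NumericMatrix min_dist_by_type_cpp(NumericVector px, NumericVector py,
                                   NumericVector x0, NumericVector y0,
                                   NumericVector x1, NumericVector y1,
                                   IntegerVector type_idx, int n_types) {
  int np = px.size(), ns = x0.size();
  NumericMatrix out(np, n_types);
  const double *PX = px.begin(), *PY = py.begin();
  const double *X0 = x0.begin(), *Y0 = y0.begin();
  const double *X1 = x1.begin(), *Y1 = y1.begin();
  const int *TY = type_idx.begin();
  double *O = out.begin();
  std::vector<double> best(n_types);
  double t;
  for (int i = 0; i < np; ++i) {
    std::fill(best.begin(), best.end(), R_PosInf);
    const double pxi = PX[i], pyi = PY[i];
    for (int s = 0; s < ns; ++s) {
      double d2 = seg_dist2(pxi, pyi, X0[s], Y0[s], X1[s], Y1[s], &t);
      if (d2 < best[TY[s]]) best[TY[s]] = d2;
    }
    for (int k = 0; k < n_types; ++k)
      O[i + (R_xlen_t)k * np] =
        R_FINITE(best[k]) ? std::sqrt(best[k]) : R_PosInf;
  }
  return out;
}

// Minimum distance from one point to one polyline given as a vertex matrix.
// [[Rcpp::export(name = ".point_polyline_dist_cpp")]]
double point_polyline_dist_cpp(double px, double py, NumericMatrix verts) {
  int nv = verts.nrow();
  double best = R_PosInf, t;
  for (int s = 0; s + 1 < nv; ++s) {
    double d2 = seg_dist2(px, py, verts(s, 0), verts(s, 1),
                          verts(s + 1, 0), verts(s + 1, 1), &t);
    if (d2 < best) best = d2;
  }
  return std::sqrt(best);
}
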