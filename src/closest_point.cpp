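#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p; Ericson, Real-Time Collision
// Detection, ch. 5.1.5. Writes result into out[3].
static inline void closest_on_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix points, NumericMatrix vertices,
                         IntegerMatrix faces) {
  int n = points.nrow(), t = faces.nrow();
  if (t == 0) stop("mesh has no faces");
  NumericMatrix closest(n, 3);
  NumericVector dist(n);
  IntegerVector face_id(n);
  // column-major access buffers
  for (int i = 0; i < n; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    int bestf = 0;
    for (int f = 0; f < t; ++f) {
      int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
      double a[3] = {vertices(ia, 0), vertices(ia, 1), vertices(ia, 2)};
      double b[3] = {vertices(ib, 0), vertices(ib, 1), vertices(ib, 2)};
      double c[3] = {vertices(ic, 0), vertices(ic, 1), vertices(ic, 2)};
      double q[3];
      closest_on_triangle(p, a, b, c, q);
      double d2 = (p[0] - q[0]) * (p[0] - q[0]) +
                  (p[1] - q[1]) * (p[1] - q[1]) +
                  (p[2] - q[2]) * (p[2] - q[2]);
      if (d2 < best) {
        best = d2;
        bestf = f;
        bestpt[0] = q[0]; bestpt[1] = q[1]; bestpt[2] = q[2];
      }
    }
    closest(i, 0) = bestpt[0];
    closest(i, 1) = bestpt[1];
    closest(i, 2) = bestpt[2];
    dist[i] = std::sqrt(best);
    face_id[i] = bestf + 1;
  }
  return List::create(_["point"] = closest, _["distance"] = dist,
                      _["face"] = face_id);
}
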