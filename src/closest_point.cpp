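#include <Rcpp.h>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision
// Detection, ch. 5.1.5 (barycentric region tests).
static inline void closestOnTri(const double *p, const double *a,
                                const double *b, const double *c,
                                double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// For each query point, the nearest point on the target triangle mesh
// (exhaustive exact point-to-triangle search; ties broken by lowest face
// index via strict improvement). Returns list(points, distances, faces).
// [[Rcpp::export]]
List closest_points_on_mesh(NumericMatrix query, NumericMatrix verts,
                            IntegerMatrix faces) {
  int nq = query.nrow(), nf = faces.nrow();
  NumericMatrix out(nq, 3);
  NumericVector dist(nq);
  IntegerVector face_id(nq);
  std::vector<double> fa(nf * 9);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int vi = faces(f, k) - 1;
      for (int d = 0; d < 3; ++d) fa[f * 9 + k * 3 + d] = verts(vi, d);
    }
  }
  for (int q = 0; q < nq; ++q) {
    double p[3] = {query(q, 0), query(q, 1), query(q, 2)};
    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    int bestf = -1;
    double cand[3];
    for (int f = 0; f < nf; ++f) {
      const double *base = &fa[f * 9];
      closestOnTri(p, base, base + 3, base + 6, cand);
      double dx = cand[0] - p[0], dy = cand[1] - p[1], dz = cand[2] - p[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bestf = f;
        bestpt[0] = cand[0]; bestpt[1] = cand[1]; bestpt[2] = cand[2];
      }
    }
    out(q, 0) = bestpt[0]; out(q, 1) = bestpt[1]; out(q, 2) = bestpt[2];
    dist[q] = std::sqrt(best);
    face_id[q] = bestf + 1;
  }
  return List::create(_["points"] = out, _["distances"] = dist,
                      _["faces"] = face_id);
}
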