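// Assembly kernel for the BEM double-layer operator: exact van
// Oosterom-Strackee solid angles of mesh triangles seen from collocation
// points, lumped to triangle vertices; triangles close to the observation
// point are integrated on a uniform barycentric subdivision with linear
// lumping (passed in as a template from R).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double vos1(const double* p, const double* a,
                          const double* b, const double* c) {
  double y1[3], y2[3], y3[3];
  for (int k = 0; k < 3; ++k) {
    y1[k] = a[k] - p[k];
    y2[k] = b[k] - p[k];
    y3[k] = c[k] - p[k];
  }
  double d1 = std::sqrt(y1[0]*y1[0] + y1[1]*y1[1] + y1[2]*y1[2]);
  double d2 = std::sqrt(y2[0]*y2[0] + y2[1]*y2[1] + y2[2]*y2[2]);
  double d3 = std::sqrt(y3[0]*y3[0] + y3[1]*y3[1] + y3[2]*y3[2]);
  if (d1 < 1e-12 || d2 < 1e-12 || d3 < 1e-12) return 0.0;
  double cx = y2[1]*y3[2] - y2[2]*y3[1];
  double cy = y2[2]*y3[0] - y2[0]*y3[2];
  double cz = y2[0]*y3[1] - y2[1]*y3[0];
  double num = y1[0]*cx + y1[1]*cy + y1[2]*cz;
  double den = d1*d2*d3 + d3*(y1[0]*y2[0] + y1[1]*y2[1] + y1[2]*y2[2])
             + d2*(y1[0]*y3[0] + y1[1]*y3[1] + y1[2]*y3[2])
             + d1*(y2[0]*y3[0] + y2[1]*y3[1] + y2[2]*y3[2]);
  return 2.0 * std::atan2(num, den);
}

// [[Rcpp::export]]
arma::mat solid_angle_cpp(const arma::mat& points, const arma::mat& verts,
                          const arma::imat& faces, double near,
                          const arma::mat& tcorners, const arma::mat& tlump) {
  const arma::uword np = points.n_rows;
  const arma::uword nv = verts.n_rows;
  const arma::uword nf = faces.n_rows;
  const arma::uword nleaf = tlump.n_rows;
  arma::mat W(np, nv, arma::fill::zeros);

  // triangle corner coordinates and size metrics
  arma::mat P1(nf, 3), P2(nf, 3), P3(nf, 3), C(nf, 3);
  arma::vec maxedge(nf);
  for (arma::uword t = 0; t < nf; ++t) {
    P1.row(t) = verts.row(faces(t, 0) - 1);
    P2.row(t) = verts.row(faces(t, 1) - 1);
    P3.row(t) = verts.row(faces(t, 2) - 1);
    C.row(t) = (P1.row(t) + P2.row(t) + P3.row(t)) / 3.0;
    double e1 = arma::norm(P1.row(t) - P2.row(t));
    double e2 = arma::norm(P2.row(t) - P3.row(t));
    double e3 = arma::norm(P3.row(t) - P1.row(t));
    maxedge(t) = std::max(e1, std::max(e2, e3));
  }

  for (arma::uword i = 0; i < np; ++i) {
    double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    double pp[3] = {px, py, pz};
    for (arma::uword t = 0; t < nf; ++t) {
      double dx = C(t, 0) - px, dy = C(t, 1) - py, dz = C(t, 2) - pz;
      double dctr = std::sqrt(dx*dx + dy*dy + dz*dz);
      double a0[3] = {P1(t, 0), P1(t, 1), P1(t, 2)};
      double b0[3] = {P2(t, 0), P2(t, 1), P2(t, 2)};
      double c0[3] = {P3(t, 0), P3(t, 1), P3(t, 2)};
      if (dctr >= near * maxedge(t)) {
        double om = vos1(pp, a0, b0, c0);
        double third = om / 3.0;
        for (int k = 0; k < 3; ++k) W(i, faces(t, k) - 1) += third;
      } else {
        // refined integration with linear lumping
        double* c1 = a0; double* c2 = b0; double* c3 = c0;
        double acc[3] = {0, 0, 0};
        for (arma::uword l = 0; l < nleaf; ++l) {
          double la[3], lb[3], lc[3];
          for (int k = 0; k < 3; ++k) {
            la[k] = tcorners(3*l, 0)*c1[k] + tcorners(3*l, 1)*c2[k] +
                    tcorners(3*l, 2)*c3[k];
            lb[k] = tcorners(3*l+1, 0)*c1[k] + tcorners(3*l+1, 1)*c2[k] +
                    tcorners(3*l+1, 2)*c3[k];
            lc[k] = tcorners(3*l+2, 0)*c1[k] + tcorners(3*l+2, 1)*c2[k] +
                    tcorners(3*l+2, 2)*c3[k];
          }
          double om = vos1(pp, la, lb, lc);
          for (int k = 0; k < 3; ++k) acc[k] += om * tlump(l, k);
        }
        for (int k = 0; k < 3; ++k) W(i, faces(t, k) - 1) += acc[k];
      }
    }
  }
  return W;
}
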