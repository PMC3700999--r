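// Fast evaluation of the exterior multi-shell series for many dipoles and
// many sensor points at once. The per-degree radial transfer coefficients
// Dt (scalp-surface value per unit normalized primary term) are precomputed
// in R; here only the angular recurrences and the radial power factors are
// accumulated. Everything is in the conventions of spherical.R: no
// Condon-Shortley phase, Q_n = P_n^1 / sin(theta).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List sph_gain_cpp(const arma::mat& dip_pos, const arma::mat& dip_mom,
                  const arma::mat& pts, const arma::vec& Dt,
                  double r1, double rK, double sigma1, double tol,
                  bool want_field) {
  const arma::uword nd = dip_pos.n_rows;
  const arma::uword np = pts.n_rows;
  const arma::uword nmax = Dt.n_elem;

  arma::mat V(np, nd, arma::fill::zeros);
  arma::mat Er, Et, Ep;
  if (want_field) {
    Er.zeros(np, nd);
    Et.zeros(np, nd);
    Ep.zeros(np, nd);
  }

  // per-point geometry in the head frame
  arma::vec rp(np);
  arma::mat ph(np, 3);
  for (arma::uword i = 0; i < np; ++i) {
    double r = std::sqrt(arma::dot(pts.row(i), pts.row(i)));
    rp(i) = r;
    ph.row(i) = pts.row(i) / r;
  }

  for (arma::uword d = 0; d < nd; ++d) {
    arma::rowvec r0v = dip_pos.row(d);
    double r0 = std::sqrt(arma::dot(r0v, r0v));
    arma::rowvec ez = r0v / r0;
    arma::rowvec mom = dip_mom.row(d);
    double mr = arma::dot(mom, ez);
    arma::rowvec mtv = mom - mr * ez;
    double mt = std::sqrt(arma::dot(mtv, mtv));
    double mnorm = std::sqrt(arma::dot(mom, mom));
    arma::rowvec ex;
    if (mt > 1e-300 * std::max(1.0, mnorm)) {
      ex = mtv / mt;
    } else {
      arma::rowvec h = (std::fabs(ez(0)) < 0.9) ?
        arma::rowvec({1, 0, 0}) : arma::rowvec({0, 1, 0});
      h -= arma::dot(h, ez) * ez;
      ex = h / std::sqrt(arma::dot(h, h));
    }
    arma::rowvec ey = {ez(1) * ex(2) - ez(2) * ex(1),
                       ez(2) * ex(0) - ez(0) * ex(2),
                       ez(0) * ex(1) - ez(1) * ex(0)};
    double lam0 = 1.0 / (4.0 * M_PI * sigma1 * r0 * r0);
    double rho1 = r0 / r1;

    for (arma::uword i = 0; i < np; ++i) {
      double u = arma::dot(ph.row(i), ez);
      if (u > 1.0) u = 1.0;
      if (u < -1.0) u = -1.0;
      double px = arma::dot(ph.row(i), ex);
      double py = arma::dot(ph.row(i), ey);
      double st = std::sqrt(px * px + py * py);
      double cphi = (st > 0) ? px / st : 1.0;
      double sphi = (st > 0) ? py / st : 0.0;
      double rho = rho1 * (rK / rp(i));
      double pw = rho;            // rho^(n+1) at n = 0 start -> updated below
      double Pm1 = 1.0, P = u;    // P_0, P_1
      double Qm1 = 0.0, Q = 1.0;  // Q_0, Q_1
      double aV = 0, aR = 0, aT = 0, aP = 0;
      double scale = 0;
      for (arma::uword n = 1; n <= nmax; ++n) {
        pw *= rho;                // rho^(n+1)
        double f = lam0 * Dt(n - 1) * pw;
        double Qn1 = ((2.0 * n + 1.0) * u * Q - (n + 1.0) * Qm1) / n;
        double bracket = n * mr * P + mt * st * Q * cphi;
        aV += f * bracket;
        if (want_field) {
          aR += f * (n + 1.0) / rp(i) * bracket;
          double dPdth = -st * Q;
          double dP1dth = n * Qn1 - (n + 1.0) * u * Q;
          aT -= f / rp(i) * (n * mr * dPdth + mt * cphi * dP1dth);
          aP += f / rp(i) * mt * Q * sphi;
        }
        double mag = std::fabs(f) * (n * std::fabs(mr) + n * (n + 1.0) *
                                     std::fabs(mt));
        double ref = want_field ? std::fabs(aR) * rp(i) : std::fabs(aV);
        if (ref > scale) scale = ref;
        if (n > 10 && mag < tol * (scale > 0 ? scale : 1e-300)) break;
        double Pn1 = ((2.0 * n + 1.0) * u * P - n * Pm1) / (n + 1.0);
        Pm1 = P; P = Pn1;
        Qm1 = Q; Q = Qn1;
      }
      V(i, d) = aV;
      if (want_field) {
        // dipole-frame spherical unit vectors at the point, in Cartesian
        arma::rowvec eth = u * cphi * ex + u * sphi * ey - st * ez;
        arma::rowvec eph = -sphi * ex + cphi * ey;
        arma::rowvec Ec = aR * ph.row(i) + aT * eth + aP * eph;
        double cth = ph(i, 2);
        double sth = std::sqrt(ph(i, 0) * ph(i, 0) + ph(i, 1) * ph(i, 1));
        double ch = (sth > 0) ? ph(i, 0) / sth : 1.0;
        double sh = (sth > 0) ? ph(i, 1) / sth : 0.0;
        arma::rowvec eth_h = {cth * ch, cth * sh, -sth};
        arma::rowvec eph_h = {-sh, ch, 0};
        Er(i, d) = arma::dot(Ec, ph.row(i));
        Et(i, d) = arma::dot(Ec, eth_h);
        Ep(i, d) = arma::dot(Ec, eph_h);
      }
    }
  }
  if (want_field)
    return List::create(_["V"] = V, _["E_r"] = Er, _["E_theta"] = Et,
                        _["E_phi"] = Ep);
  return List::create(_["V"] = V);
}
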