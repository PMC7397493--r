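// Direct-summation structure factors and brute-force rotation/translation
// scans.  Exactness over speed at desk scale: no FFT, no interpolation.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double TWOPI = 6.283185307179586;

// form factor f(s) = sum_i a_i exp(-b_i s^2), s = sin(theta)/lambda
static inline double ffeval(const NumericMatrix& fa, const NumericMatrix& fb,
                            int e, double s2) {
  double f = 0.0;
  for (int i = 0; i < 5; ++i) f += fa(e, i) * std::exp(-fb(e, i) * s2);
  return f;
}

// per-atom scattering coefficient occ * f(s) * exp(-B s^2) for one s
static void atomCoefs(const NumericVector& occ, const NumericVector& bfac,
                      const IntegerVector& fidx, const NumericMatrix& fa,
                      const NumericMatrix& fb, double s, double* out) {
  const int m = occ.size();
  double s2 = s * s;
  // cache per element
  int nel = fa.nrow();
  std::vector<double> fel(nel, -1.0);
  for (int j = 0; j < m; ++j) {
    int e = fidx[j] - 1;
    if (fel[e] < 0) fel[e] = ffeval(fa, fb, e, s2);
    out[j] = occ[j] * fel[e] * std::exp(-bfac[j] * s2);
  }
}

// [[Rcpp::export]]
ComplexVector cpp_structure_factors(const NumericMatrix& hkl,
                                    const NumericVector& s,
                                    const NumericMatrix& frac,
                                    const NumericVector& occ,
                                    const NumericVector& bfac,
                                    const IntegerVector& fidx,
                                    const NumericMatrix& fa,
                                    const NumericMatrix& fb,
                                    const List& symR, const List& symT) {
  const int n = hkl.nrow(), m = frac.nrow(), ns = symR.size();
  ComplexVector F(n);
  // precompute symmetry images of the atoms: R x + t (fractional)
  std::vector<double> sx(ns * m), sy(ns * m), sz(ns * m);
  for (int k = 0; k < ns; ++k) {
    NumericMatrix R = symR[k];
    NumericVector t = symT[k];
    for (int j = 0; j < m; ++j) {
      double x = frac(j, 0), y = frac(j, 1), z = frac(j, 2);
      sx[k * m + j] = R(0, 0) * x + R(0, 1) * y + R(0, 2) * z + t[0];
      sy[k * m + j] = R(1, 0) * x + R(1, 1) * y + R(1, 2) * z + t[1];
      sz[k * m + j] = R(2, 0) * x + R(2, 1) * y + R(2, 2) * z + t[2];
    }
  }
  std::vector<double> coef(m);
  for (int i = 0; i < n; ++i) {
    atomCoefs(occ, bfac, fidx, fa, fb, s[i], coef.data());
    double h = hkl(i, 0), k = hkl(i, 1), l = hkl(i, 2);
    double re = 0.0, im = 0.0;
    for (int ks = 0; ks < ns; ++ks) {
      const double* px = &sx[ks * m];
      const double* py = &sy[ks * m];
      const double* pz = &sz[ks * m];
      for (int j = 0; j < m; ++j) {
        double arg = TWOPI * (h * px[j] + k * py[j] + l * pz[j]);
        re += coef[j] * std::cos(arg);
        im += coef[j] * std::sin(arg);
      }
    }
    F[i].r = re;
    F[i].i = im;
  }
  return F;
}

// molecular transform G(svec) = sum_j occ f exp(-B s^2) exp(2 pi i svec.r)
// svec are Cartesian reciprocal vectors (|svec| = 1/d); coords Cartesian.
// [[Rcpp::export]]
ComplexVector cpp_molecular_transform(const NumericMatrix& svec,
                                      const NumericMatrix& coords,
                                      const NumericVector& occ,
                                      const NumericVector& bfac,
                                      const IntegerVector& fidx,
                                      const NumericMatrix& fa,
                                      const NumericMatrix& fb) {
  const int n = svec.nrow(), m = coords.nrow();
  ComplexVector G(n);
  std::vector<double> coef(m);
  for (int i = 0; i < n; ++i) {
    double sxv = svec(i, 0), syv = svec(i, 1), szv = svec(i, 2);
    double smag = 0.5 * std::sqrt(sxv * sxv + syv * syv + szv * szv);
    atomCoefs(occ, bfac, fidx, fa, fb, smag, coef.data());
    double re = 0.0, im = 0.0;
    for (int j = 0; j < m; ++j) {
      double arg = TWOPI * (sxv * coords(j, 0) + syv * coords(j, 1) +
                            szv * coords(j, 2));
      re += coef[j] * std::cos(arg);
      im += coef[j] * std::sin(arg);
    }
    G[i].r = re;
    G[i].i = im;
  }
  return G;
}

// Rotation scan: for each rotation (rows of 'rots', 9 values row-major
// per rotation), compute the squared molecular transform of the rotated
// fragment at the data's scattering vectors, shell-normalize it to
// E^2 - 1, and correlate with the observed E^2 - 1.
// [[Rcpp::export]]
NumericVector cpp_rotation_scan(const NumericMatrix& svec,
                                const NumericMatrix& rots,
                                const NumericMatrix& coords,
                                const NumericVector& occ,
                                const NumericVector& bfac,
                                const IntegerVector& fidx,
                                const NumericMatrix& fa,
                                const NumericMatrix& fb,
                                const NumericVector& eobs,
                                const IntegerVector& shell,
                                int nshell) {
  const int n = svec.nrow(), m = coords.nrow(), K = rots.nrow();
  // per-reflection atom coefficients depend only on |s|: precompute matrix
  std::vector<double> coef(static_cast<size_t>(n) * m);
  for (int i = 0; i < n; ++i) {
    double sxv = svec(i, 0), syv = svec(i, 1), szv = svec(i, 2);
    double smag = 0.5 * std::sqrt(sxv * sxv + syv * syv + szv * szv);
    atomCoefs(occ, bfac, fidx, fa, fb, smag, &coef[static_cast<size_t>(i) * m]);
  }
  // observed moments for the Pearson correlation
  double mo = 0.0, vo = 0.0;
  for (int i = 0; i < n; ++i) mo += eobs[i];
  mo /= n;
  for (int i = 0; i < n; ++i) vo += (eobs[i] - mo) * (eobs[i] - mo);
  NumericVector out(K);
  std::vector<double> rx(m), ry(m), rz(m), I(n), e2(n);
  std::vector<double> shsum(nshell), shcnt(nshell);
  for (int kk = 0; kk < K; ++kk) {
    const double r00 = rots(kk, 0), r01 = rots(kk, 1), r02 = rots(kk, 2),
                 r10 = rots(kk, 3), r11 = rots(kk, 4), r12 = rots(kk, 5),
                 r20 = rots(kk, 6), r21 = rots(kk, 7), r22 = rots(kk, 8);
    for (int j = 0; j < m; ++j) {
      double x = coords(j, 0), y = coords(j, 1), z = coords(j, 2);
      rx[j] = r00 * x + r01 * y + r02 * z;
      ry[j] = r10 * x + r11 * y + r12 * z;
      rz[j] = r20 * x + r21 * y + r22 * z;
    }
    std::fill(shsum.begin(), shsum.end(), 0.0);
    std::fill(shcnt.begin(), shcnt.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double sxv = svec(i, 0), syv = svec(i, 1), szv = svec(i, 2);
      double re = 0.0, im = 0.0;
      const double* cf = &coef[static_cast<size_t>(i) * m];
      for (int j = 0; j < m; ++j) {
        double arg = TWOPI * (sxv * rx[j] + syv * ry[j] + szv * rz[j]);
        re += cf[j] * std::cos(arg);
        im += cf[j] * std::sin(arg);
      }
      I[i] = re * re + im * im;
      shsum[shell[i] - 1] += I[i];
      shcnt[shell[i] - 1] += 1.0;
    }
    double mc = 0.0;
    for (int i = 0; i < n; ++i) {
      double mean = shsum[shell[i] - 1] / shcnt[shell[i] - 1];
      e2[i] = (mean > 0) ? I[i] / mean - 1.0 : 0.0;
      mc += e2[i];
    }
    mc /= n;
    double vc = 0.0, cv = 0.0;
    for (int i = 0; i < n; ++i) {
      double dc = e2[i] - mc;
      vc += dc * dc;
      cv += dc * (eobs[i] - mo);
    }
    out[kk] = (vc > 0 && vo > 0) ? cv / std::sqrt(vc * vo) : 0.0;
  }
  return out;
}

// Partial structure factors per symmetry operator, translation factored
// out:  F(h; t) = sum_s G[i, s] * exp(2 pi i (hR_s).t), where
// G[i, s] = exp(2 pi i h.tau_s) * sum_j c_j exp(2 pi i h.(R_s x_j)).
// [[Rcpp::export]]
List cpp_sym_partials(const NumericMatrix& hkl, const NumericVector& s,
                      const NumericMatrix& frac, const NumericVector& occ,
                      const NumericVector& bfac, const IntegerVector& fidx,
                      const NumericMatrix& fa, const NumericMatrix& fb,
                      const List& symR, const List& symT) {
  const int n = hkl.nrow(), m = frac.nrow(), ns = symR.size();
  ComplexMatrix G(n, ns);
  NumericMatrix hR(n, 3 * ns);
  std::vector<double> coef(m);
  std::vector<double> cs(n);
  for (int i = 0; i < n; ++i) cs[i] = s[i];
  for (int k = 0; k < ns; ++k) {
    NumericMatrix R = symR[k];
    NumericVector t = symT[k];
    std::vector<double> px(m), py(m), pz(m);
    for (int j = 0; j < m; ++j) {
      double x = frac(j, 0), y = frac(j, 1), z = frac(j, 2);
      px[j] = R(0, 0) * x + R(0, 1) * y + R(0, 2) * z;
      py[j] = R(1, 0) * x + R(1, 1) * y + R(1, 2) * z;
      pz[j] = R(2, 0) * x + R(2, 1) * y + R(2, 2) * z;
    }
    for (int i = 0; i < n; ++i) {
      atomCoefs(occ, bfac, fidx, fa, fb, cs[i], coef.data());
      double h = hkl(i, 0), kv = hkl(i, 1), l = hkl(i, 2);
      double re = 0.0, im = 0.0;
      for (int j = 0; j < m; ++j) {
        double arg = TWOPI * (h * px[j] + kv * py[j] + l * pz[j]);
        re += coef[j] * std::cos(arg);
        im += coef[j] * std::sin(arg);
      }
      double ph = TWOPI * (h * t[0] + kv * t[1] + l * t[2]);
      double cp = std::cos(ph), sp = std::sin(ph);
      G(i, k).r = re * cp - im * sp;
      G(i, k).i = re * sp + im * cp;
      // h R_s (row-vector convention)
      hR(i, 3 * k + 0) = h * R(0, 0) + kv * R(1, 0) + l * R(2, 0);
      hR(i, 3 * k + 1) = h * R(0, 1) + kv * R(1, 1) + l * R(2, 1);
      hR(i, 3 * k + 2) = h * R(0, 2) + kv * R(1, 2) + l * R(2, 2);
    }
  }
  return List::create(Named("G") = G, Named("hR") = hR);
}

// Translation scan: Pearson correlation of |F(t)| with fobs over a grid.
// [[Rcpp::export]]
NumericVector cpp_translation_scan(const ComplexMatrix& G,
                                   const NumericMatrix& hR,
                                   const NumericMatrix& tgrid,
                                   const NumericVector& fobs) {
  const int n = G.nrow(), ns = G.ncol(), T = tgrid.nrow();
  double mo = 0.0, vo = 0.0;
  for (int i = 0; i < n; ++i) mo += fobs[i];
  mo /= n;
  for (int i = 0; i < n; ++i) vo += (fobs[i] - mo) * (fobs[i] - mo);
  NumericVector out(T);
  std::vector<double> fc(n);
  for (int tt = 0; tt < T; ++tt) {
    double tx = tgrid(tt, 0), ty = tgrid(tt, 1), tz = tgrid(tt, 2);
    for (int i = 0; i < n; ++i) {
      double re = 0.0, im = 0.0;
      for (int k = 0; k < ns; ++k) {
        double arg = TWOPI * (hR(i, 3 * k) * tx + hR(i, 3 * k + 1) * ty +
                              hR(i, 3 * k + 2) * tz);
        double cp = std::cos(arg), sp = std::sin(arg);
        re += G(i, k).r * cp - G(i, k).i * sp;
        im += G(i, k).r * sp + G(i, k).i * cp;
      }
      fc[i] = std::sqrt(re * re + im * im);
    }
    double mc = 0.0;
    for (int i = 0; i < n; ++i) mc += fc[i];
    mc /= n;
    double vc = 0.0, cv = 0.0;
    for (int i = 0; i < n; ++i) {
      double dc = fc[i] - mc;
      vc += dc * dc;
      cv += dc * (fobs[i] - mo);
    }
    out[tt] = (vc > 0 && vo > 0) ? cv / std::sqrt(vc * vo) : 0.0;
  }
  return out;
}
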