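#include <Rcpp.h>
using namespace Rcpp;

// All kernels take memberships u in [0,1] and intensities I in [0,1] as
// dense matrices, plus the disc footprint as a k x 2 matrix of 0-based
// (dy, dx) offsets.  Patches are clipped to the image: sums run over
// in-image pixels only, so a zero-padded convolution and these loops agree.

static const double DEGEN_TOL = 1e-12;

// u^m with a guard for tiny negative rounding residue; matches R's `^`
// (R special-cases integer-valued exponents the same way libm pow does).
static inline double powm(double x, double m) {
  if (x <= 0.0) return 0.0;
  if (m == 2.0) return x * x;
  if (m == 1.0) return x;
  return std::pow(x, m);
}

static inline double sq(double x) { return x * x; }

// Membership candidate u_n = 1 / (1 + (l1 (I0-c1)^2 / (l2 (I0-c2)^2))^(1/(m-1)))
// with the zero-distance limits made explicit.
static inline double candidate(double I0, double c1, double c2,
                               double m, double l1, double l2) {
  double d1 = l1 * sq(I0 - c1), d2 = l2 * sq(I0 - c2);
  if (d1 == 0.0 && d2 == 0.0) return 0.5;
  if (d1 == 0.0) return 1.0;
  if (d2 == 0.0) return 0.0;
  double ratio = std::pow(d1 / d2, 1.0 / (m - 1.0));
  if (!std::isfinite(ratio)) return 0.0;
  return 1.0 / (1.0 + ratio);
}

// Per-patch statistics at every pixel:
//   s1(x) = sum_y W(x,y) u(y)^m          s2(x) = sum_y W(x,y) (1-u(y))^m
//   c1(x) = sum_y W(x,y) u(y)^m I(y) / s1(x)   (analogously c2)
// Empty-class patches (s = 0) fall back to the unweighted patch mean.
// [[Rcpp::export]]
List local_stats_cpp(const NumericMatrix I, const NumericMatrix u,
                     const IntegerMatrix off, double m) {
  int nr = I.nrow(), nc = I.ncol(), k = off.nrow();
  NumericMatrix s1(nr, nc), s2(nr, nc), c1(nr, nc), c2(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double a1 = 0, a2 = 0, b1 = 0, b2 = 0, sumI = 0;
      int cnt = 0;
      for (int t = 0; t < k; ++t) {
        int y = i + off(t, 0), x = j + off(t, 1);
        if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
        double uy = u(y, x), Iy = I(y, x);
        double um = powm(uy, m), vm = powm(1.0 - uy, m);
        a1 += um; b1 += um * Iy;
        a2 += vm; b2 += vm * Iy;
        sumI += Iy; ++cnt;
      }
      double pmean = cnt > 0 ? sumI / cnt : 0.0;
      s1(i, j) = a1; s2(i, j) = a2;
      c1(i, j) = a1 > 0 ? b1 / a1 : pmean;
      c2(i, j) = a2 > 0 ? b2 / a2 : pmean;
    }
  }
  return List::create(_["s1"] = s1, _["s2"] = s2,
                      _["c1"] = c1, _["c2"] = c2);
}

// Total localized energy, direct evaluation:
//   F = sum_x sum_y W(x,y) [ u(y)^m (I(y)-c1(x))^2 + (1-u(y))^m (I(y)-c2(x))^2 ]
// [[Rcpp::export]]
double total_energy_cpp(const NumericMatrix I, const NumericMatrix u,
                        const NumericMatrix c1, const NumericMatrix c2,
                        const IntegerMatrix off, double m) {
  int nr = I.nrow(), nc = I.ncol(), k = off.nrow();
  double F = 0.0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double f1 = 0, f2 = 0, C1 = c1(i, j), C2 = c2(i, j);
      for (int t = 0; t < k; ++t) {
        int y = i + off(t, 0), x = j + off(t, 1);
        if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
        double uy = u(y, x), Iy = I(y, x);
        f1 += powm(uy, m) * sq(Iy - C1);
        f2 += powm(1.0 - uy, m) * sq(Iy - C2);
      }
      F += f1 + f2;
    }
  }
  return F;
}

// Recompute one patch's statistics from scratch, with u(pi,pj) overridden by
// uP when pi >= 0.  Used for degenerate patches (an incremental denominator
// that is not safely positive) and for resynchronization.
static void patch_stats(const NumericMatrix& I, const NumericMatrix& u,
                        const IntegerMatrix& off, double m,
                        int ci, int cj, int pi, int pj, double uP,
                        double& s1, double& s2, double& c1, double& c2) {
  int nr = I.nrow(), nc = I.ncol(), k = off.nrow();
  double a1 = 0, a2 = 0, b1 = 0, b2 = 0, sumI = 0;
  int cnt = 0;
  for (int t = 0; t < k; ++t) {
    int y = ci + off(t, 0), x = cj + off(t, 1);
    if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
    double uy = (y == pi && x == pj) ? uP : u(y, x);
    double Iy = I(y, x);
    double um = powm(uy, m), vm = powm(1.0 - uy, m);
    a1 += um; b1 += um * Iy;
    a2 += vm; b2 += vm * Iy;
    sumI += Iy; ++cnt;
  }
  double pmean = cnt > 0 ? sumI / cnt : 0.0;
  s1 = a1; s2 = a2;
  c1 = a1 > 0 ? b1 / a1 : pmean;
  c2 = a2 > 0 ? b2 / a2 : pmean;
}

// One patch's energy contribution with given prototypes and optional
// membership override at (pi,pj).
static double patch_energy(const NumericMatrix& I, const NumericMatrix& u,
                           const IntegerMatrix& off, double m,
                           int ci, int cj, int pi, int pj, double uP,
                           double c1, double c2) {
  int nr = I.nrow(), nc = I.ncol(), k = off.nrow();
  double f = 0.0;
  for (int t = 0; t < k; ++t) {
    int y = ci + off(t, 0), x = cj + off(t, 1);
    if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
    double uy = (y == pi && x == pj) ? uP : u(y, x);
    double Iy = I(y, x);
    f += powm(uy, m) * sq(Iy - c1) + powm(1.0 - uy, m) * sq(Iy - c2);
  }
  return f;
}

// Closed-form energy change for a single membership change u0 -> un at P,
// summed over exactly the patch centers whose footprint contains P:
//   dF = sum_x [ s1 du1/(s1+du1) (I0-c1(x))^2 + s2 du2/(s2+du2) (I0-c2(x))^2 ]
// with du1 = un^m - u0^m, du2 = (1-un)^m - (1-u0)^m.  Degenerate centers
// (denominator <= tol) are evaluated directly from the membership field.
// [[Rcpp::export]]
List energy_change_cpp(const NumericMatrix I, const NumericMatrix u,
                       const NumericMatrix s1, const NumericMatrix s2,
                       const NumericMatrix c1, const NumericMatrix c2,
                       const IntegerMatrix off, double m,
                       int pi, int pj, double un) {
  int nr = I.nrow(), nc = I.ncol(), k = off.nrow();
  double I0 = I(pi, pj), u0 = u(pi, pj);
  double du1 = powm(un, m) - powm(u0, m);
  double du2 = powm(1.0 - un, m) - powm(1.0 - u0, m);
  double dF = 0.0;
  int n_degen = 0;
  std::vector<int> ci_v, cj_v;
  std::vector<double> ns1, ns2, nc1, nc2;
  ci_v.reserve(k); cj_v.reserve(k);
  for (int t = 0; t < k; ++t) {
    // the centers whose patch contains P are P + (symmetric) footprint
    int y = pi + off(t, 0), x = pj + off(t, 1);
    if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
    double S1 = s1(y, x), S2 = s2(y, x), C1 = c1(y, x), C2 = c2(y, x);
    double d1 = S1 + du1, d2 = S2 + du2;
    double t1, t2, t3, t4;
    if (d1 <= DEGEN_TOL || d2 <= DEGEN_TOL) {
      // direct fallback: recompute this patch before/after the change
      ++n_degen;
      double e_old = patch_energy(I, u, off, m, y, x, -1, -1, 0.0, C1, C2);
      patch_stats(I, u, off, m, y, x, pi, pj, un, t1, t2, t3, t4);
      dF += patch_energy(I, u, off, m, y, x, pi, pj, un, t3, t4) - e_old;
    } else {
      dF += S1 * du1 / d1 * sq(I0 - C1) + S2 * du2 / d2 * sq(I0 - C2);
      t1 = d1; t2 = d2;
      t3 = C1 + du1 / d1 * (I0 - C1);
      t4 = C2 + du2 / d2 * (I0 - C2);
    }
    ci_v.push_back(y + 1); cj_v.push_back(x + 1);
    ns1.push_back(t1); ns2.push_back(t2);
    nc1.push_back(t3); nc2.push_back(t4);
  }
  return List::create(_["delta_f"] = dF,
                      _["center_row"] = wrap(ci_v), _["center_col"] = wrap(cj_v),
                      _["s1"] = wrap(ns1), _["s2"] = wrap(ns2),
                      _["c1"] = wrap(nc1), _["c2"] = wrap(nc2),
                      _["n_degenerate"] = n_degen);
}

// One narrow-band sweep of the localized model.  Band pixels are visited in
// the given order; each candidate is accepted iff dF < 0, and on acceptance
// the statistics of every patch containing the pixel are updated immediately
// (Gauss-Seidel style), so later candidates in the same sweep see them.
// Inputs are modified in place; the R wrapper passes fresh copies.
// [[Rcpp::export]]
List sweep_cpp(const NumericMatrix I, NumericMatrix u,
               NumericMatrix s1, NumericMatrix s2,
               NumericMatrix c1, NumericMatrix c2,
               const IntegerMatrix band, const IntegerMatrix off, double m) {
  int nr = I.nrow(), nc = I.ncol(), k = off.nrow(), nb = band.nrow();
  int accepted = 0;
  long n_degen = 0;
  double dtot = 0.0;
  for (int b = 0; b < nb; ++b) {
    int pi = band(b, 0), pj = band(b, 1);
    double I0 = I(pi, pj), u0 = u(pi, pj);
    double un = candidate(I0, c1(pi, pj), c2(pi, pj), m, 1.0, 1.0);
    if (un == u0) continue;
    double du1 = powm(un, m) - powm(u0, m);
    double du2 = powm(1.0 - un, m) - powm(1.0 - u0, m);
    if (du1 == 0.0 && du2 == 0.0) continue;
    double dF = 0.0;
    for (int t = 0; t < k; ++t) {
      int y = pi + off(t, 0), x = pj + off(t, 1);
      if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
      double S1 = s1(y, x), S2 = s2(y, x);
      double d1 = S1 + du1, d2 = S2 + du2;
      if (d1 <= DEGEN_TOL || d2 <= DEGEN_TOL) {
        ++n_degen;
        double e_old = patch_energy(I, u, off, m, y, x, -1, -1, 0.0,
                                    c1(y, x), c2(y, x));
        double t1, t2, t3, t4;
        patch_stats(I, u, off, m, y, x, pi, pj, un, t1, t2, t3, t4);
        dF += patch_energy(I, u, off, m, y, x, pi, pj, un, t3, t4) - e_old;
      } else {
        dF += S1 * du1 / d1 * sq(I0 - c1(y, x)) +
              S2 * du2 / d2 * sq(I0 - c2(y, x));
      }
    }
    if (dF < 0.0) {
      for (int t = 0; t < k; ++t) {
        int y = pi + off(t, 0), x = pj + off(t, 1);
        if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
        double d1 = s1(y, x) + du1, d2 = s2(y, x) + du2;
        if (d1 <= DEGEN_TOL || d2 <= DEGEN_TOL) {
          double t1, t2, t3, t4;
          patch_stats(I, u, off, m, y, x, pi, pj, un, t1, t2, t3, t4);
          s1(y, x) = t1; s2(y, x) = t2; c1(y, x) = t3; c2(y, x) = t4;
        } else {
          c1(y, x) += du1 / d1 * (I0 - c1(y, x));
          c2(y, x) += du2 / d2 * (I0 - c2(y, x));
          s1(y, x) = d1; s2(y, x) = d2;
        }
      }
      u(pi, pj) = un;
      ++accepted;
      dtot += dF;
    }
  }
  return List::create(_["u"] = u, _["s1"] = s1, _["s2"] = s2,
                      _["c1"] = c1, _["c2"] = c2,
                      _["accepted"] = accepted, _["delta_f"] = dtot,
                      _["n_degenerate"] = (double)n_degen);
}

// Count of 4-neighbor edges whose endpoints straddle the 0.5 threshold; the
// discrete contour-length surrogate used by the FEAC baseline's mu term.
// [[Rcpp::export]]
double perimeter_cpp(const NumericMatrix u) {
  int nr = u.nrow(), nc = u.ncol();
  double p = 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      bool b = u(i, j) > 0.5;
      if (i + 1 < nr && b != (u(i + 1, j) > 0.5)) ++p;
      if (j + 1 < nc && b != (u(i, j + 1) > 0.5)) ++p;
    }
  return p;
}

// One narrow-band sweep of the global FEAC baseline: a single pair of
// whole-image prototypes, the same closed-form dF with scalar s1/s2, class
// weights lambda1/lambda2, and an optional mu * perimeter term recounted
// locally over the 4 edges at the changed pixel.  A change that would empty
// one class (denominator <= tol) is skipped.
// [[Rcpp::export]]
List feac_sweep_cpp(const NumericMatrix I, NumericMatrix u,
                    double s1, double s2, double c1, double c2,
                    const IntegerMatrix band, double m,
                    double lambda1, double lambda2, double mu) {
  int nr = I.nrow(), nc = I.ncol(), nb = band.nrow();
  int accepted = 0;
  double dtot = 0.0;
  static const int di[4] = {-1, 1, 0, 0};
  static const int dj[4] = {0, 0, -1, 1};
  for (int b = 0; b < nb; ++b) {
    int pi = band(b, 0), pj = band(b, 1);
    double I0 = I(pi, pj), u0 = u(pi, pj);
    double un = candidate(I0, c1, c2, m, lambda1, lambda2);
    if (un == u0) continue;
    double du1 = powm(un, m) - powm(u0, m);
    double du2 = powm(1.0 - un, m) - powm(1.0 - u0, m);
    if (du1 == 0.0 && du2 == 0.0) continue;
    double d1 = s1 + du1, d2 = s2 + du2;
    if (d1 <= DEGEN_TOL || d2 <= DEGEN_TOL) continue;
    double dF = lambda1 * s1 * du1 / d1 * sq(I0 - c1) +
                lambda2 * s2 * du2 / d2 * sq(I0 - c2);
    if (mu > 0.0 && (un > 0.5) != (u0 > 0.5)) {
      double dperim = 0.0;
      bool b_old = u0 > 0.5, b_new = un > 0.5;
      for (int q = 0; q < 4; ++q) {
        int y = pi + di[q], x = pj + dj[q];
        if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
        bool bq = u(y, x) > 0.5;
        dperim += (double)(b_new != bq) - (double)(b_old != bq);
      }
      dF += mu * dperim;
    }
    if (dF < 0.0) {
      c1 += du1 / d1 * (I0 - c1);
      c2 += du2 / d2 * (I0 - c2);
      s1 = d1; s2 = d2;
      u(pi, pj) = un;
      ++accepted;
      dtot += dF;
    }
  }
  return List::create(_["u"] = u, _["s1"] = s1, _["s2"] = s2,
                      _["c1"] = c1, _["c2"] = c2,
                      _["accepted"] = accepted, _["delta_f"] = dtot);
}
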