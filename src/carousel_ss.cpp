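// Fast steady-state kernel for the simplified carousel model.
//
// Species order (matches the R network):
//   0 R, 1 LR, 2 RG, 3 LRG, 4 RGt, 5 LRGt, 6 RGd, 7 LRGd,
//   8 G, 9 Gt, 10 Gd, 11 Gbg
// Rate vector k:
//   0 kon_LR, 1 koff_LR, 2 kon_RG, 3 koff_RG, 4 kA_Gd, 5 koff_GdGbg,
//   6 kE_G, 7 kE_RG, 8 kE_LRG, 9 kH_Gt, 10 kH_RGt, 11 kH_LRGt
//
// The solver is a damped pseudo-transient continuation (implicit Euler with
// a growing step) that turns into full Newton as the step grows, applied to
// the conservation-constrained system: the rate equations of R, G and Gbg
// are replaced by the three conservation laws, which removes the rank
// deficiency of the stoichiometry and pins the totals exactly.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int NS = 12;

// rhs f, absolute-turnover vector gross (sum of |flux| contributions per
// species), and Jacobian J (optional)
static void carousel_f(const double* k, const double* x, double L,
                       double* f, double* gross, double (*J)[NS]) {
  const double konLR = k[0], koffLR = k[1], konRG = k[2], koffRG = k[3],
               kAGd = k[4], koffGG = k[5], kEG = k[6], kERG = k[7],
               kELRG = k[8], kHGt = k[9], kHRGt = k[10], kHLRGt = k[11];

  // forward/backward parts of the 19 reactions
  double vf[19], vb[19];
  vf[0] = konLR * L * x[0];  vb[0] = koffLR * x[1];   // L+R = LR
  vf[1] = konLR * L * x[2];  vb[1] = koffLR * x[3];   // L+RG = LRG
  vf[2] = konLR * L * x[4];  vb[2] = koffLR * x[5];   // L+RGt = LRGt
  vf[3] = konLR * L * x[6];  vb[3] = koffLR * x[7];   // L+RGd = LRGd
  vf[4] = konRG * x[0] * x[8];  vb[4] = koffRG * x[2];   // R+G = RG
  vf[5] = konRG * x[1] * x[8];  vb[5] = koffRG * x[3];   // LR+G = LRG
  vf[6] = konRG * x[0] * x[9];  vb[6] = koffRG * x[4];   // R+Gt = RGt
  vf[7] = konRG * x[1] * x[9];  vb[7] = koffRG * x[5];   // LR+Gt = LRGt
  vf[8] = konRG * x[0] * x[10]; vb[8] = koffRG * x[6];   // R+Gd = RGd
  vf[9] = konRG * x[1] * x[10]; vb[9] = koffRG * x[7];   // LR+Gd = LRGd
  vf[10] = kEG * x[8];    vb[10] = 0.0;                  // G -> Gt+Gbg
  vf[11] = kERG * x[2];   vb[11] = 0.0;                  // RG -> RGt+Gbg
  vf[12] = kELRG * x[3];  vb[12] = 0.0;                  // LRG -> LRGt+Gbg
  vf[13] = kHGt * x[9];   vb[13] = 0.0;                  // Gt -> Gd
  vf[14] = kHRGt * x[4];  vb[14] = 0.0;                  // RGt -> RGd
  vf[15] = kHLRGt * x[5]; vb[15] = 0.0;                  // LRGt -> LRGd
  vf[16] = kAGd * x[10] * x[11]; vb[16] = koffGG * x[8]; // Gd+Gbg = G
  vf[17] = kAGd * x[6] * x[11];  vb[17] = koffGG * x[2]; // RGd+Gbg = RG
  vf[18] = kAGd * x[7] * x[11];  vb[18] = koffGG * x[3]; // LRGd+Gbg = LRG

  double v[19];
  for (int j = 0; j < 19; ++j) v[j] = vf[j] - vb[j];

  f[0] = -v[0] - v[4] - v[6] - v[8];
  f[1] = v[0] - v[5] - v[7] - v[9];
  f[2] = v[4] - v[1] - v[11] + v[17];
  f[3] = v[1] + v[5] - v[12] + v[18];
  f[4] = v[6] - v[2] + v[11] - v[14];
  f[5] = v[2] + v[7] + v[12] - v[15];
  f[6] = v[8] - v[3] + v[14] - v[17];
  f[7] = v[3] + v[9] + v[15] - v[18];
  f[8] = -v[4] - v[5] - v[10] + v[16];
  f[9] = v[10] - v[13] - v[6] - v[7];
  f[10] = v[13] - v[8] - v[9] - v[16];
  f[11] = v[10] + v[11] + v[12] - v[16] - v[17] - v[18];

  if (gross) {
    // same stoichiometry with |forward| + |backward| per reaction
    double a[19];
    for (int j = 0; j < 19; ++j) a[j] = std::abs(vf[j]) + std::abs(vb[j]);
    gross[0] = a[0] + a[4] + a[6] + a[8];
    gross[1] = a[0] + a[5] + a[7] + a[9];
    gross[2] = a[4] + a[1] + a[11] + a[17];
    gross[3] = a[1] + a[5] + a[12] + a[18];
    gross[4] = a[6] + a[2] + a[11] + a[14];
    gross[5] = a[2] + a[7] + a[12] + a[15];
    gross[6] = a[8] + a[3] + a[14] + a[17];
    gross[7] = a[3] + a[9] + a[15] + a[18];
    gross[8] = a[4] + a[5] + a[10] + a[16];
    gross[9] = a[10] + a[13] + a[6] + a[7];
    gross[10] = a[13] + a[8] + a[9] + a[16];
    gross[11] = a[10] + a[11] + a[12] + a[16] + a[17] + a[18];
  }

  if (J) {
    for (int i = 0; i < NS; ++i)
      for (int j = 0; j < NS; ++j) J[i][j] = 0.0;
    // d v[j] / d x[i] assembled reaction by reaction:
    // affected species, their stoichiometric signs, forward reactants and
    // the (single) reverse reactant of each of the 19 reactions
    static const int nsp[19] = {2,2,2,2,3,3,3,3,3,3,3,3,3,2,2,2,3,3,3};
    static const int spc[19][3] = {
      {0,1,-1},{2,3,-1},{4,5,-1},{6,7,-1},
      {0,8,2},{1,8,3},{0,9,4},{1,9,5},{0,10,6},{1,10,7},
      {8,9,11},{2,4,11},{3,5,11},
      {9,10,-1},{4,6,-1},{5,7,-1},
      {10,11,8},{6,11,2},{7,11,3}
    };
    static const int sgn[19][3] = {
      {-1,1,0},{-1,1,0},{-1,1,0},{-1,1,0},
      {-1,-1,1},{-1,-1,1},{-1,-1,1},{-1,-1,1},{-1,-1,1},{-1,-1,1},
      {-1,1,1},{-1,1,1},{-1,1,1},
      {-1,1,0},{-1,1,0},{-1,1,0},
      {-1,-1,1},{-1,-1,1},{-1,-1,1}
    };
    // forward reactant indices per reaction (up to 2), -1 = none
    static const int fr[19][2] = {
      {0,-1},{2,-1},{4,-1},{6,-1},
      {0,8},{1,8},{0,9},{1,9},{0,10},{1,10},
      {8,-1},{2,-1},{3,-1},
      {9,-1},{4,-1},{5,-1},
      {10,11},{6,11},{7,11}
    };
    // reverse reactant index per reaction (-1 = irreversible)
    static const int rr[19] = {1,3,5,7,2,3,4,5,6,7,-1,-1,-1,-1,-1,-1,8,2,3};
    const double kfv[19] = {konLR*L, konLR*L, konLR*L, konLR*L,
                            konRG, konRG, konRG, konRG, konRG, konRG,
                            kEG, kERG, kELRG, kHGt, kHRGt, kHLRGt,
                            kAGd, kAGd, kAGd};
    const double krv[19] = {koffLR, koffLR, koffLR, koffLR,
                            koffRG, koffRG, koffRG, koffRG, koffRG, koffRG,
                            0, 0, 0, 0, 0, 0, koffGG, koffGG, koffGG};
    for (int j = 0; j < 19; ++j) {
      // forward part derivatives
      for (int m = 0; m < 2; ++m) {
        int i = fr[j][m];
        if (i < 0) continue;
        int other = fr[j][1 - m];
        double dv = kfv[j] * (other >= 0 ? x[other] : 1.0);
        for (int s = 0; s < nsp[j]; ++s) {
          J[spc[j][s]][i] += sgn[j][s] * dv;
        }
      }
      // backward part derivative (single reverse reactant here)
      if (rr[j] >= 0 && krv[j] > 0) {
        for (int s = 0; s < nsp[j]; ++s) {
          J[spc[j][s]][rr[j]] -= sgn[j][s] * krv[j];
        }
      }
    }
  }
}

// Row-equilibrated partial-pivot LU solve of an NS x NS system, in place.
// Returns false when (numerically) singular. Much faster than a LAPACK
// round trip at this size, and this solve is the inner-loop hot spot.
static bool lu_solve(double A[NS][NS], double b[NS], double x[NS]) {
  int piv[NS];
  // equilibrate rows
  for (int i = 0; i < NS; ++i) {
    double m = 0.0;
    for (int j = 0; j < NS; ++j) m = std::max(m, std::abs(A[i][j]));
    if (m == 0.0) return false;
    double s = 1.0 / m;
    for (int j = 0; j < NS; ++j) A[i][j] *= s;
    b[i] *= s;
    piv[i] = i;
  }
  for (int c = 0; c < NS; ++c) {
    int p = c;
    double m = std::abs(A[piv[c]][c]);
    for (int r = c + 1; r < NS; ++r) {
      double v = std::abs(A[piv[r]][c]);
      if (v > m) { m = v; p = r; }
    }
    if (m < 1e-300) return false;
    std::swap(piv[c], piv[p]);
    const double d = 1.0 / A[piv[c]][c];
    for (int r = c + 1; r < NS; ++r) {
      double f = A[piv[r]][c] * d;
      if (f == 0.0) continue;
      A[piv[r]][c] = 0.0;
      for (int j = c + 1; j < NS; ++j) A[piv[r]][j] -= f * A[piv[c]][j];
      b[piv[r]] -= f * b[piv[c]];
    }
  }
  for (int c = NS - 1; c >= 0; --c) {
    double s = b[piv[c]];
    for (int j = c + 1; j < NS; ++j) s -= A[piv[c]][j] * x[j];
    x[c] = s / A[piv[c]][c];
  }
  return true;
}

// residuals: conc-scaled (spec definition) and turnover-scaled
static void residuals(const double* f, const double* x, const double* gross,
                      double* res_conc, double* res_turn) {
  double rc = 0.0, rt = 0.0;
  for (int i = 0; i < NS; ++i) {
    double sc = x[i] > 1e-12 ? x[i] : 1e-12;
    double a = std::abs(f[i]);
    if (a / sc > rc) rc = a / sc;
    double g = gross[i] + 1e-300;
    if (a / g > rt) rt = a / g;
  }
  *res_conc = rc;
  *res_turn = rt;
}

// one solve; x is in/out. returns true on convergence.
static bool solve_point(const double* k, double Rtot, double Gtot, double L,
                        double* x, double tol, int maxit,
                        double* res_out, int* iters) {
  double J[NS][NS], B[NS][NS];
  double rhs[NS], dx[NS];
  double f[NS], gross[NS];

  // characteristic first-order rate for the initial pseudo-time step
  double conc = std::max(1.0, std::max(Rtot, Gtot));
  double kmax = std::max({k[1], k[3], k[5], k[6], k[7], k[8], k[9], k[10],
                          k[11], k[0] * std::max(L, 1.0), k[2] * conc,
                          k[4] * conc});
  double dt = 0.1 / kmax;
  const double dtmax = 1e18 / kmax;

  carousel_f(k, x, L, f, gross, nullptr);
  double rc, rt;
  residuals(f, x, gross, &rc, &rt);

  for (int it = 0; it < maxit; ++it) {
    if (rc <= tol || rt <= 1e-11) {
      *res_out = rc; *iters = it;
      return true;
    }
    carousel_f(k, x, L, f, gross, J);
    // constrained implicit-Euler/Newton matrix
    for (int i = 0; i < NS; ++i) {
      for (int j = 0; j < NS; ++j) B[i][j] = -J[i][j];
      rhs[i] = f[i];
    }
    for (int i = 0; i < NS; ++i) {
      if (i == 0 || i == 8 || i == 11) continue;
      B[i][i] += 1.0 / dt;
    }
    // receptor conservation replaces row 0
    for (int j = 0; j < NS; ++j) B[0][j] = (j < 8) ? 1.0 : 0.0;
    double rsum = 0; for (int i = 0; i < 8; ++i) rsum += x[i];
    rhs[0] = Rtot - rsum;
    // Galpha conservation replaces row 8
    for (int j = 0; j < NS; ++j) B[8][j] = (j >= 2 && j <= 10) ? 1.0 : 0.0;
    double gsum = 0; for (int i = 2; i <= 10; ++i) gsum += x[i];
    rhs[8] = Gtot - gsum;
    // Gbetagamma conservation replaces row 11
    for (int j = 0; j < NS; ++j) B[11][j] = 0.0;
    B[11][2] = B[11][3] = B[11][8] = B[11][11] = 1.0;
    rhs[11] = Gtot - (x[2] + x[3] + x[8] + x[11]);

    bool ok = lu_solve(B, rhs, dx);
    if (ok) {
      for (int i = 0; i < NS; ++i) {
        if (!std::isfinite(dx[i])) { ok = false; break; }
      }
    }
    if (!ok) {
      dt *= 0.2;
      if (dt < 1e-30 / kmax) break;
      continue;
    }
    double xn[NS];
    for (int i = 0; i < NS; ++i) {
      xn[i] = x[i] + dx[i];
      if (xn[i] < 0) xn[i] = 0;
    }
    carousel_f(k, xn, L, f, gross, nullptr);
    double rcn, rtn;
    residuals(f, xn, gross, &rcn, &rtn);
    if (!std::isfinite(rcn) || !std::isfinite(rtn)) {
      dt *= 0.2;
      if (dt < 1e-30 / kmax) break;
      continue;
    }
    // conservation rows plus clipping keep iterates bounded, so steps are
    // always accepted; the pseudo-time step scales with the improvement
    // ratio of the (bounded) turnover residual, which is neutral to noise
    // near the fixed point
    double fac;
    if (rtn <= 0.3 * rt) {
      fac = 10.0;                     // strong progress: accelerate hard
    } else if (rtn <= rt) {
      fac = 3.0;                      // progressing (or tied): accelerate
    } else {
      fac = rt / rtn;                 // worsening: damp by the ratio
      if (fac < 0.3) fac = 0.3;
    }
    for (int i = 0; i < NS; ++i) x[i] = xn[i];
    rc = rcn; rt = rtn;
    dt = std::min(std::max(dt * fac, 1e-25 / kmax), dtmax);
  }
  carousel_f(k, x, L, f, gross, nullptr);
  residuals(f, x, gross, &rc, &rt);
  *res_out = rc; *iters = maxit;
  return (rc <= tol || rt <= 1e-11);
}

// [[Rcpp::export(name = ".css_rhs")]]
NumericVector css_rhs(NumericVector k, NumericVector x, double L) {
  double f[NS];
  carousel_f(REAL(k), REAL(x), L, f, nullptr, nullptr);
  return NumericVector(f, f + NS);
}

// [[Rcpp::export(name = ".css_solve")]]
List css_solve(NumericVector k, double Rtot, double Gtot, double L,
               NumericVector x0, double tol, int maxit) {
  double x[NS];
  for (int i = 0; i < NS; ++i) x[i] = x0[i];
  double res; int it;
  bool conv = solve_point(REAL(k), Rtot, Gtot, L, x, tol, maxit, &res, &it);
  return List::create(_["state"] = NumericVector(x, x + NS),
                      _["residual"] = res, _["converged"] = conv,
                      _["iterations"] = it);
}

// Solve a whole dose-response curve with warm starts along the grid.
// Lgrid must be sorted ascending; the first point starts from the naive
// unliganded state (all receptor free, all G as trimer).
// [[Rcpp::export(name = ".css_curve")]]
List css_curve(NumericVector k, double Rtot, double Gtot,
               NumericVector Lgrid, double tol, int maxit) {
  int nL = Lgrid.size();
  NumericMatrix states(NS, nL);
  NumericVector res(nL);
  LogicalVector conv(nL);
  double x[NS];
  for (int i = 0; i < NS; ++i) x[i] = 0.0;
  x[0] = Rtot; x[8] = Gtot;
  // pre-equilibrate at L = 0 (also the first grid point when grid includes 0)
  double r0; int it0;
  bool c0 = solve_point(REAL(k), Rtot, Gtot, 0.0, x, tol, maxit, &r0, &it0);
  if (!c0) {
    c0 = solve_point(REAL(k), Rtot, Gtot, 0.0, x, tol, 5 * maxit, &r0, &it0);
  }
  double xbase[NS];
  for (int i = 0; i < NS; ++i) xbase[i] = x[i];
  for (int j = 0; j < nL; ++j) {
    double L = Lgrid[j];
    if (L == 0.0) {
      for (int i = 0; i < NS; ++i) states(i, j) = xbase[i];
      res[j] = r0; conv[j] = c0;
      for (int i = 0; i < NS; ++i) x[i] = xbase[i];
      continue;
    }
    double r; int it;
    bool c = solve_point(REAL(k), Rtot, Gtot, L, x, tol, maxit, &r, &it);
    if (!c) {
      // continue from the partial solution with a larger budget
      c = solve_point(REAL(k), Rtot, Gtot, L, x, tol, 5 * maxit, &r, &it);
    }
    if (!c) {
      // last resort: restart from the naive state
      for (int i = 0; i < NS; ++i) x[i] = 0.0;
      x[0] = Rtot; x[8] = Gtot;
      c = solve_point(REAL(k), Rtot, Gtot, L, x, tol, 5 * maxit, &r, &it);
    }
    for (int i = 0; i < NS; ++i) states(i, j) = x[i];
    res[j] = r; conv[j] = c;
  }
  return List::create(_["states"] = states, _["residual"] = res,
                      _["converged"] = conv);
}
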