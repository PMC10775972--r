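#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama kernels for the six-species flowering network and for the
// 2-D quartic double-well toy used to validate the landscape/FPT machinery.
//
// Parameter vector order (keep in sync with .param_order in R/params.R):
//  0 a12, 1 a14, 2 a32, 3 a65, 4 a_svp,
//  5 bm, 6 bm21, 7 bm34, 8 bm43, 9 bm44, 10 bm54,
// 11 b, 12 b21, 13 b34, 14 b43, 15 b44, 16 b54,
// 17 k, 18 n, 19 S, 20 c, 21 svp, 22 co2, 23 D
//
// All kernels draw noise through R's RNG (norm_rand), so results are
// reproducible under set.seed() and the package's child-seed scheme.

static inline double hillA(double x, double a, double Sn, double n) {
  double xn = std::pow(x, n);
  return a * xn / (Sn + xn);
}
static inline double hillR(double x, double bm, double b, double Sn, double n) {
  double xn = std::pow(x, n);
  return bm * (1.0 - b + b * Sn / (Sn + xn));
}

static inline void drift6(const double* x, const double* p, double Sn,
                          double* f) {
  const double n = p[18], k = p[17];
  f[0] = hillA(x[1], p[0], Sn, n) + hillA(x[3], p[1], Sn, n)
       + hillR(p[20] * p[22], p[5], p[11], Sn, n) - k * x[0];
  f[1] = hillR(x[0], p[6], p[12], Sn, n) - k * x[1];
  f[2] = hillA(x[1], p[2], Sn, n) + hillR(x[3], p[7], p[13], Sn, n)
       + hillA(p[21], p[4], Sn, n) - k * x[2];
  f[3] = hillR(x[3], p[9], p[15], Sn, n) + hillR(x[2], p[8], p[14], Sn, n)
       - k * x[3];
  f[4] = hillR(x[3], p[10], p[16], Sn, n) - k * x[4];
  f[5] = hillA(x[4], p[3], Sn, n) - k * x[5];
}

// [[Rcpp::export]]
NumericVector drift_cpp(NumericVector x, NumericVector par) {
  NumericVector f(6);
  double Sn = std::pow(par[19], par[18]);
  drift6(REAL(x), par.begin(), Sn, REAL(f));
  return f;
}

// One trajectory; returns states thinned to every `thin`-th step (row 0 is
// the initial state). Negative components are reflected at 0.
// [[Rcpp::export]]
NumericMatrix sim_path_cpp(NumericVector par, NumericVector x0, double T,
                           double dt, int thin) {
  double Sn = std::pow(par[19], par[18]);
  double sq = std::sqrt(2.0 * par[23] * dt);
  long nstep = (long)std::floor(T / dt + 1e-9);
  long nkeep = nstep / thin + 1;
  NumericMatrix out(nkeep, 6);
  double x[6], f[6];
  for (int j = 0; j < 6; ++j) { x[j] = x0[j]; out(0, j) = x[j]; }
  RNGScope scope;
  long row = 1;
  for (long s = 1; s <= nstep; ++s) {
    drift6(x, par.begin(), Sn, f);
    for (int j = 0; j < 6; ++j) {
      x[j] += f[j] * dt + sq * norm_rand();
      if (x[j] < 0.0) x[j] = -x[j];
      if (!R_finite(x[j]))
        stop("non-finite state at step %ld (component %d)", s, j + 1);
    }
    if (s % thin == 0 && row < nkeep) {
      for (int j = 0; j < 6; ++j) out(row, j) = x[j];
      ++row;
    }
  }
  return out;
}

// First-passage times of `n_traj` trajectories from x0 to the ball of radius
// r_abs around `target`, all drawn from the current RNG stream.
// [[Rcpp::export]]
List sim_fpt_cpp(NumericVector par, NumericVector x0, NumericVector target,
                 double r_abs, double dt, double tmax, int n_traj) {
  NumericVector times(n_traj);
  LogicalVector censored(n_traj);
  double Sn = std::pow(par[19], par[18]);
  double sq = std::sqrt(2.0 * par[23] * dt);
  double r2 = r_abs * r_abs;
  long nstep = (long)std::ceil(tmax / dt);
  double x[6], f[6];
  RNGScope scope;
  for (int i = 0; i < n_traj; ++i) {
    for (int j = 0; j < 6; ++j) x[j] = x0[j];
    bool hit = false;
    long s;
    for (s = 1; s <= nstep; ++s) {
      drift6(x, par.begin(), Sn, f);
      double d2 = 0.0;
      for (int j = 0; j < 6; ++j) {
        x[j] += f[j] * dt + sq * norm_rand();
        if (x[j] < 0.0) x[j] = -x[j];
        double dd = x[j] - target[j];
        d2 += dd * dd;
      }
      if (d2 < r2) { hit = true; break; }
    }
    if (hit) { times[i] = s * dt; censored[i] = false; }
    else { times[i] = tmax; censored[i] = true; }
  }
  return List::create(_["time"] = times, _["censored"] = censored);
}

// ---- 2-D quartic double-well toy -------------------------------------------
// V(x, y) = h * (x^2 - 1)^2 + tilt * x + 0.5 * ky * y^2, drift = -grad V.
static inline void drift_toy(const double* z, double h, double tilt, double ky,
                             double* f) {
  f[0] = -4.0 * h * z[0] * (z[0] * z[0] - 1.0) - tilt;
  f[1] = -ky * z[1];
}

// [[Rcpp::export]]
NumericMatrix toy_path_cpp(double h, double tilt, double ky, double D,
                           NumericVector z0, double T, double dt, int thin) {
  double sq = std::sqrt(2.0 * D * dt);
  long nstep = (long)std::floor(T / dt + 1e-9);
  long nkeep = nstep / thin + 1;
  NumericMatrix out(nkeep, 2);
  double z[2] = { z0[0], z0[1] }, f[2];
  out(0, 0) = z[0]; out(0, 1) = z[1];
  RNGScope scope;
  long row = 1;
  for (long s = 1; s <= nstep; ++s) {
    drift_toy(z, h, tilt, ky, f);
    z[0] += f[0] * dt + sq * norm_rand();
    z[1] += f[1] * dt + sq * norm_rand();
    if (s % thin == 0 && row < nkeep) {
      out(row, 0) = z[0]; out(row, 1) = z[1];
      ++row;
    }
  }
  return out;
}

// [[Rcpp::export]]
List toy_fpt_cpp(double h, double tilt, double ky, double D,
                 NumericVector z0, NumericVector target, double r_abs,
                 double dt, double tmax, int n_traj) {
  NumericVector times(n_traj);
  LogicalVector censored(n_traj);
  double sq = std::sqrt(2.0 * D * dt);
  double r2 = r_abs * r_abs;
  long nstep = (long)std::ceil(tmax / dt);
  double z[2], f[2];
  RNGScope scope;
  for (int i = 0; i < n_traj; ++i) {
    z[0] = z0[0]; z[1] = z0[1];
    bool hit = false;
    long s;
    for (s = 1; s <= nstep; ++s) {
      drift_toy(z, h, tilt, ky, f);
      z[0] += f[0] * dt + sq * norm_rand();
      z[1] += f[1] * dt + sq * norm_rand();
      double dx = z[0] - target[0], dy = z[1] - target[1];
      if (dx * dx + dy * dy < r2) { hit = true; break; }
    }
    if (hit) { times[i] = s * dt; censored[i] = false; }
    else { times[i] = tmax; censored[i] = true; }
  }
  return List::create(_["time"] = times, _["censored"] = censored);
}
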