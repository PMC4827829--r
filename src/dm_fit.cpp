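#include <Rcpp.h>
using namespace Rcpp;

// Angles live on [0, 2pi); differences are taken to (-pi, pi] before any
// trigonometric use so that tan(0.5 * diff) sits on the principal branch.

static const double TWOPI = 2.0 * M_PI;

static inline double wrap2pi(double x) {
  double w = x - TWOPI * std::floor(x / TWOPI);
  if (w >= TWOPI) w -= TWOPI;  // guard against rounding at the seam
  if (w < 0) w = 0;
  return w;
}

// wrap a difference to (-pi, pi]
static inline double wrap_pm_pi(double x) {
  double w = wrap2pi(x);
  if (w > M_PI) w -= TWOPI;
  return w;
}

// Downs-Mardia conditional mean direction: beta + 2 atan(omega tan((u - alpha)/2)).
// At the branch point u - alpha == pi the limit is beta + pi sign(omega)
// (beta itself when omega == 0).
static inline double dm_mu(double u, double alpha, double beta, double omega) {
  double w = wrap_pm_pi(u - alpha);
  if (w == M_PI) {
    if (omega == 0.0) return beta;
    return beta + (omega > 0 ? M_PI : -M_PI);
  }
  return beta + 2.0 * std::atan(omega * std::tan(0.5 * w));
}

// Mean cosine of the angular errors: the precision estimate rho(alpha, beta, omega).
static double rho_stat(const double* u, const double* v, int n,
                       double alpha, double beta, double omega) {
  double s = 0.0;
  for (int j = 0; j < n; ++j)
    s += std::cos(v[j] - dm_mu(u[j], alpha, beta, omega));
  return s / n;
}

// [[Rcpp::export]]
double dm_rho_cpp(NumericVector u, NumericVector v,
                  double alpha, double beta, double omega) {
  return rho_stat(u.begin(), v.begin(), u.size(), alpha, beta, omega);
}

// [[Rcpp::export]]
NumericVector dm_predict_cpp(NumericVector u, double alpha, double beta,
                             double omega) {
  int n = u.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) out[j] = wrap2pi(dm_mu(u[j], alpha, beta, omega));
  return out;
}

// Exhaustive search of rho over the lattice alpha in [-pi, pi) x beta in
// [-pi, pi) x omega in [-1, 1] \ {0}.  For fixed (alpha, omega) the sum
// factorises as C cos(beta) + S sin(beta) with C = sum cos(v - g),
// S = sum sin(v - g), so each beta costs O(1); the result is identical to
// the triple loop.  Ties at the maximum resolve to the lexicographically
// smallest (alpha, beta, omega).
// [[Rcpp::export]]
List dm_grid_cpp(NumericVector u, NumericVector v,
                 double alpha_step, double omega_step) {
  int n = u.size();
  int na = (int)std::floor((TWOPI - 1e-12) / alpha_step) + 1;
  int nw = (int)std::floor((2.0 + 1e-12) / omega_step) + 1;
  if (na < 1 || nw < 1) stop("degenerate lattice");

  std::vector<double> alphas(na), betas(na), omegas;
  for (int i = 0; i < na; ++i) alphas[i] = -M_PI + i * alpha_step;
  betas = alphas;
  omegas.reserve(nw);
  for (int k = 0; k < nw; ++k) {
    double w = -1.0 + k * omega_step;
    if (std::abs(w) > 1e-12) omegas.push_back(w);  // omega = 0 is degenerate
  }
  if (omegas.empty()) stop("degenerate lattice");

  double best = -2.0;
  double ba = 0, bb = 0, bw = 0;
  std::vector<double> h(n);
  int nb = (int)betas.size();
  for (int ia = 0; ia < na; ++ia) {
    double alpha = alphas[ia];
    for (int j = 0; j < n; ++j)
      h[j] = std::tan(0.5 * wrap_pm_pi(u[j] - alpha));  // branch hit -> +-inf, atan handles it
    for (size_t iw = 0; iw < omegas.size(); ++iw) {
      double omega = omegas[iw];
      double C = 0.0, S = 0.0;
      for (int j = 0; j < n; ++j) {
        double r = v[j] - 2.0 * std::atan(omega * h[j]);
        C += std::cos(r);
        S += std::sin(r);
      }
      for (int ib = 0; ib < nb; ++ib) {
        double rho = (C * std::cos(betas[ib]) + S * std::sin(betas[ib])) / n;
        bool take = rho > best;
        if (!take && rho == best) {
          // lexicographic (alpha, beta, omega) tie-break
          take = (alpha < ba) ||
                 (alpha == ba && (betas[ib] < bb ||
                                  (betas[ib] == bb && omega < bw)));
        }
        if (take) { best = rho; ba = alpha; bb = betas[ib]; bw = omega; }
      }
    }
  }
  return List::create(_["alpha"] = ba, _["beta"] = bb, _["omega"] = bw,
                      _["rho"] = best);
}

// Objective for the fitter: -rho, with the slope kept inside [-1, 1] by a
// linear penalty on the excursion (the model constrains |omega| <= 1).
static double neg_rho_pen(const double* u, const double* v, int n,
                          const double* p) {
  double omega = p[2], pen = 0.0;
  if (omega > 1.0)  { pen = omega - 1.0;  omega = 1.0; }
  if (omega < -1.0) { pen = -1.0 - omega; omega = -1.0; }
  return -rho_stat(u, v, n, p[0], p[1], omega) + pen;
}

// Nelder-Mead simplex on (alpha, beta, omega).  The likelihood profile over
// kappa is monotone in rho, so maximising rho is the full ML problem; the
// surface is continuous but not smooth across the tangent branch point,
// which is why a derivative-free method is used.  Compiled because the
// Monte-Carlo calibration refits the model hundreds of thousands of times.
static void nm_run(const double* u, const double* v, int n, double* p,
                   const double* steps, double ftol, double ptol, int maxit,
                   double* fbest) {
  const int d = 3, np = 4;
  double sim[4][3], fval[4];
  for (int i = 0; i < np; ++i) {
    for (int j = 0; j < d; ++j) sim[i][j] = p[j];
    if (i > 0) sim[i][i - 1] += steps[i - 1];
    fval[i] = neg_rho_pen(u, v, n, sim[i]);
  }
  for (int it = 0; it < maxit; ++it) {
    // order: lo = best, hi = worst, nh = next worst
    int lo = 0, hi = 0, nh = 0;
    for (int i = 1; i < np; ++i) {
      if (fval[i] < fval[lo]) lo = i;
      if (fval[i] > fval[hi]) hi = i;
    }
    nh = lo;
    for (int i = 0; i < np; ++i)
      if (i != hi && fval[i] > fval[nh]) nh = i;

    double prange = 0.0;
    for (int j = 0; j < d; ++j) {
      double mn = sim[0][j], mx = sim[0][j];
      for (int i = 1; i < np; ++i) {
        mn = std::min(mn, sim[i][j]);
        mx = std::max(mx, sim[i][j]);
      }
      prange = std::max(prange, mx - mn);
    }
    if (fval[hi] - fval[lo] < ftol && prange < ptol) break;

    double cen[3] = {0, 0, 0};
    for (int i = 0; i < np; ++i)
      if (i != hi)
        for (int j = 0; j < d; ++j) cen[j] += sim[i][j] / (np - 1);

    double xr[3], xe[3], xc[3];
    for (int j = 0; j < d; ++j) xr[j] = cen[j] + (cen[j] - sim[hi][j]);
    double fr = neg_rho_pen(u, v, n, xr);
    if (fr < fval[lo]) {
      for (int j = 0; j < d; ++j) xe[j] = cen[j] + 2.0 * (cen[j] - sim[hi][j]);
      double fe = neg_rho_pen(u, v, n, xe);
      if (fe < fr) { std::copy(xe, xe + d, sim[hi]); fval[hi] = fe; }
      else { std::copy(xr, xr + d, sim[hi]); fval[hi] = fr; }
    } else if (fr < fval[nh]) {
      std::copy(xr, xr + d, sim[hi]); fval[hi] = fr;
    } else {
      for (int j = 0; j < d; ++j) xc[j] = cen[j] + 0.5 * (sim[hi][j] - cen[j]);
      double fc = neg_rho_pen(u, v, n, xc);
      if (fc < fval[hi]) { std::copy(xc, xc + d, sim[hi]); fval[hi] = fc; }
      else {
        // shrink towards the best vertex
        for (int i = 0; i < np; ++i) {
          if (i == lo) continue;
          for (int j = 0; j < d; ++j)
            sim[i][j] = sim[lo][j] + 0.5 * (sim[i][j] - sim[lo][j]);
          fval[i] = neg_rho_pen(u, v, n, sim[i]);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < np; ++i)
    if (fval[i] < fval[lo]) lo = i;
  std::copy(sim[lo], sim[lo] + d, p);
  *fbest = fval[lo];
}

// [[Rcpp::export]]
List dm_fit_cpp(NumericVector u, NumericVector v, NumericVector init,
                double ftol = 1e-12, double ptol = 1e-8,
                int maxit = 1000, int restarts = 1, double step0 = 0.2) {
  int n = u.size();
  double p[3] = {init[0], init[1], init[2]};
  double fbest = 0.0;
  double steps[3] = {step0, step0, 0.5 * step0};
  nm_run(u.begin(), v.begin(), n, p, steps, ftol, ptol, maxit, &fbest);
  for (int r = 0; r < restarts; ++r) {
    // fresh, smaller simplex around the current optimum guards against
    // premature simplex collapse
    double s2[3] = {0.05, 0.05, 0.02};
    nm_run(u.begin(), v.begin(), n, p, s2, ftol, ptol, maxit, &fbest);
  }
  if (p[2] > 1.0) p[2] = 1.0;
  if (p[2] < -1.0) p[2] = -1.0;
  return List::create(_["alpha"] = wrap_pm_pi(p[0]),
                      _["beta"] = wrap_pm_pi(p[1]),
                      _["omega"] = p[2],
                      _["rho"] = -neg_rho_pen(u.begin(), v.begin(), n, p));
}
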