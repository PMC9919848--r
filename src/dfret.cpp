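#include <Rcpp.h>
using namespace Rcpp;

// Thomas algorithm for a tridiagonal system.
// dl[i] multiplies x[i-1] in row i (dl[0] unused), d is the diagonal,
// du[i] multiplies x[i+1] in row i (du[n-1] unused).
// [[Rcpp::export]]
NumericVector tridiag_solve(NumericVector dl, NumericVector d,
                            NumericVector du, NumericVector b) {
  int n = d.size();
  NumericVector cp(n), x(n);
  double m = d[0];
  if (m == 0.0) stop("singular tridiagonal system");
  cp[0] = du[0] / m;
  x[0] = b[0] / m;
  for (int i = 1; i < n; ++i) {
    m = d[i] - dl[i] * cp[i - 1];
    if (m == 0.0) stop("singular tridiagonal system");
    cp[i] = (i < n - 1) ? du[i] / m : 0.0;
    x[i] = (b[i] - dl[i] * x[i - 1]) / m;
  }
  for (int i = n - 2; i >= 0; --i) x[i] -= cp[i] * x[i + 1];
  return x;
}

// Theta-method march of dN/dt = M N for a tridiagonal operator M
// (theta = 0.5: Crank-Nicolson; theta = 1: implicit Euler, L-stable).
// Returns the survival trace Q(t_k) = sum(wq * N_k), k = 0..K, stepping
// until Q < qtol * Q(0) or max_steps is reached.
// [[Rcpp::export]]
List cn_march(NumericVector ml, NumericVector md, NumericVector mu,
              NumericVector N0, NumericVector wq, double dt,
              double qtol, int max_steps, double theta = 0.5) {
  int n = md.size();
  double dti = theta * dt;       // implicit weight
  double dt2 = (1.0 - theta) * dt;  // explicit weight

  // LHS = I - theta dt M, factorized once (Thomas forward coefficients)
  NumericVector la(n), lb(n), lc(n), cp(n), denom(n);
  for (int i = 0; i < n; ++i) {
    la[i] = -dti * ml[i];
    lb[i] = 1.0 - dti * md[i];
    lc[i] = -dti * mu[i];
  }
  denom[0] = lb[0];
  cp[0] = lc[0] / denom[0];
  for (int i = 1; i < n; ++i) {
    denom[i] = lb[i] - la[i] * cp[i - 1];
    if (denom[i] == 0.0) stop("singular CN system; reduce dt");
    cp[i] = (i < n - 1) ? lc[i] / denom[i] : 0.0;
  }

  NumericVector N = clone(N0), rhs(n), dp(n);
  std::vector<double> qs;
  double q0 = 0.0;
  for (int i = 0; i < n; ++i) q0 += wq[i] * N[i];
  qs.push_back(q0);

  int k = 0;
  double q = q0;
  while (k < max_steps && q > qtol * q0) {
    // rhs = (I + (1-theta) dt M) N
    for (int i = 0; i < n; ++i) {
      double acc = N[i] + dt2 * md[i] * N[i];
      if (i > 0) acc += dt2 * ml[i] * N[i - 1];
      if (i < n - 1) acc += dt2 * mu[i] * N[i + 1];
      rhs[i] = acc;
    }
    dp[0] = rhs[0] / denom[0];
    for (int i = 1; i < n; ++i)
      dp[i] = (rhs[i] - la[i] * dp[i - 1]) / denom[i];
    N[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) N[i] = dp[i] - cp[i] * N[i + 1];
    q = 0.0;
    for (int i = 0; i < n; ++i) q += wq[i] * N[i];
    qs.push_back(q);
    ++k;
  }
  return List::create(_["Q"] = NumericVector(qs.begin(), qs.end()),
                      _["dt"] = dt, _["n_steps"] = k,
                      _["N_final"] = N);
}

static inline double interp_tab(const NumericVector &tab, double r,
                                double r0, double inv_h, int n) {
  double u = (r - r0) * inv_h;
  if (u <= 0.0) return tab[0];
  if (u >= n - 1) return tab[n - 1];
  int j = (int)u;
  double f = u - j;
  return tab[j] * (1.0 - f) + tab[j + 1] * f;
}

// Overdamped Brownian-dynamics estimator of the transfer efficiency.
// Trajectories diffuse on [r_lo, r_hi] with drift D dln(p)/dr (table
// lookup) and reflecting walls; donor decay and the r^-6 FRET sink are
// handled by an analytic survival weight w(t), so the estimator is
// E_i = 1 - W_i / tauD with W_i = int w dt (trapezoid along the path,
// exponential tail completion at the weight cutoff).
// Uses R's RNG: seed with set.seed() on the R side.
// [[Rcpp::export]]
List brownian_mc(NumericVector start, NumericVector drift_tab,
                 NumericVector haz_tab, double tab_r0, double tab_h,
                 double r_lo, double r_hi, double D, double tauD,
                 double dt_base, double eta_h, double wtol,
                 double tmax) {
  RNGScope scope;
  int n_traj = start.size();
  int n_tab = haz_tab.size();
  double inv_h = 1.0 / tab_h;
  double sum = 0.0, sumsq = 0.0;

  for (int k = 0; k < n_traj; ++k) {
    double r = start[k], w = 1.0, W = 0.0, t = 0.0;
    double h = interp_tab(haz_tab, r, tab_r0, inv_h, n_tab);
    while (true) {
      double dt = dt_base;
      if (h * dt > eta_h) dt = eta_h / h;
      double sig = std::sqrt(2.0 * D * dt);
      double mu = (D > 0.0)
          ? interp_tab(drift_tab, r, tab_r0, inv_h, n_tab) : 0.0;
      // clamp divergent drift near the vanishing-density wall
      double mu_max = 4.0 * sig / dt;
      if (mu > mu_max) mu = mu_max;
      if (mu < -mu_max) mu = -mu_max;
      double rn = r + mu * dt + sig * norm_rand();
      while (rn < r_lo || rn > r_hi) {
        if (rn < r_lo) rn = 2.0 * r_lo - rn;
        else rn = 2.0 * r_hi - rn;
      }
      double hn = interp_tab(haz_tab, rn, tab_r0, inv_h, n_tab);
      double wn = w * std::exp(-0.5 * (h + hn) * dt);
      W += 0.5 * (w + wn) * dt;
      r = rn; h = hn; w = wn; t += dt;
      if (w < wtol || t > tmax) {
        W += w / h;  // frozen-position tail completion
        break;
      }
    }
    double e = 1.0 - W / tauD;
    sum += e; sumsq += e * e;
  }
  double mean = sum / n_traj;
  double var = (sumsq - n_traj * mean * mean) / (n_traj - 1.0);
  double se = std::sqrt(var / n_traj);
  return List::create(_["E"] = mean, _["se"] = se, _["n_traj"] = n_traj);
}

// Drift-diffusion positions after a fixed time, no decay/sink: used to
// verify that the stationary law of the simulated dynamics is p(r).
// [[Rcpp::export]]
NumericVector brownian_positions(NumericVector start,
                                 NumericVector drift_tab, double tab_r0,
                                 double tab_h, double r_lo, double r_hi,
                                 double D, double total_time, double dt) {
  RNGScope scope;
  int n_traj = start.size();
  int n_tab = drift_tab.size();
  double inv_h = 1.0 / tab_h;
  int n_steps = (int)std::ceil(total_time / dt);
  double sig = std::sqrt(2.0 * D * dt);
  double mu_max = 4.0 * sig / dt;
  NumericVector out(n_traj);
  for (int k = 0; k < n_traj; ++k) {
    double r = start[k];
    for (int s = 0; s < n_steps; ++s) {
      double mu = interp_tab(drift_tab, r, tab_r0, inv_h, n_tab);
      if (mu > mu_max) mu = mu_max;
      if (mu < -mu_max) mu = -mu_max;
      r += mu * dt + sig * norm_rand();
      while (r < r_lo || r > r_hi) {
        if (r < r_lo) r = 2.0 * r_lo - r;
        else r = 2.0 * r_hi - r;
      }
    }
    out[k] = r;
  }
  return out;
}
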