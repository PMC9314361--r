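// Exact stochastic simulation (Gillespie SSA) of an augmented CTMC.
//
// The state vector is [x (d base species), y (shift registers), z (snapshot
// registers)].  Base reactions act on x only; register reset reactions fire
// at constant rates and copy the output species into the registers.  While
// simulating we accumulate exact path integrals over [Tc, Tf] (piecewise
// constant paths, so integrals are sums of value * holding-time), split into
// `n_batch` equal-width time batches for standard-error computation, and
// optionally a table of unique base states with their occupation times (used
// to evaluate expensive state functionals once per visited state).

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// propensity type codes (keep in sync with R/network.R)
#define P_MASS 0
#define P_CONST 1
#define P_AFFINE 2
#define P_HILLR 3
#define P_HILLFB 4
#define P_PROPFB 5

// displacement type codes
#define D_FIXED 0
#define D_BINOM 1
#define D_STRICT 2
#define D_SHIFT 3
#define D_SNAP 4

static double eval_propensity(int type, const NumericVector& par,
                              const IntegerMatrix& nu, int k,
                              const std::vector<double>& x, int d) {
  switch (type) {
  case P_MASS: {
    double a = par[0];
    for (int j = 0; j < d; ++j) {
      int njk = nu(k, j);
      if (njk > 0) {
        double xj = x[j];
        if (xj < njk) return 0.0;
        for (int r = 0; r < njk; ++r) a *= (xj - r);
        for (int r = 2; r <= njk; ++r) a /= r;
      }
    }
    return a;
  }
  case P_CONST:
    return par[0];
  case P_AFFINE: {
    double a = par[0];
    for (int j = 0; j < d; ++j) a += par[1 + j] * x[j];
    return a > 0.0 ? a : 0.0;
  }
  case P_HILLR: {
    // K0 / (K1 + x_j^H)
    double K0 = par[0], K1 = par[1], H = par[2];
    int j = (int)par[3];
    return K0 / (K1 + std::pow(x[j], H));
  }
  case P_HILLFB: {
    // 4 kfb mu^2 / (mu + x_j)
    double kfb = par[0], mu = par[1];
    int j = (int)par[2];
    return 4.0 * kfb * mu * mu / (mu + x[j]);
  }
  case P_PROPFB: {
    // kfb * max(3 mu - x_j, 0)
    double kfb = par[0], mu = par[1];
    int j = (int)par[2];
    double v = 3.0 * mu - x[j];
    return v > 0.0 ? kfb * v : 0.0;
  }
  }
  return 0.0;
}

// [[Rcpp::export]]
List ssa_run_cpp(NumericVector x0, int d, int n_out,
                 IntegerVector prop_type, List prop_params,
                 IntegerMatrix nu,
                 IntegerVector disp_type, List disp_params,
                 double Tf, double Tc, int n_batch,
                 double sample_dt,
                 bool record_path, bool record_table,
                 double max_events) {
  const int Dtot = x0.size();
  const int K = prop_type.size();
  const int n_reg = Dtot - d;  // y and z registers combined

  std::vector<double> x(x0.begin(), x0.end());

  // cache parameter vectors
  std::vector<NumericVector> ppar(K), dpar(K);
  for (int k = 0; k < K; ++k) {
    ppar[k] = as<NumericVector>(prop_params[k]);
    dpar[k] = as<NumericVector>(disp_params[k]);
  }

  const double bw = (Tf - Tc) / n_batch;  // batch width
  std::vector<double> int_x(n_batch, 0.0), int_x2(n_batch, 0.0);
  std::vector<std::vector<double> > int_reg(n_batch,
      std::vector<double>(n_reg > 0 ? n_reg : 1, 0.0));
  std::vector<double> t_eff(n_batch, 0.0);

  std::map<std::vector<int>, std::vector<double> > table;

  // path recording
  std::vector<double> path_t;
  std::vector<int> path_which;
  std::vector<double> path_x;
  if (record_path) {
    path_t.push_back(0.0);
    path_which.push_back(NA_INTEGER);
    for (int j = 0; j < Dtot; ++j) path_x.push_back(x[j]);
  }

  // uniform sampling
  std::vector<double> samples;
  double next_sample = Tc;
  bool do_sample = sample_dt > 0.0;

  double t = 0.0;
  double n_events = 0.0;

  std::vector<double> a(K);

  while (t < Tf) {
    double a0 = 0.0;
    for (int k = 0; k < K; ++k) {
      a[k] = eval_propensity(prop_type[k], ppar[k], nu, k, x, d);
      if (a[k] < 0.0) stop("negative propensity encountered for reaction %d", k + 1);
      a0 += a[k];
    }
    double t_next;
    if (a0 <= 0.0) {
      t_next = Tf;  // absorbing state: pad to horizon
    } else {
      t_next = t + exp_rand() / a0;
    }
    double t_hi = t_next < Tf ? t_next : Tf;

    // accumulate over [t, t_hi] intersect [Tc, Tf], split by batch
    if (t_hi > Tc) {
      double u0 = t > Tc ? t : Tc;
      double xn = x[n_out];
      int b0 = (int)std::floor((u0 - Tc) / bw);
      if (b0 >= n_batch) b0 = n_batch - 1;
      while (u0 < t_hi) {
        double bend = Tc + (b0 + 1) * bw;
        double u1 = t_hi < bend ? t_hi : bend;
        double w = u1 - u0;
        if (w > 0.0) {
          int_x[b0] += xn * w;
          int_x2[b0] += xn * xn * w;
          for (int r = 0; r < n_reg; ++r) {
            double dy = x[d + r] - xn;
            int_reg[b0][r] += dy * dy * w;
          }
          t_eff[b0] += w;
          if (record_table) {
            std::vector<int> key(d);
            for (int j = 0; j < d; ++j) key[j] = (int)std::lround(x[j]);
            std::map<std::vector<int>, std::vector<double> >::iterator it =
                table.find(key);
            if (it == table.end()) {
              std::vector<double> wv(n_batch, 0.0);
              wv[b0] = w;
              table.insert(std::make_pair(key, wv));
            } else {
              it->second[b0] += w;
            }
          }
        }
        u0 = u1;
        if (u0 >= bend - 1e-300) ++b0;
        if (b0 >= n_batch) break;
      }
    }

    // uniform samples within [t, t_next): the path is right-continuous, so a
    // sample falling exactly on a jump epoch takes the post-jump state
    if (do_sample) {
      while (next_sample <= Tf && next_sample < t_next) {
        for (int j = 0; j < d; ++j) samples.push_back(x[j]);
        next_sample += sample_dt;
      }
    }

    if (t_next >= Tf) break;
    if (a0 <= 0.0) break;

    // select reaction
    double u = unif_rand() * a0;
    int k = 0;
    double cum = a[0];
    while (cum < u && k < K - 1) { ++k; cum += a[k]; }

    // apply displacement
    const NumericVector& dp = dpar[k];
    switch (disp_type[k]) {
    case D_FIXED:
      for (int j = 0; j < Dtot; ++j) x[j] += dp[j];
      break;
    case D_BINOM: {
      int m = (int)dp[0];
      for (int i = 0; i < m; ++i) {
        int j = (int)dp[1 + i];
        x[j] = R::rbinom(x[j], 0.5);
      }
      for (int j = 0; j < Dtot; ++j) x[j] += dp[1 + m + j];
      break;
    }
    case D_STRICT: {
      int m = (int)dp[0];
      for (int i = 0; i < m; ++i) {
        int j = (int)dp[1 + i];
        double xv = x[j];
        double half = std::floor(xv / 2.0);
        bool odd = (xv - 2.0 * half) > 0.5;
        if (odd && unif_rand() < 0.5) half += 1.0;
        x[j] = half;
      }
      for (int j = 0; j < Dtot; ++j) x[j] += dp[1 + m + j];
      break;
    }
    case D_SHIFT: {
      int start = (int)dp[0], len = (int)dp[1];
      for (int j = start + len - 1; j > start; --j) x[j] = x[j - 1];
      x[start] = x[n_out];
      break;
    }
    case D_SNAP:
      x[(int)dp[0]] = x[n_out];
      break;
    }

    t = t_next;
    n_events += 1.0;
    if (n_events > max_events)
      stop("simulation exceeded max_events (%.0f); increase the cap or shorten Tf",
           max_events);

    if (record_path) {
      path_t.push_back(t);
      path_which.push_back(k + 1);
      for (int j = 0; j < Dtot; ++j) path_x.push_back(x[j]);
    }
  }

  // emit any samples landing exactly at the horizon
  if (do_sample) {
    while (next_sample <= Tf * (1.0 + 1e-15)) {
      for (int j = 0; j < d; ++j) samples.push_back(x[j]);
      next_sample += sample_dt;
    }
  }

  List out;
  out["n_events"] = n_events;
  out["t_eff"] = NumericVector(t_eff.begin(), t_eff.end());
  out["int_x"] = NumericVector(int_x.begin(), int_x.end());
  out["int_x2"] = NumericVector(int_x2.begin(), int_x2.end());
  NumericMatrix ir(n_batch, n_reg > 0 ? n_reg : 0);
  for (int b = 0; b < n_batch; ++b)
    for (int r = 0; r < n_reg; ++r) ir(b, r) = int_reg[b][r];
  out["int_reg"] = ir;
  out["final_state"] = NumericVector(x.begin(), x.end());

  if (record_table) {
    int ns = table.size();
    IntegerMatrix st(ns, d);
    NumericMatrix wt(ns, n_batch);
    int i = 0;
    for (std::map<std::vector<int>, std::vector<double> >::const_iterator it =
             table.begin(); it != table.end(); ++it, ++i) {
      for (int j = 0; j < d; ++j) st(i, j) = it->first[j];
      for (int b = 0; b < n_batch; ++b) wt(i, b) = it->second[b];
    }
    out["table_states"] = st;
    out["table_weights"] = wt;
  }

  if (record_path) {
    int ne = path_t.size();
    NumericMatrix pm(ne, Dtot);
    for (int i = 0; i < ne; ++i)
      for (int j = 0; j < Dtot; ++j) pm(i, j) = path_x[(size_t)i * Dtot + j];
    out["times"] = NumericVector(path_t.begin(), path_t.end());
    out["which"] = IntegerVector(path_which.begin(), path_which.end());
    out["states"] = pm;
  }

  if (do_sample) {
    int ns = samples.size() / d;
    NumericMatrix sm(ns, d);
    for (int i = 0; i < ns; ++i)
      for (int j = 0; j < d; ++j) sm(i, j) = samples[(size_t)i * d + j];
    out["samples"] = sm;
  }

  return out;
}
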