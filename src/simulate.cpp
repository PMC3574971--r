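#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Piecewise-constant drive schedule: value of the last breakpoint <= t.
// Breakpoints are sorted; the first is always 0.
static inline double sched_value(const double *times, const double *values,
                                 const int n, const double t) {
  int i = n - 1;
  while (i > 0 && times[i] > t) --i;
  return values[i];
}

// Rectified Naka-Rushton gain, maximum c1, semi-saturation c2.
static inline double gain(const double x, const double c1, const double c2sq) {
  if (x <= 0.0) return 0.0;
  const double x2 = x * x;
  return c1 * x2 / (c2sq + x2);
}

struct NetDeriv {
  int M;                 // number of memory units
  double a1, a2, b1, b2, c1, c2sq;
  double a1c, a2c;       // Central Unit relaxation rates (theta time scale)
  double w1, w2;
  const double *ct, *cv; int cn;                 // central schedule
  std::vector<const double*> mt, mv;             // memory schedules
  std::vector<int> mn;
  bool has_coinc; int out_idx;                   // 0-based memory index
  double ramp_rate, ramp_ceiling;

  // E[0], I[0] central; E[1..M], I[1..M] memory units.
  // fired_at < 0 means the coincidence unit has not fired.
  void operator()(const double *E, const double *I, const double t,
                  const double fired_at, double *dE, double *dI) const {
    double sumE = 0.0;
    for (int j = 1; j <= M; ++j) sumE += E[j];
    // Central Unit: executive go/no-go current only, no feedback coupling.
    double Kc = sched_value(ct, cv, cn, t);
    dE[0] = a1c * (-E[0] + gain(b1 * E[0] - I[0] + Kc, c1, c2sq));
    dI[0] = a2c * (-I[0] + gain(b2 * E[0], c1, c2sq));
    for (int j = 1; j <= M; ++j) {
      double K = sched_value(mt[j - 1], mv[j - 1], mn[j - 1], t)
               + w1 * E[0] - w2 * (sumE - E[j]);
      if (has_coinc && fired_at >= 0.0 && (j - 1) == out_idx) {
        double ramp = ramp_rate * (t - fired_at);
        K += (ramp > ramp_ceiling) ? ramp_ceiling : ramp;
      }
      dE[j] = a1 * (-E[j] + gain(b1 * E[j] - I[j] + K, c1, c2sq));
      dI[j] = a2 * (-I[j] + gain(b2 * E[j], c1, c2sq));
    }
  }
};

//' @name simulate_network_cpp
//' @title Compiled fixed-step RK4 core for the coupled network
//' @description Internal. Classical RK4 with couplings re-evaluated at each
//'   sub-stage; drive schedules are piecewise-constant in time (ms). The
//'   coincidence detector is checked once per step on the pre-step states and
//'   latches on first crossing.
//' @keywords internal
// [[Rcpp::export]]
List simulate_network_cpp(int n_memory, double w1, double w2,
                          NumericVector params, NumericVector central_rates,
                          NumericVector central_times, NumericVector central_values,
                          List memory_times, List memory_values,
                          double duration_ms, double dt,
                          NumericVector E0, NumericVector I0,
                          int stride,
                          bool has_coinc, int pos_idx, int mot_idx, int out_idx,
                          double threshold, double ramp_rate, double ramp_ceiling) {
  const int M = n_memory, U = M + 1;
  NetDeriv f;
  f.M = M;
  f.a1 = params[0]; f.a2 = params[1]; f.b1 = params[2]; f.b2 = params[3];
  f.c1 = params[4]; f.c2sq = params[5] * params[5];
  f.a1c = central_rates[0]; f.a2c = central_rates[1];
  f.w1 = w1; f.w2 = w2;
  f.ct = REAL(central_times); f.cv = REAL(central_values);
  f.cn = central_times.size();
  std::vector<NumericVector> keep_t(M), keep_v(M);
  for (int j = 0; j < M; ++j) {
    keep_t[j] = as<NumericVector>(memory_times[j]);
    keep_v[j] = as<NumericVector>(memory_values[j]);
    f.mt.push_back(REAL(keep_t[j]));
    f.mv.push_back(REAL(keep_v[j]));
    f.mn.push_back(keep_t[j].size());
  }
  f.has_coinc = has_coinc; f.out_idx = out_idx;
  f.ramp_rate = ramp_rate; f.ramp_ceiling = ramp_ceiling;

  const long n_steps = (long) std::lround(duration_ms / dt);
  const long n_save = n_steps / stride;
  NumericMatrix Eout(n_save, U), Iout(n_save, U);
  NumericVector t_out(n_save), coinc_current(n_save);

  std::vector<double> E(U), I(U), En(U), In(U);
  std::vector<double> k1E(U), k1I(U), k2E(U), k2I(U), k3E(U), k3I(U), k4E(U), k4I(U);
  for (int u = 0; u < U; ++u) { E[u] = E0[u]; I[u] = I0[u]; }

  double fired_at = -1.0;
  long save_row = 0;
  for (long s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    if (has_coinc && fired_at < 0.0 &&
        E[pos_idx + 1] + E[mot_idx + 1] > threshold)
      fired_at = t;
    f(E.data(), I.data(), t, fired_at, k1E.data(), k1I.data());
    for (int u = 0; u < U; ++u) { En[u] = E[u] + 0.5 * dt * k1E[u]; In[u] = I[u] + 0.5 * dt * k1I[u]; }
    f(En.data(), In.data(), t + 0.5 * dt, fired_at, k2E.data(), k2I.data());
    for (int u = 0; u < U; ++u) { En[u] = E[u] + 0.5 * dt * k2E[u]; In[u] = I[u] + 0.5 * dt * k2I[u]; }
    f(En.data(), In.data(), t + 0.5 * dt, fired_at, k3E.data(), k3I.data());
    for (int u = 0; u < U; ++u) { En[u] = E[u] + dt * k3E[u]; In[u] = I[u] + dt * k3I[u]; }
    f(En.data(), In.data(), t + dt, fired_at, k4E.data(), k4I.data());
    for (int u = 0; u < U; ++u) {
      E[u] += dt / 6.0 * (k1E[u] + 2.0 * k2E[u] + 2.0 * k3E[u] + k4E[u]);
      I[u] += dt / 6.0 * (k1I[u] + 2.0 * k2I[u] + 2.0 * k3I[u] + k4I[u]);
      if (!std::isfinite(E[u]) || !std::isfinite(I[u]))
        stop("integration blow-up in unit %d (0 = central) at t = %.4f ms",
             u, t + dt);
    }
    if ((s + 1) % stride == 0) {
      const double ts = (s + 1) * dt;
      t_out[save_row] = ts;
      for (int u = 0; u < U; ++u) { Eout(save_row, u) = E[u]; Iout(save_row, u) = I[u]; }
      if (has_coinc && fired_at >= 0.0) {
        double ramp = ramp_rate * (ts - fired_at);
        coinc_current[save_row] = (ramp > ramp_ceiling) ? ramp_ceiling : ramp;
      }
      ++save_row;
    }
  }
  return List::create(_["times_ms"] = t_out, _["E"] = Eout, _["I"] = Iout,
                      _["fired_at_ms"] = fired_at,
                      _["coinc_current"] = coinc_current);
}
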