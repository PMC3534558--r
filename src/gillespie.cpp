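#include <Rcpp.h>
using namespace Rcpp;

// Stochastic simulation of the circuit reaction systems.
//
// A reaction system is encoded as:
//  - stoich: n_species x n_rx integer matrix of state changes
//  - rxpar:  7 x n_rx numeric matrix, one column per reaction, rows
//      0 type, 1 k, 2 i (0-based species index), 3 n (Hill), 4 h,
//      5 j (0-based species index), 6 h2
//    propensity types:
//      0: k
//      1: k * x[i]
//      2: k * x[i]^n / (h^n + x[i]^n)          (Michaelis-Menten/Hill activation)
//      3: k * x[i] / (1 + x[j]/h2)             (linear x repression)
//      4: k * (x[i]^n/(h^n + x[i]^n)) / (1 + x[j]/h2)
//    h or h2 equal to R_PosInf disables the corresponding saturation/repression
//    factor (x/Inf == 0 in IEEE arithmetic, which gives exactly factor 1 for
//    the repression term; type 2/4 guard the activation term explicitly).
//
// All draws come from R's RNG so set.seed() makes paths bit-reproducible.

static inline double propensity(const double* x, const double* par) {
  const int type = (int) par[0];
  const double k = par[1];
  switch (type) {
  case 0:
    return k;
  case 1:
    return k * x[(int) par[2]];
  case 2: {
    const double xi = x[(int) par[2]], n = par[3], h = par[4];
    if (xi <= 0.0) return 0.0;
    if (!R_FINITE(h)) return 0.0; // saturating constant at infinity: no activation
    const double xn = (n == 1.0) ? xi : std::pow(xi, n);
    const double hn = (n == 1.0) ? h : std::pow(h, n);
    return k * xn / (hn + xn);
  }
  case 3: {
    const double xi = x[(int) par[2]], xj = x[(int) par[5]], h2 = par[6];
    return k * xi / (1.0 + xj / h2);
  }
  case 4: {
    const double xi = x[(int) par[2]], n = par[3], h = par[4];
    const double xj = x[(int) par[5]], h2 = par[6];
    if (xi <= 0.0) return 0.0;
    double act;
    if (!R_FINITE(h)) act = 0.0;
    else {
      const double xn = (n == 1.0) ? xi : std::pow(xi, n);
      const double hn = (n == 1.0) ? h : std::pow(h, n);
      act = xn / (hn + xn);
    }
    return k * act / (1.0 + xj / h2);
  }
  case 5: {
    // constant production under repression (used when the TF level is a
    // fixed parameter rather than a species)
    const double xj = x[(int) par[5]], h2 = par[6];
    return k / (1.0 + xj / h2);
  }
  default:
    return 0.0;
  }
}

// advance the state by one reaction event; returns the waiting time, or -1 if
// all propensities vanish.  method 0 = direct, 1 = first-reaction (Gillespie's
// original scheme; statistically identical, kept as the named algorithm).
static inline double step(std::vector<double>& x, const IntegerMatrix& stoich,
                          const NumericMatrix& rxpar, std::vector<double>& a,
                          int method) {
  const int n_rx = rxpar.ncol(), n_sp = stoich.nrow();
  double atot = 0.0;
  for (int j = 0; j < n_rx; ++j) {
    a[j] = propensity(x.data(), &rxpar(0, j));
    atot += a[j];
  }
  if (atot <= 0.0) return -1.0;
  double tau;
  int jmin = -1;
  if (method == 1) {
    tau = R_PosInf;
    for (int j = 0; j < n_rx; ++j) {
      if (a[j] > 0.0) {
        const double tj = R::exp_rand() / a[j];
        if (tj < tau) { tau = tj; jmin = j; }
      }
    }
  } else {
    tau = R::exp_rand() / atot;
    double u = unif_rand() * atot, c = 0.0;
    for (int j = 0; j < n_rx; ++j) {
      c += a[j];
      if (u <= c) { jmin = j; break; }
    }
    if (jmin < 0) jmin = n_rx - 1;
  }
  for (int s = 0; s < n_sp; ++s) {
    const int d = stoich(s, jmin);
    if (d != 0) x[s] += d;
  }
  return tau;
}

// [[Rcpp::export(name = ".ssa_path")]]
NumericMatrix ssa_path(IntegerMatrix stoich, NumericMatrix rxpar,
                       NumericVector init, NumericVector record_times,
                       int method) {
  const int n_sp = stoich.nrow(), n_t = record_times.size();
  std::vector<double> x(init.begin(), init.end());
  std::vector<double> a(rxpar.ncol());
  NumericMatrix out(n_t, n_sp);
  double t = 0.0;
  int k = 0;
  long ev = 0;
  while (k < n_t) {
    const std::vector<double> xc = x; // state holds on [t, t + tau)
    const double tau = step(x, stoich, rxpar, a, method);
    const double t_next = (tau < 0.0) ? R_PosInf : t + tau;
    while (k < n_t && record_times[k] < t_next) {
      for (int s = 0; s < n_sp; ++s) out(k, s) = xc[s];
      ++k;
    }
    if (tau < 0.0) break;
    t = t_next;
    if ((++ev & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".ssa_final")]]
NumericMatrix ssa_final(IntegerMatrix stoich, NumericMatrix rxpar,
                        NumericVector init, double t_end, int n_trials,
                        int method) {
  const int n_sp = stoich.nrow();
  NumericMatrix out(n_trials, n_sp);
  std::vector<double> a(rxpar.ncol());
  for (int tr = 0; tr < n_trials; ++tr) {
    std::vector<double> x(init.begin(), init.end());
    double t = 0.0;
    for (;;) {
      const double tau = step(x, stoich, rxpar, a, method);
      if (tau < 0.0 || t + tau > t_end) break;
      t += tau;
    }
    for (int s = 0; s < n_sp; ++s) out(tr, s) = x[s];
    if (tr % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".ssa_timeavg")]]
List ssa_timeavg(IntegerMatrix stoich, NumericMatrix rxpar,
                 NumericVector init, double t_burn, double t_sample,
                 int n_batches, int method) {
  const int n_sp = stoich.nrow();
  std::vector<double> x(init.begin(), init.end());
  std::vector<double> a(rxpar.ncol());
  double t = 0.0;
  long ev = 0;
  // burn-in
  while (t < t_burn) {
    const double tau = step(x, stoich, rxpar, a, method);
    if (tau < 0.0) break;
    t += tau;
    if ((++ev & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  // time-weighted accumulation over [t_burn, t_burn + t_sample), split into
  // batches for batch-means standard errors
  const double batch_len = t_sample / n_batches;
  NumericMatrix bmean(n_batches, n_sp), bm2(n_batches, n_sp);
  std::vector<double> sum1(n_sp, 0.0), sum2(n_sp, 0.0);
  double t_rel = t - t_burn; // >= 0: overshoot of the last burn-in event
  if (t_rel < 0) t_rel = 0;
  int b = 0;
  double b_end = batch_len;
  // NB: state x is constant between events
  while (t_rel < t_sample) {
    const std::vector<double> xc = x;
    const double tau = step(x, stoich, rxpar, a, method);
    double t_next = (tau < 0.0) ? t_sample : t_rel + tau;
    if (t_next > t_sample) t_next = t_sample;
    double seg_start = t_rel;
    while (seg_start < t_next) {
      const double seg_end = std::min(t_next, b_end);
      const double dt = seg_end - seg_start;
      if (dt > 0) {
        for (int s = 0; s < n_sp; ++s) {
          bmean(b, s) += xc[s] * dt;
          bm2(b, s) += xc[s] * xc[s] * dt;
        }
      }
      seg_start = seg_end;
      if (seg_start >= b_end && b < n_batches - 1) { ++b; b_end += batch_len; }
      else if (seg_start >= t_sample) break;
    }
    if (tau < 0.0) { // absorbing state: remaining time spent at x
      t_rel = t_sample;
      break;
    }
    t_rel += tau;
    if ((++ev & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector mean(n_sp), m2(n_sp);
  for (int s = 0; s < n_sp; ++s) {
    double s1 = 0, s2 = 0;
    for (int bb = 0; bb < n_batches; ++bb) { s1 += bmean(bb, s); s2 += bm2(bb, s); }
    mean[s] = s1 / t_sample;
    m2[s] = s2 / t_sample;
    for (int bb = 0; bb < n_batches; ++bb) {
      bmean(bb, s) /= batch_len;
      bm2(bb, s) /= batch_len;
    }
  }
  return List::create(_["mean"] = mean, _["m2"] = m2,
                      _["batch_mean"] = bmean, _["batch_m2"] = bm2,
                      _["n_events"] = (double) ev);
}

// [[Rcpp::export(name = ".ssa_events")]]
List ssa_events(IntegerMatrix stoich, NumericMatrix rxpar, NumericVector init,
                int n_events, int method) {
  // record the exact event sequence (for determinism tests)
  const int n_sp = stoich.nrow();
  std::vector<double> x(init.begin(), init.end());
  std::vector<double> a(rxpar.ncol());
  NumericVector times(n_events);
  NumericMatrix states(n_events, n_sp);
  double t = 0.0;
  int k = 0;
  for (; k < n_events; ++k) {
    const double tau = step(x, stoich, rxpar, a, method);
    if (tau < 0.0) break;
    t += tau;
    times[k] = t;
    for (int s = 0; s < n_sp; ++s) states(k, s) = x[s];
  }
  if (k < n_events) {
    NumericVector t2(k);
    NumericMatrix s2(k, n_sp);
    for (int i = 0; i < k; ++i) {
      t2[i] = times[i];
      for (int s = 0; s < n_sp; ++s) s2(i, s) = states(i, s);
    }
    return List::create(_["times"] = t2, _["states"] = s2);
  }
  return List::create(_["times"] = times, _["states"] = states);
}
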