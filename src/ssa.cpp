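#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact stochastic simulation of competitive adsorption at particle
// resolution. Each nanoparticle p carries a continuous free surface
// fraction theta_p; a binding event of species i on particle p has
// propensity k_a,i * c_free,i * n_i * theta_p (events/s) and consumes a
// surface increment with mean 1/n_i; an unbinding event has propensity
// k_d,i per bound molecule and restores the increment recorded when that
// molecule bound, so theta_p stays in [0, 1] exactly. Counts map to molar
// concentrations through volume_scale (count = M * volume_scale).
//
// increment_model: 0 = deterministic (exactly 1/n_i), 1 = uniform on
// [0, 2/n_i]. Uses R's RNG so set.seed() gives bit-identical runs.
// [[Rcpp::export]]
List ssa_run_cpp(NumericVector ka, NumericVector kd, NumericVector n,
                 NumericVector c0, double N0, int n_particles,
                 double volume_scale, NumericVector out_times,
                 int increment_model, double max_events) {
  const int m = ka.size();
  const int P = n_particles;
  const int nt = out_times.size();

  std::vector<double> free_count(m);
  for (int i = 0; i < m; ++i)
    free_count[i] = std::floor(c0[i] * volume_scale + 0.5);

  std::vector<double> theta(P, 1.0);
  // increments of bound molecules, per species x particle
  std::vector< std::vector< std::vector<double> > > inc(
      m, std::vector< std::vector<double> >(P));
  std::vector<double> bound_total(m, 0.0);
  std::vector<double> occ_total(m, 0.0); // surface occupied by species i,
                                         // summed over particles
  double S_theta = (double)P;

  NumericMatrix X(nt, m);       // bound concentration (M)
  NumericMatrix F(nt, m);       // ensemble-mean occupied surface fraction
  NumericVector THETA_BAR(nt);  // ensemble-mean free surface fraction
  int out_idx = 0;
  double t = 0.0;
  double events = 0.0;
  bool ended_early = false;

  std::vector<double> a_bind(m), a_unbind(m);

  auto record_until = [&](double t_now) {
    while (out_idx < nt && out_times[out_idx] <= t_now) {
      for (int i = 0; i < m; ++i) {
        X(out_idx, i) = bound_total[i] / volume_scale;
        F(out_idx, i) = occ_total[i] / (double)P;
      }
      THETA_BAR[out_idx] = S_theta / (double)P;
      ++out_idx;
    }
  };

  while (out_idx < nt) {
    // the running sum drifts by subtraction round-off; refresh it when it
    // is small enough that the drift could mask a truly empty surface
    if (S_theta < 1e-9 * (double)P) {
      double s = 0.0;
      for (int q = 0; q < P; ++q) s += theta[q];
      S_theta = s;
    }
    double A = 0.0;
    for (int i = 0; i < m; ++i) {
      a_bind[i] = ka[i] * (free_count[i] / volume_scale) * n[i] * S_theta;
      if (a_bind[i] < 0) a_bind[i] = 0;
      a_unbind[i] = kd[i] * bound_total[i];
      A += a_bind[i] + a_unbind[i];
    }
    if (A <= 0.0) { ended_early = true; break; }

    double dt = exp_rand() / A;
    double t_next = t + dt;
    record_until(std::min(t_next, out_times[nt - 1] + 0.0));
    t = t_next;
    if (out_idx >= nt) break;

    // choose reaction channel
    double u = unif_rand() * A;
    int species = -1;
    bool is_bind = true;
    for (int i = 0; i < m; ++i) {
      if (u < a_bind[i]) { species = i; is_bind = true; break; }
      u -= a_bind[i];
      if (u < a_unbind[i]) { species = i; is_bind = false; break; }
      u -= a_unbind[i];
    }
    if (species < 0) { species = m - 1; is_bind = (a_bind[m - 1] > 0); }

    if (is_bind) {
      // particle chosen proportional to its free surface
      double target = unif_rand() * S_theta;
      int p = P - 1;
      double cum = 0.0;
      for (int q = 0; q < P; ++q) {
        cum += theta[q];
        if (cum >= target) { p = q; break; }
      }
      double d = (increment_model == 0) ? 1.0 / n[species]
                                        : unif_rand() * 2.0 / n[species];
      double actual = std::min(d, theta[p]);
      theta[p] -= actual;
      S_theta -= actual;
      inc[species][p].push_back(actual);
      occ_total[species] += actual;
      bound_total[species] += 1.0;
      free_count[species] -= 1.0;
    } else {
      // particle chosen proportional to its bound count of this species
      double target = unif_rand() * bound_total[species];
      int p = P - 1;
      double cum = 0.0;
      for (int q = 0; q < P; ++q) {
        cum += (double)inc[species][q].size();
        if (cum >= target) { p = q; break; }
      }
      std::vector<double> &stack = inc[species][p];
      if (!stack.empty()) {
        int j = (int)std::floor(unif_rand() * stack.size());
        if (j >= (int)stack.size()) j = (int)stack.size() - 1;
        double restored = stack[j];
        stack[j] = stack.back();
        stack.pop_back();
        theta[p] += restored;
        if (theta[p] > 1.0) theta[p] = 1.0;
        S_theta += restored;
        occ_total[species] -= restored;
        bound_total[species] -= 1.0;
        free_count[species] += 1.0;
      }
    }

    events += 1.0;
    if (events > max_events)
      stop("SSA event-count guard exceeded (%.3g events).", max_events);
    // refresh the running free-surface sum to control round-off drift
    if (((long long)events) % 100000LL == 0LL) {
      double s = 0.0;
      for (int q = 0; q < P; ++q) s += theta[q];
      S_theta = s;
    }
  }

  if (ended_early) record_until(out_times[nt - 1]);

  NumericMatrix bound(m, P);
  for (int i = 0; i < m; ++i)
    for (int p = 0; p < P; ++p)
      bound(i, p) = (double)inc[i][p].size();

  return List::create(
    _["x"] = X,
    _["f"] = F,
    _["theta_bar"] = THETA_BAR,
    _["theta_p"] = NumericVector(theta.begin(), theta.end()),
    _["bound_counts"] = bound,
    _["free_counts"] = NumericVector(free_count.begin(), free_count.end()),
    _["n_events"] = events,
    _["ended_early"] = ended_early
  );
}
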