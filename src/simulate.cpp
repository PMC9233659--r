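#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Event-driven (Gillespie) simulation of the proliferation process.
//
// State: N agents on sites 1..N, a subset of positions carrying marks.
// Events occur at total rate lambda*N; the event site is uniform on
// {1,...,N}; an unmarked agent is inserted at the site, shifting every
// mark at or right of it one place up.
//
// snap_times must be sorted nondecreasing; the last entry is the horizon.
// A snapshot at time tau records the state after all events with T <= tau
// (half-open convention: events with T <= t_end are applied).
//
// Uses R's RNG (exp_rand/unif_rand), so set.seed() governs reproducibility.
// [[Rcpp::export]]
List cpp_simulate_prolif(double lambda, int n0, IntegerVector marks0,
                         NumericVector snap_times, bool keep_events) {
  std::vector<int> marks(marks0.begin(), marks0.end());
  int ns = snap_times.size();
  List snap_marks(ns);
  IntegerVector snap_n(ns);
  std::vector<double> ev_time;
  std::vector<int> ev_site, ev_n;

  double t = 0.0;
  int N = n0, si = 0;
  unsigned long iter = 0;
  for (;;) {
    double t_next = t + R::exp_rand() / (lambda * (double)N);
    while (si < ns && snap_times[si] < t_next) {
      snap_marks[si] = IntegerVector(marks.begin(), marks.end());
      snap_n[si] = N;
      ++si;
    }
    if (si >= ns) break;  // t_next beyond the horizon: event not applied
    int site = (int)(unif_rand() * N) + 1;
    if (site > N) site = N;
    for (std::vector<int>::iterator it =
             std::lower_bound(marks.begin(), marks.end(), site);
         it != marks.end(); ++it)
      ++(*it);
    ++N;
    t = t_next;
    if (keep_events) {
      ev_time.push_back(t);
      ev_site.push_back(site);
      ev_n.push_back(N);
    }
    if ((++iter & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["marks"] = snap_marks, _["n"] = snap_n);
  if (keep_events) {
    int ne = (int)ev_time.size();
    IntegerVector idx(ne);
    for (int i = 0; i < ne; ++i) idx[i] = i + 1;
    out["events"] = DataFrame::create(
        _["index"] = idx,
        _["time"] = NumericVector(ev_time.begin(), ev_time.end()),
        _["site"] = IntegerVector(ev_site.begin(), ev_site.end()),
        _["n_after"] = IntegerVector(ev_n.begin(), ev_n.end()));
  }
  return out;
}

// Independent Yule-Furry walkers: each start position evolves on its own
// stream (holding time in state k is Exp(lambda*k)).  Returns an
// (n_walkers x n_snapshots) matrix of positions.
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_walks(double lambda, IntegerVector starts,
                                 NumericVector snap_times) {
  int m = starts.size(), ns = snap_times.size();
  IntegerMatrix pos(m, ns);
  for (int w = 0; w < m; ++w) {
    double t = 0.0;
    int k = starts[w], si = 0;
    for (;;) {
      double t_next = t + R::exp_rand() / (lambda * (double)k);
      while (si < ns && snap_times[si] < t_next) pos(w, si++) = k;
      if (si >= ns) break;
      ++k;
      t = t_next;
    }
    Rcpp::checkUserInterrupt();
  }
  return pos;
}

// Implicit-Euler finite differences for the second-order occupancy PDE
//   dC/dt = -lambda d/dx (x C) + (lambda*delta/2) d^2/dx^2 (x C)
// on cell centres x (uniform spacing dx), zero far-field values.
// First-order upwind advection (velocity lambda*x > 0), centred diffusion;
// both terms are in flux/telescoping form, so interior mass is conserved.
// The tridiagonal system (I - dt A) C^{n+1} = C^n is solved by the Thomas
// algorithm.  Snapshots at t_out; step size <= dt_max within each interval.
// [[Rcpp::export]]
List cpp_pde_hywood(double lambda, double delta, NumericVector x, double dx,
                    NumericVector t_out, double dt_max, NumericVector c0) {
  int n = x.size(), nt = t_out.size();
  NumericMatrix field(n, nt);
  NumericVector mass(nt);
  std::vector<double> C(c0.begin(), c0.end());
  std::vector<double> sub(n), dia(n), sup(n), cp(n), dp(n);
  double nu = 0.5 * lambda * delta;  // diffusion coefficient multiplier
  double t = 0.0;

  for (int k = 0; k < nt; ++k) {
    double span = t_out[k] - t;
    if (span > 1e-14) {
      int nsteps = (int)std::ceil(span / dt_max);
      double dt = span / nsteps;
      for (int i = 0; i < n; ++i) {
        double xm = (i > 0) ? x[i - 1] : 0.0;
        double xp = (i < n - 1) ? x[i + 1] : 0.0;
        sub[i] = -dt * xm * (lambda / dx + nu / (dx * dx));
        dia[i] = 1.0 + dt * x[i] * (lambda / dx + 2.0 * nu / (dx * dx));
        sup[i] = -dt * xp * (nu / (dx * dx));
      }
      for (int s = 0; s < nsteps; ++s) {
        cp[0] = sup[0] / dia[0];
        dp[0] = C[0] / dia[0];
        for (int i = 1; i < n; ++i) {
          double den = dia[i] - sub[i] * cp[i - 1];
          cp[i] = sup[i] / den;
          dp[i] = (C[i] - sub[i] * dp[i - 1]) / den;
        }
        C[n - 1] = dp[n - 1];
        for (int i = n - 2; i >= 0; --i) C[i] = dp[i] - cp[i] * C[i + 1];
      }
      t = t_out[k];
      Rcpp::checkUserInterrupt();
    }
    double ms = 0.0;
    for (int i = 0; i < n; ++i) {
      field(i, k) = C[i];
      ms += C[i];
    }
    mass[k] = ms * dx;
  }
  return List::create(_["field"] = field, _["mass"] = mass);
}
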