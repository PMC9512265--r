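#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dominance discrimination weight sigma(x) = 1/(1+exp(lambda*x)).
static inline double sig(double x, double lambda) {
  double z = lambda * x;
  if (z > 35.0) return 0.0;
  if (z < -35.0) return 1.0;
  return 1.0 / (1.0 + std::exp(z));
}

// Weighted pick: index i with probability w_i / sum(w). 'total' is sum(w).
template <typename W>
static inline int pick(const W& w, int N, double total) {
  double u = unif_rand() * total, c = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    c += w(i);
    if (u <= c) return i;
  }
  return N - 1;
}

// Event-driven simulation of the reduced colony model.
// State: n_i product counts. Channels (scaled units, delta = 1):
//   production   rate mu per insect               (n_i -> n_i + 1)
//   degradation  rate n_i per insect              (n_i -> n_i - 1)
//   interaction  i subdominant to j at rate
//                alpha * (n_i/n_ss)(n_j/n_ss) sigma((n_i-n_j)/n_ss)
//                (n_i -> max(n_i - m, 0))
// The interaction channel is sampled by thinning with envelope
// alpha * (S^2 - Q)/n_ss^2 (S = sum n, Q = sum n^2), exact since sigma <= 1.
// Uses R's RNG: callers set.seed() for reproducibility.
// [[Rcpp::export]]
List cpp_simulate_reduced(IntegerVector n0, double mu, double alpha,
                          double lambda, int m, int n_ss, double horizon,
                          double sample_dt, bool record_events) {
  const int N = n0.size();
  std::vector<double> n(N);
  for (int i = 0; i < N; ++i) n[i] = n0[i];

  double S = 0.0, Q = 0.0;
  for (int i = 0; i < N; ++i) { S += n[i]; Q += n[i] * n[i]; }
  const double inv2 = 1.0 / ((double)n_ss * (double)n_ss);

  const int n_samp = (int)std::floor(horizon / sample_dt + 1e-9) + 1;
  NumericVector times(n_samp);
  IntegerMatrix snap(n_samp, N);
  IntegerVector int_counts(n_samp);  // interactions in (t_{k-1}, t_k]
  std::vector<double> ev_t; std::vector<int> ev_dom, ev_sub;

  int k = 0;  // next sample index
  double t = 0.0;
  long long steps = 0;
  auto take_samples = [&](double upto) {
    while (k < n_samp && k * sample_dt <= upto + 1e-12) {
      times[k] = k * sample_dt;
      for (int i = 0; i < N; ++i) snap(k, i) = (int)n[i];
      ++k;
    }
  };

  while (t < horizon) {
    double a_prod = mu * N;
    double a_deg = S;
    double a_int = alpha * (S * S - Q) * inv2;
    if (a_int < 0) a_int = 0;
    double a_tot = a_prod + a_deg + a_int;
    if (a_tot <= 0) { t = horizon; break; }
    t += exp_rand() / a_tot;
    take_samples(std::min(t, horizon));
    if (t >= horizon) break;

    double u = unif_rand() * a_tot;
    if (u < a_prod) {
      int i = (int)(unif_rand() * N); if (i >= N) i = N - 1;
      S += 1.0; Q += 2.0 * n[i] + 1.0; n[i] += 1.0;
    } else if (u < a_prod + a_deg) {
      int i = pick([&](int i) { return n[i]; }, N, S);
      S -= 1.0; Q += -2.0 * n[i] + 1.0; n[i] -= 1.0;
    } else {
      // candidate ordered pair (i sub, j dom) with weight n_i * n_j, i != j
      int i = pick([&](int i) { return n[i] * (S - n[i]); }, N, S * S - Q);
      double tot_j = S - n[i];
      if (tot_j > 0) {
        int j = pick([&](int j) { return j == i ? 0.0 : n[j]; }, N, tot_j);
        if (j != i && unif_rand() < sig((n[i] - n[j]) / n_ss, lambda)) {
          double d = std::min((double)m, n[i]);
          S -= d; Q += d * d - 2.0 * n[i] * d; n[i] -= d;
          if (k < n_samp) int_counts[k] += 1;
          if (record_events) {
            ev_t.push_back(t); ev_dom.push_back(j + 1); ev_sub.push_back(i + 1);
          }
        }
      }
    }
    // refresh running sums against float drift
    if (++steps % 1000000LL == 0) {
      S = 0.0; Q = 0.0;
      for (int i = 0; i < N; ++i) { S += n[i]; Q += n[i] * n[i]; }
    }
  }
  take_samples(horizon);

  return List::create(
    _["times"] = times, _["n"] = snap, _["int_counts"] = int_counts,
    _["events"] = DataFrame::create(_["time"] = wrap(ev_t),
                                    _["dominant"] = wrap(ev_dom),
                                    _["subdominant"] = wrap(ev_sub)));
}

// Event-driven simulation of the full colony model with explicit repression
// state q_i in {0, 1}. Channels:
//   production        rate mu * (1 - q_i)
//   degradation       rate delta * n_i
//   repression decay  q_i: 1 -> 0 at rate Gamma (Markovian) or after a
//                     deterministic refractory period 1/Gamma
//   interaction       q_i: 0 -> 1 at rate omega * sum_j K(r_i, r_j);
//                     encounters involving already-repressed insects are
//                     recorded but change no state.
// [[Rcpp::export]]
List cpp_simulate_full(IntegerVector n0, IntegerVector q0, double mu,
                       double delta, double Gamma, double omega, double lambda,
                       int n_ss, double horizon, double sample_dt,
                       bool deterministic_refractory, bool record_events) {
  const int N = n0.size();
  std::vector<double> n(N); std::vector<int> q(N);
  std::vector<double> unrep(N, R_PosInf);  // scheduled unrepression times
  for (int i = 0; i < N; ++i) { n[i] = n0[i]; q[i] = q0[i]; }
  const double refract = (Gamma > 0) ? 1.0 / Gamma : R_PosInf;

  double S = 0.0, Q = 0.0; int n_rep = 0;
  for (int i = 0; i < N; ++i) {
    S += n[i]; Q += n[i] * n[i];
    if (q[i]) { n_rep++; if (deterministic_refractory) unrep[i] = refract; }
  }
  const double inv2 = 1.0 / ((double)n_ss * (double)n_ss);

  const int n_samp = (int)std::floor(horizon / sample_dt + 1e-9) + 1;
  NumericVector times(n_samp);
  IntegerMatrix snap(n_samp, N), qsnap(n_samp, N);
  IntegerVector int_counts(n_samp);
  std::vector<double> ev_t; std::vector<int> ev_dom, ev_sub;

  int k = 0; double t = 0.0; long long steps = 0;
  auto take_samples = [&](double upto) {
    while (k < n_samp && k * sample_dt <= upto + 1e-12) {
      times[k] = k * sample_dt;
      for (int i = 0; i < N; ++i) { snap(k, i) = (int)n[i]; qsnap(k, i) = q[i]; }
      ++k;
    }
  };

  while (t < horizon) {
    double a_prod = mu * (N - n_rep);
    double a_deg = delta * S;
    double a_gam = deterministic_refractory ? 0.0 : Gamma * n_rep;
    double a_int = omega * (S * S - Q) * inv2;
    if (a_int < 0) a_int = 0;
    double a_tot = a_prod + a_deg + a_gam + a_int;

    double t_next = (a_tot > 0) ? t + exp_rand() / a_tot : R_PosInf;
    if (deterministic_refractory && n_rep > 0) {
      double t_sched = R_PosInf; int i_sched = -1;
      for (int i = 0; i < N; ++i)
        if (q[i] && unrep[i] < t_sched) { t_sched = unrep[i]; i_sched = i; }
      if (t_sched <= t_next) {  // deterministic unrepression fires first
        t = t_sched;
        take_samples(std::min(t, horizon));
        if (t >= horizon) break;
        q[i_sched] = 0; unrep[i_sched] = R_PosInf; n_rep--;
        continue;
      }
    }
    if (!R_FINITE(t_next)) { t = horizon; break; }
    t = t_next;
    take_samples(std::min(t, horizon));
    if (t >= horizon) break;

    double u = unif_rand() * a_tot;
    if (u < a_prod) {
      // choose among unrepressed insects uniformly
      int idx = (int)(unif_rand() * (N - n_rep)); if (idx >= N - n_rep) idx = N - n_rep - 1;
      int i = -1, c = -1;
      for (i = 0; i < N; ++i) { if (!q[i]) ++c; if (c == idx) break; }
      S += 1.0; Q += 2.0 * n[i] + 1.0; n[i] += 1.0;
    } else if (u < a_prod + a_deg) {
      int i = pick([&](int i) { return n[i]; }, N, S);
      S -= 1.0; Q += -2.0 * n[i] + 1.0; n[i] -= 1.0;
    } else if (u < a_prod + a_deg + a_gam) {
      int idx = (int)(unif_rand() * n_rep); if (idx >= n_rep) idx = n_rep - 1;
      int i = -1, c = -1;
      for (i = 0; i < N; ++i) { if (q[i]) ++c; if (c == idx) break; }
      q[i] = 0; n_rep--;
    } else {
      int i = pick([&](int i) { return n[i] * (S - n[i]); }, N, S * S - Q);
      double tot_j = S - n[i];
      if (tot_j > 0) {
        int j = pick([&](int j) { return j == i ? 0.0 : n[j]; }, N, tot_j);
        if (j != i && unif_rand() < sig((n[i] - n[j]) / n_ss, lambda)) {
          if (k < n_samp) int_counts[k] += 1;
          if (record_events) {
            ev_t.push_back(t); ev_dom.push_back(j + 1); ev_sub.push_back(i + 1);
          }
          if (!q[i]) {
            q[i] = 1; n_rep++;
            if (deterministic_refractory) unrep[i] = t + refract;
          }
        }
      }
    }
    if (++steps % 1000000LL == 0) {
      S = 0.0; Q = 0.0;
      for (int i = 0; i < N; ++i) { S += n[i]; Q += n[i] * n[i]; }
    }
  }
  take_samples(horizon);

  return List::create(
    _["times"] = times, _["n"] = snap, _["q"] = qsnap,
    _["int_counts"] = int_counts,
    _["events"] = DataFrame::create(_["time"] = wrap(ev_t),
                                    _["dominant"] = wrap(ev_dom),
                                    _["subdominant"] = wrap(ev_sub)));
}
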