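#include <Rcpp.h>
using namespace Rcpp;

// The network is passed in compressed sparse row form: idx has length n+1 and
// nbr[idx[i]..idx[i+1]-1] are the 0-based neighbours of node i. Gene order is
// fixed by the caller (lexicographic), so sweeps are deterministic.
//
// Both samplers maintain, for every node k, the count n1[k] of neighbours
// currently labelled +1 and the weight sum sw1[k] over those neighbours, so a
// single-site update costs O(degree) rather than O(sum of neighbour degrees).

static inline double log_sigmoid(double eta) {
  // log(1/(1+exp(-eta))), stable for large |eta|
  if (eta > 0) {
    return -log1p(std::exp(-eta));
  } else {
    return eta - log1p(std::exp(eta));
  }
}

struct SweepState {
  int n;
  const int *idx, *nbr;
  const double *w;
  std::vector<double> sumw;   // sum of neighbour weights per node
  std::vector<int> deg;
  std::vector<int> n1;        // neighbours labelled +1
  std::vector<double> sw1;    // weight sum over +1 neighbours
  std::vector<int> s;

  SweepState(const IntegerVector &idx_, const IntegerVector &nbr_,
             const NumericVector &w_, const IntegerVector &s0) {
    n = idx_.size() - 1;
    idx = idx_.begin();
    nbr = nbr_.begin();
    w = w_.begin();
    sumw.assign(n, 0.0);
    deg.assign(n, 0);
    n1.assign(n, 0);
    sw1.assign(n, 0.0);
    s.assign(s0.begin(), s0.end());
    for (int i = 0; i < n; ++i) {
      deg[i] = idx[i + 1] - idx[i];
      for (int e = idx[i]; e < idx[i + 1]; ++e) {
        int k = nbr[e];
        sumw[i] += w[k];
        if (s[k] == 1) {
          n1[i] += 1;
          sw1[i] += w[k];
        }
      }
    }
  }

  // linear predictor of the prior full conditional of node i:
  // h + tau1 * X_i1 - tau0 * X_i0
  inline double eta(int i, double h, double tau0, double tau1) const {
    double x1 = w[i] * n1[i] + sw1[i];
    double x0 = w[i] * (deg[i] - n1[i]) + (sumw[i] - sw1[i]);
    return h + tau1 * x1 - tau0 * x0;
  }

  // flip node i to s_new, updating neighbour tallies
  inline void set_state(int i, int s_new) {
    if (s_new == s[i]) return;
    int d = (s_new == 1) ? 1 : -1;
    for (int e = idx[i]; e < idx[i + 1]; ++e) {
      int k = nbr[e];
      n1[k] += d;
      sw1[k] += d * w[i];
    }
    s[i] = s_new;
  }
};

// Systematic-sweep Gibbs sampler for the latent risk states. logem_diff[i] is
// log f(Y_i | S_i = +1) - log f(Y_i | S_i = -1); pass zeros to sample from the
// MRF prior. Returns the fraction of post-burn-in sweeps with S_i = -1 and the
// final state. Uses R's RNG stream.
// [[Rcpp::export(name = ".gibbs_sweeps_cpp")]]
List gibbs_sweeps_cpp(IntegerVector idx, IntegerVector nbr, NumericVector w,
                      double h, double tau0, double tau1,
                      NumericVector logem_diff, IntegerVector s_init,
                      int n_iter, int n_burnin) {
  SweepState st(idx, nbr, w, s_init);
  int n = st.n;
  std::vector<double> neg_count(n, 0.0);
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      double eta_full = st.eta(i, h, tau0, tau1) + logem_diff[i];
      double p1 = 1.0 / (1.0 + std::exp(-eta_full));
      int s_new = (unif_rand() < p1) ? 1 : -1;
      st.set_state(i, s_new);
    }
    if (it >= n_burnin) {
      ++kept;
      for (int i = 0; i < n; ++i)
        if (st.s[i] == -1) neg_count[i] += 1.0;
    }
  }
  NumericVector q(n);
  IntegerVector s_final(n);
  for (int i = 0; i < n; ++i) {
    q[i] = (kept > 0) ? neg_count[i] / kept : NA_REAL;
    s_final[i] = st.s[i];
  }
  return List::create(_["q"] = q, _["state"] = s_final, _["kept"] = kept);
}

// Iterated conditional modes: each node is set to the state maximizing
// emission(Y_i|S_i) * Pr(S_i|S_Ni) * prod over neighbours k of
// Pr(S_k | S_i, S_{N_k - i}), with immediate updates in sweep order.
// Ties favour the null label -1.
// [[Rcpp::export(name = ".icm_sweeps_cpp")]]
List icm_sweeps_cpp(IntegerVector idx, IntegerVector nbr, NumericVector w,
                    double h, double tau0, double tau1,
                    NumericVector logem_diff, IntegerVector s_init,
                    int n_sweeps) {
  SweepState st(idx, nbr, w, s_init);
  int n = st.n;
  int changed_total = 0;
  for (int sw = 0; sw < n_sweeps; ++sw) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      // own conditional: log P(+1|.) - log P(-1|.) = eta_i
      double delta = logem_diff[i] + st.eta(i, h, tau0, tau1);
      // neighbour conditionals under the two candidate states of i
      double coup = tau1 + tau0;
      for (int e = st.idx[i]; e < st.idx[i + 1]; ++e) {
        int k = st.nbr[e];
        double shift = coup * (w[k] + w[i]);
        double eta_k_cur = st.eta(k, h, tau0, tau1);
        // eta of k with S_i = +1 / -1
        double eta_plus = (st.s[i] == 1) ? eta_k_cur : eta_k_cur + shift;
        double eta_minus = eta_plus - shift;
        if (st.s[k] == 1) {
          delta += log_sigmoid(eta_plus) - log_sigmoid(eta_minus);
        } else {
          delta += log_sigmoid(-eta_plus) - log_sigmoid(-eta_minus);
        }
      }
      int s_new = (delta > 0) ? 1 : -1;
      if (s_new != st.s[i]) ++changed;
      st.set_state(i, s_new);
    }
    changed_total = changed;
    if (changed == 0) break;
  }
  IntegerVector s_final(n);
  for (int i = 0; i < n; ++i) s_final[i] = st.s[i];
  return List::create(_["state"] = s_final,
                      _["changed_last_sweep"] = changed_total);
}
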