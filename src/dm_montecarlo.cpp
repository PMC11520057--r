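// Monte-Carlo engine for the Dirichlet-multinomial droplet test.
//
// Per iteration one composition theta ~ Dirichlet(alpha * p) is drawn and a
// null count vector is grown one unit at a time by alias sampling from theta,
// with the DM log-likelihood updated incrementally:
//   logL(X + e_g, t+1) - logL(X, t)
//     = log((t+1)/(t+alpha)) + log((X_g + alpha*p_g)/(X_g + 1)).
// Conditional on theta the counts at total t are exactly Multinomial(t,
// theta), so marginally each snapshot is an exact DM(t, alpha*p) draw; only
// snapshots within one iteration are coupled across totals, which does not
// affect the per-total null distribution. At each requested total the running
// log-likelihood is compared with the observed log-likelihoods of the
// droplets at that total.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// Walker alias table over unnormalized weights w (sum s > 0).
struct AliasTable {
  std::vector<double> q;
  std::vector<int> j;

  void build(const std::vector<double>& w, double s) {
    const int n = static_cast<int>(w.size());
    q.assign(n, 0.0);
    j.assign(n, 0);
    std::vector<int> small, large;
    small.reserve(n);
    large.reserve(n);
    std::vector<double> p(n);
    for (int k = 0; k < n; ++k) {
      p[k] = w[k] * n / s;
      if (p[k] < 1.0) small.push_back(k); else large.push_back(k);
    }
    while (!small.empty() && !large.empty()) {
      int a = small.back(); small.pop_back();
      int g = large.back(); large.pop_back();
      q[a] = p[a];
      j[a] = g;
      p[g] = (p[g] + p[a]) - 1.0;
      if (p[g] < 1.0) small.push_back(g); else large.push_back(g);
    }
    while (!large.empty()) { q[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { q[small.back()] = 1.0; small.pop_back(); }
  }

  inline int draw(int n) const {
    double u = unif_rand() * n;
    int k = static_cast<int>(u);
    if (k >= n) k = n - 1;  // guard u == n after rounding
    return (u - k < q[k]) ? k : j[k];
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerVector dm_mc_extreme_counts(NumericVector prop, double alpha,
                                   IntegerVector unique_totals,
                                   NumericVector obs_loglik,
                                   IntegerVector group_starts,
                                   int n_iters, double tie_tol) {
  const int n_feat = prop.size();
  const int n_tot = unique_totals.size();
  const int n_obs = obs_loglik.size();
  if (n_tot == 0 || n_obs == 0) return IntegerVector(n_obs);
  const int t_max = unique_totals[n_tot - 1];

  std::vector<double> ap(n_feat);
  for (int g = 0; g < n_feat; ++g) ap[g] = alpha * prop[g];

  // Likelihood ratios are accumulated as a running product with the log
  // taken out only when the product nears the double range limits; this
  // avoids one std::log per unit count. (t+1)/(t+alpha) and 1/(c+1) are
  // tabulated once.
  std::vector<double> stepratio(t_max);
  for (int t = 0; t < t_max; ++t)
    stepratio[t] = (t + 1.0) / (t + alpha);
  std::vector<double> inv_cp1(t_max + 1);
  for (int c = 0; c <= t_max; ++c) inv_cp1[c] = 1.0 / (c + 1.0);

  std::vector<double> theta(n_feat);
  std::vector<int> counts(n_feat, 0);
  std::vector<int> touched;
  touched.reserve(std::min(n_feat, t_max));
  AliasTable alias;
  IntegerVector m_c(n_obs);

  for (int iter = 0; iter < n_iters; ++iter) {
    if ((iter & 127) == 0) checkUserInterrupt();

    double s = 0.0;
    for (int g = 0; g < n_feat; ++g) {
      theta[g] = R::rgamma(ap[g], 1.0);
      s += theta[g];
    }
    if (!(s > 0.0)) {  // all gamma draws underflowed: fall back to p itself
      for (int g = 0; g < n_feat; ++g) theta[g] = prop[g];
      s = 1.0;
    }
    alias.build(theta, s);

    for (size_t k = 0; k < touched.size(); ++k) counts[touched[k]] = 0;
    touched.clear();

    double ll = 0.0;
    double acc = 1.0;
    int t = 0;
    for (int u = 0; u < n_tot; ++u) {
      const int target = unique_totals[u];
      while (t < target) {
        const int g = alias.draw(n_feat);
        const int c = counts[g];
        acc *= stepratio[t] * (c + ap[g]) * inv_cp1[c];
        if (acc < 1e-280 || acc > 1e280) {
          ll += std::log(acc);
          acc = 1.0;
        }
        if (c == 0) touched.push_back(g);
        ++counts[g];
        ++t;
      }
      const double ll_here = ll + std::log(acc);
      for (int k = group_starts[u]; k < group_starts[u + 1]; ++k) {
        if (ll_here <= obs_loglik[k] + tie_tol) ++m_c[k];
      }
    }
  }
  return m_c;
}
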