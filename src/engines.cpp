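// Sequential Monte Carlo and Gibbs engines for the fixed-component
// (trained) approximation: cluster means are collapsed analytically, so a
// hypothesis is just the discrete item->cluster and cluster->component
// assignment.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct PredCache {
  bool ready = false;
  mat V;        // posterior mean covariance at m members
  mat predinv;  // inverse of (Sigma + V)
  double logdet;
};

// One fixed-covariance component set plus the mean-prior hyperparameters.
struct Engine {
  int D, J;
  double sigma_r2, alpha, alpha_c;
  vec omega;
  std::vector<mat> Sigma, Sinv;
  std::vector<std::vector<PredCache>> cache;  // [j][m]
  int n_labels;

  Engine(const cube& comps, const vec& omega_, double sigma_r2_,
         double alpha_, double alpha_c_, int n_labels_, int max_m)
      : D(comps.n_rows), J(comps.n_slices), sigma_r2(sigma_r2_),
        alpha(alpha_), alpha_c(alpha_c_), omega(omega_),
        n_labels(n_labels_) {
    for (int j = 0; j < J; ++j) {
      mat S = comps.slice(j);
      Sigma.push_back(S);
      Sinv.push_back(inv_sympd(S));
      cache.emplace_back(max_m + 2);
    }
  }

  const PredCache& pc(int j, int m) {
    PredCache& c = cache[j][m];
    if (!c.ready) {
      mat prior_prec = eye(D, D) / sigma_r2;
      if (m == 0)
        c.V = sigma_r2 * eye(D, D);
      else
        c.V = inv_sympd(prior_prec + m * Sinv[j]);
      mat P = Sigma[j] + c.V;
      c.predinv = inv_sympd(P);
      double sign;
      log_det(c.logdet, sign, P);
      c.ready = true;
    }
    return c;
  }

  // Collapsed-mean predictive log density of x for a cluster with m members
  // summing to s under component j.
  double logpred(int j, int m, const vec& s, const vec& x) {
    const PredCache& c = pc(j, m);
    vec mu = (m == 0) ? omega
                      : vec(c.V * (omega / sigma_r2 + Sinv[j] * s));
    vec d = x - mu;
    double q = dot(d, c.predinv * d);
    return -0.5 * (D * std::log(2.0 * M_PI) + c.logdet + q);
  }

  // Hierarchical-CRP component probabilities in one context with counts cc.
  vec comp_probs(const vec& cc) const {
    if (!std::isfinite(alpha_c)) return vec(J, fill::value(1.0 / J));
    vec score = cc + alpha_c / J;
    return score / accu(score);
  }
};

double logsumexp(const std::vector<double>& v) {
  double mx = -datum::inf;
  for (double x : v) mx = std::max(mx, x);
  if (!std::isfinite(mx)) return mx;
  double s = 0;
  for (double x : v) s += std::exp(x - mx);
  return mx + std::log(s);
}

struct Particle {
  std::vector<int> z;          // item -> cluster
  std::vector<int> comp, lab;  // per cluster
  std::vector<int> m;
  std::vector<vec> s;
  vec ccount;  // context-level per-component cluster counts

  explicit Particle(int J) : ccount(J, fill::zeros) {}

  void add_item(int item, int cluster, int j, int label, const vec& x) {
    if (cluster < 0) {
      comp.push_back(j);
      lab.push_back(label);
      m.push_back(0);
      s.push_back(zeros<vec>(x.n_elem));
      ccount(j) += 1;
      cluster = comp.size() - 1;
    }
    m[cluster] += 1;
    s[cluster] += x;
    if ((int)z.size() <= item) z.resize(item + 1, -1);
    z[item] = cluster;
  }
};

}  // namespace

// Particle filter over labeled (or unlabeled, label = -1) trials.
// components: D x D x J cube; labels: 0-based ints or -1; returns per-trial
// label probabilities (pre-feedback) and the final particle set.
// [[Rcpp::export(name = ".pf_run_cpp")]]
Rcpp::List pf_run_cpp(const arma::mat& X, const Rcpp::IntegerVector& labels,
                      const arma::cube& components, const arma::vec& omega,
                      double sigma_r2, double alpha, double alpha_c,
                      int n_labels, int n_particles,
                      double resample_threshold, int seed) {
  const int n = X.n_rows;
  Engine eng(components, omega, sigma_r2, alpha, alpha_c, n_labels, n);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> runif(0.0, 1.0);

  std::vector<Particle> ps(n_particles, Particle(eng.J));
  vec logw(n_particles, fill::zeros);
  mat responses(n, std::max(n_labels, 1), fill::zeros);

  for (int t = 0; t < n; ++t) {
    vec x = X.row(t).t();
    int lab = labels[t];
    // normalized particle weights
    vec w = exp(logw - logw.max());
    w /= accu(w);

    for (int p = 0; p < n_particles; ++p) {
      Particle& pa = ps[p];
      int K = pa.comp.size();
      vec pcomp = eng.comp_probs(pa.ccount);
      std::vector<double> lw_clu(K);
      for (int k = 0; k < K; ++k)
        lw_clu[k] = std::log((double)pa.m[k]) +
                    eng.logpred(pa.comp[k], pa.m[k], pa.s[k], x);
      std::vector<double> lw_new(eng.J, -datum::inf);
      for (int j = 0; j < eng.J; ++j)
        if (pcomp(j) > 0)
          lw_new[j] = std::log(alpha) + std::log(pcomp(j)) +
                      eng.logpred(j, 0, x, x);  // s unused at m = 0

      if (n_labels > 0) {
        // pre-feedback response: mass per label + new mass spread uniformly
        std::vector<double> all(lw_clu);
        all.insert(all.end(), lw_new.begin(), lw_new.end());
        double lz = logsumexp(all);
        vec resp(n_labels, fill::zeros);
        for (int k = 0; k < K; ++k)
          if (pa.lab[k] >= 0) resp(pa.lab[k]) += std::exp(lw_clu[k] - lz);
        double newmass = 0;
        for (int j = 0; j < eng.J; ++j)
          newmass += std::exp(lw_new[j] - lz);
        resp += newmass / n_labels;
        responses.row(t) += (w(p) * resp).t();
      }

      // propagate by the exact conditional given the revealed label
      std::vector<double> lw_opt;
      std::vector<int> opt_cluster, opt_comp;
      for (int k = 0; k < K; ++k) {
        if (lab >= 0 && pa.lab[k] != lab) continue;
        lw_opt.push_back(lw_clu[k]);
        opt_cluster.push_back(k);
        opt_comp.push_back(pa.comp[k]);
      }
      double lab_base = (lab >= 0 && n_labels > 0)
                            ? -std::log((double)n_labels) : 0.0;
      for (int j = 0; j < eng.J; ++j) {
        if (!std::isfinite(lw_new[j])) continue;
        lw_opt.push_back(lw_new[j] + lab_base);
        opt_cluster.push_back(-1);
        opt_comp.push_back(j);
      }
      double lz = logsumexp(lw_opt);
      logw(p) += lz;  // incremental marginal weight (optimal proposal)
      double u = runif(rng), acc = 0;
      int pick = lw_opt.size() - 1;
      for (size_t o = 0; o < lw_opt.size(); ++o) {
        acc += std::exp(lw_opt[o] - lz);
        if (u <= acc) { pick = o; break; }
      }
      pa.add_item(t, opt_cluster[pick], opt_comp[pick], lab, x);
    }

    // weight degeneracy guard and systematic resampling
    if (!logw.is_finite()) logw.zeros();
    vec wn = exp(logw - logw.max());
    wn /= accu(wn);
    double ess = 1.0 / accu(square(wn));
    if (ess < resample_threshold * n_particles && t < n - 1) {
      std::vector<Particle> nps;
      nps.reserve(n_particles);
      double u0 = runif(rng) / n_particles;
      double cum = 0;
      int i = 0;
      for (int p = 0; p < n_particles; ++p) {
        double target = u0 + (double)p / n_particles;
        while (cum + wn(i) < target && i < n_particles - 1) cum += wn(i++);
        nps.push_back(ps[i]);
      }
      ps = std::move(nps);
      logw.zeros();
    }
  }

  vec wfin = exp(logw - logw.max());
  wfin /= accu(wfin);
  Rcpp::IntegerMatrix zmat(n_particles, n);
  Rcpp::List comps_out(n_particles);
  for (int p = 0; p < n_particles; ++p) {
    for (int t = 0; t < n; ++t) zmat(p, t) = ps[p].z[t] + 1;
    comps_out[p] = Rcpp::IntegerVector(ps[p].comp.begin(), ps[p].comp.end());
  }
  return Rcpp::List::create(
      Rcpp::Named("responses") = responses,
      Rcpp::Named("z") = zmat,
      Rcpp::Named("cluster_components") = comps_out,
      Rcpp::Named("weights") = wfin);
}

// Collapsed Gibbs sampler over (z, u) with fixed components, for small
// stimulus sets. Returns the partition after every post-burn-in sweep.
// [[Rcpp::export(name = ".gibbs_fixed_cpp")]]
Rcpp::List gibbs_fixed_cpp(const arma::mat& X,
                           const Rcpp::IntegerVector& labels,
                           const arma::cube& components,
                           const arma::vec& omega, double sigma_r2,
                           double alpha, double alpha_c, int n_labels,
                           int n_sweeps, int burn_in, int seed) {
  const int n = X.n_rows;
  Engine eng(components, omega, sigma_r2, alpha, alpha_c, n_labels, n);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> runif(0.0, 1.0);

  // state: one cluster per item, components drawn sequentially from prior
  std::vector<int> z(n), comp;
  std::vector<int> lab;
  vec ccount(eng.J, fill::zeros);
  for (int i = 0; i < n; ++i) {
    vec pcomp = eng.comp_probs(ccount);
    double u = runif(rng), acc = 0;
    int j = eng.J - 1;
    for (int jj = 0; jj < eng.J; ++jj) {
      acc += pcomp(jj);
      if (u <= acc) { j = jj; break; }
    }
    z[i] = i;
    comp.push_back(j);
    lab.push_back(labels[i]);
    ccount(j) += 1;
  }

  auto cluster_members = [&](int k) {
    std::vector<int> out;
    for (int i = 0; i < n; ++i)
      if (z[i] == k) out.push_back(i);
    return out;
  };

  // chain-rule marginal log likelihood of a member set under component j
  auto clu_loglik = [&](const std::vector<int>& idx, int j) {
    double ll = 0;
    vec s = zeros<vec>(eng.D);
    int m = 0;
    for (int i : idx) {
      vec x = X.row(i).t();
      ll += eng.logpred(j, m, s, x);
      s += x;
      m += 1;
    }
    return ll;
  };

  Rcpp::IntegerMatrix out(std::max(n_sweeps - burn_in, 0), n);
  int row = 0;
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    // --- update z item by item
    for (int i = 0; i < n; ++i) {
      int old = z[i];
      z[i] = -1;
      std::vector<int> mem = cluster_members(old);
      if (mem.empty()) {  // cluster died: drop it, relabel
        ccount(comp[old]) -= 1;
        comp.erase(comp.begin() + old);
        lab.erase(lab.begin() + old);
        for (int t = 0; t < n; ++t)
          if (z[t] > old) z[t] -= 1;
      }
      int K = comp.size();
      vec x = X.row(i).t();
      vec pcomp = eng.comp_probs(ccount);
      std::vector<double> lw;
      std::vector<int> opt_cluster, opt_comp;
      for (int k = 0; k < K; ++k) {
        if (labels[i] >= 0 && lab[k] >= 0 && lab[k] != labels[i]) continue;
        std::vector<int> mk = cluster_members(k);
        vec s = zeros<vec>(eng.D);
        for (int t : mk) s += X.row(t).t();
        lw.push_back(std::log((double)mk.size()) +
                     eng.logpred(comp[k], mk.size(), s, x));
        opt_cluster.push_back(k);
        opt_comp.push_back(comp[k]);
      }
      double lab_base = (labels[i] >= 0 && n_labels > 0)
                            ? -std::log((double)n_labels) : 0.0;
      for (int j = 0; j < eng.J; ++j) {
        if (pcomp(j) <= 0) continue;
        lw.push_back(std::log(alpha) + std::log(pcomp(j)) + lab_base +
                     eng.logpred(j, 0, x, x));
        opt_cluster.push_back(-1);
        opt_comp.push_back(j);
      }
      double lz = logsumexp(lw);
      double u = runif(rng), acc = 0;
      int pick = lw.size() - 1;
      for (size_t o = 0; o < lw.size(); ++o) {
        acc += std::exp(lw[o] - lz);
        if (u <= acc) { pick = o; break; }
      }
      if (opt_cluster[pick] < 0) {
        comp.push_back(opt_comp[pick]);
        lab.push_back(labels[i]);
        ccount(opt_comp[pick]) += 1;
        z[i] = comp.size() - 1;
      } else {
        z[i] = opt_cluster[pick];
      }
    }
    // --- update u cluster by cluster
    for (size_t k = 0; k < comp.size(); ++k) {
      ccount(comp[k]) -= 1;
      vec pcomp = eng.comp_probs(ccount);
      std::vector<int> mk = cluster_members(k);
      std::vector<double> lw(eng.J, -datum::inf);
      for (int j = 0; j < eng.J; ++j)
        if (pcomp(j) > 0)
          lw[j] = std::log(pcomp(j)) + clu_loglik(mk, j);
      double lz = logsumexp(lw);
      double u = runif(rng), acc = 0;
      int pick = eng.J - 1;
      for (int j = 0; j < eng.J; ++j) {
        acc += std::exp(lw[j] - lz);
        if (u <= acc) { pick = j; break; }
      }
      comp[k] = pick;
      ccount(pick) += 1;
    }
    if (sweep >= burn_in) {
      for (int i = 0; i < n; ++i) out(row, i) = z[i] + 1;
      ++row;
    }
  }
  return Rcpp::List::create(Rcpp::Named("z") = out);
}
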