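#include <Rcpp.h>
using namespace Rcpp;

// ---- union-find over the ddCRP join graph -------------------------------

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Connected components of the (undirected closure of the) join graph.
// joins: n x R integer matrix, 1-based; column r holds the sample each of
// the n samples joins in draw r. Returns n x R matrix of cluster labels,
// canonical (first-appearance) order 1..K per column.
// [[Rcpp::export]]
IntegerMatrix cpp_components(IntegerMatrix joins) {
  const int n = joins.nrow(), R = joins.ncol();
  IntegerMatrix labels(n, R);
  std::vector<int> parent(n), relab(n);
  for (int r = 0; r < R; ++r) {
    for (int i = 0; i < n; ++i) parent[i] = i;
    for (int i = 0; i < n; ++i) {
      int j = joins(i, r) - 1;
      int ri = uf_find(parent, i), rj = uf_find(parent, j);
      if (ri != rj) parent[ri] = rj;
    }
    std::fill(relab.begin(), relab.end(), 0);
    int next = 0;
    for (int i = 0; i < n; ++i) {
      int root = uf_find(parent, i);
      if (relab[root] == 0) relab[root] = ++next;
      labels(i, r) = relab[root];
    }
  }
  return labels;
}

// Per-draw cluster summaries. labels: n x R canonical labels; x: n sample
// positions. Returns K per draw plus size and centroid matrices padded to
// the maximal K (sizes 0, centroids NA beyond K).
// [[Rcpp::export]]
List cpp_cluster_stats(IntegerMatrix labels, NumericVector x) {
  const int n = labels.nrow(), R = labels.ncol();
  IntegerVector K(R);
  int kmax = 0;
  for (int r = 0; r < R; ++r) {
    int k = 0;
    for (int i = 0; i < n; ++i) k = std::max(k, labels(i, r));
    K[r] = k;
    kmax = std::max(kmax, k);
  }
  IntegerMatrix sizes(R, kmax);
  NumericMatrix centroids(R, kmax);
  std::fill(centroids.begin(), centroids.end(), NA_REAL);
  std::vector<double> sum(kmax);
  std::vector<int> cnt(kmax);
  for (int r = 0; r < R; ++r) {
    const int k = K[r];
    std::fill(sum.begin(), sum.begin() + k, 0.0);
    std::fill(cnt.begin(), cnt.begin() + k, 0);
    for (int i = 0; i < n; ++i) {
      int lab = labels(i, r) - 1;
      sum[lab] += x[i];
      cnt[lab] += 1;
    }
    for (int j = 0; j < k; ++j) {
      sizes(r, j) = cnt[j];
      centroids(r, j) = sum[j] / cnt[j];
    }
  }
  return List::create(_["K"] = K, _["sizes"] = sizes,
                      _["centroids"] = centroids);
}

// Per-draw Mean read-outs M* for a padded ensemble. C and W are R x Kmax
// (centroids NA and weights 0 beyond each draw's K). Applies the power
// transform w^alpha and/or the Gaussian-distance shunting denominator.
// [[Rcpp::export]]
NumericVector cpp_mean_points(NumericMatrix C, NumericMatrix W,
                              double alpha, double sigma_li,
                              bool use_power, bool use_li) {
  const int R = C.nrow(), kmax = C.ncol();
  NumericVector out(R);
  const double s2 = 2.0 * sigma_li * sigma_li;
  std::vector<double> th(kmax);
  for (int r = 0; r < R; ++r) {
    int K = 0;
    while (K < kmax && !NumericMatrix::is_na(C(r, K))) ++K;
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double num = use_power ? std::pow(W(r, k), alpha) : W(r, k);
      double den = 1.0;
      if (use_li) {
        den = 0.0;
        for (int l = 0; l < K; ++l) {
          double d = C(r, l) - C(r, k);
          den += W(r, l) * std::exp(-(d * d) / s2);
        }
        if (den <= 0.0) den = 1.0;
      }
      th[k] = num / den;
      tot += th[k];
    }
    double m = 0.0;
    for (int k = 0; k < K; ++k) m += C(r, k) * th[k] / tot;
    out[r] = m;
  }
  return out;
}

// ---- DPMM ideal observer: Gibbs sampler ---------------------------------

static double rtruncnorm1(double mean, double sd, double lo, double hi) {
  double plo = R::pnorm(lo, mean, sd, 1, 0);
  double phi = R::pnorm(hi, mean, sd, 1, 0);
  if (phi - plo < 1e-12) {
    // numerically degenerate tail; clamp to nearest bound
    return (mean < lo) ? lo : ((mean > hi) ? hi : mean);
  }
  double u = R::runif(plo, phi);
  double z = R::qnorm(u, mean, sd, 1, 0);
  if (z < lo) z = lo;
  if (z > hi) z = hi;
  return z;
}

// Non-conjugate Gibbs sampler (auxiliary-component assignment updates with
// m_aux extra components) for a DP mixture of equal-precision Gaussians with
// uniform base measure on [a, b]. Shared precision tau ~ Gamma(alpha_tau,
// rate beta_tau), beta_tau ~ Gamma(1, 1), concentration alpha ~
// Gamma(alpha_c, 1) resampled by the beta-augmentation scheme.
// Caller must seed R's RNG. Returns retained per-draw mixture means/modes,
// trace vectors, and the posterior-averaged mixture density on `grid`.
// [[Rcpp::export]]
List cpp_dpmm_gibbs(NumericVector x, double a, double b, double alpha_tau,
                    double alpha_c, int n_chains, int n_iter, int burn_in,
                    int m_aux, NumericVector grid) {
  const int N = x.size(), G = grid.size();
  const int keep_per_chain = n_iter - burn_in;
  const int n_keep = n_chains * keep_per_chain;
  NumericVector d_mean(n_keep), d_mode(n_keep), d_alpha(n_keep),
      d_tau(n_keep), d_btau(n_keep);
  IntegerVector d_K(n_keep);
  NumericVector avg_density(G);
  int keep = 0;

  for (int chain = 0; chain < n_chains; ++chain) {
    // init: one cluster holding everything
    std::vector<int> z(N, 0);
    std::vector<double> mu;
    std::vector<int> nk;
    double xbar = Rcpp::mean(x), xvar = Rcpp::var(x);
    mu.push_back(std::min(std::max(xbar, a), b));
    nk.push_back(N);
    double tau = 1.0 / std::max(xvar, 1e-6);
    double beta_tau = 1.0, alpha = 1.0;

    std::vector<double> prob, mu_aux;
    for (int it = 0; it < n_iter; ++it) {
      // 1) assignments, Neal's auxiliary-component scheme
      for (int i = 0; i < N; ++i) {
        int zi = z[i];
        nk[zi] -= 1;
        double orphan_mu = mu[zi];
        bool was_singleton = (nk[zi] == 0);
        if (was_singleton) {  // drop empty cluster (swap with last)
          int last = (int)mu.size() - 1;
          if (zi != last) {
            mu[zi] = mu[last];
            nk[zi] = nk[last];
            for (int j = 0; j < N; ++j)
              if (z[j] == last) z[j] = zi;
          }
          mu.pop_back();
          nk.pop_back();
        }
        int K = (int)mu.size();
        prob.assign(K + m_aux, 0.0);
        mu_aux.assign(m_aux, 0.0);
        double sd = 1.0 / std::sqrt(tau);
        for (int k = 0; k < K; ++k)
          prob[k] = nk[k] * R::dnorm(x[i], mu[k], sd, 0);
        for (int m = 0; m < m_aux; ++m) {
          // if i was a singleton, its old mu is reused for one auxiliary
          mu_aux[m] = (was_singleton && m == 0) ? orphan_mu : R::runif(a, b);
          prob[K + m] = (alpha / m_aux) * R::dnorm(x[i], mu_aux[m], sd, 0);
        }
        double tot = 0.0;
        for (double p : prob) tot += p;
        double u = R::runif(0.0, tot);
        int pick = 0;
        double acc = prob[0];
        while (acc < u && pick < K + m_aux - 1) acc += prob[++pick];
        if (pick < K) {
          z[i] = pick;
          nk[pick] += 1;
        } else {
          mu.push_back(mu_aux[pick - K]);
          nk.push_back(1);
          z[i] = K;
        }
      }
      int K = (int)mu.size();
      // 2) cluster means: truncated-normal conditionals (uniform base)
      std::vector<double> sum(K, 0.0);
      for (int i = 0; i < N; ++i) sum[z[i]] += x[i];
      for (int k = 0; k < K; ++k)
        mu[k] = rtruncnorm1(sum[k] / nk[k], 1.0 / std::sqrt(nk[k] * tau),
                            a, b);
      // 3) shared precision tau
      double ss = 0.0;
      for (int i = 0; i < N; ++i) {
        double d = x[i] - mu[z[i]];
        ss += d * d;
      }
      tau = R::rgamma(alpha_tau + 0.5 * N, 1.0 / (beta_tau + 0.5 * ss));
      // 4) rate hyperparameter beta_tau | tau ~ Gamma(1 + alpha_tau, 1 + tau)
      beta_tau = R::rgamma(1.0 + alpha_tau, 1.0 / (1.0 + tau));
      // 5) concentration alpha: beta-augmentation for Gamma(alpha_c, 1) prior
      double eta = R::rbeta(alpha + 1.0, (double)N);
      double rate = 1.0 - std::log(eta);
      double odds = (alpha_c + K - 1.0) / (N * rate);
      if (R::runif(0.0, 1.0) < odds / (1.0 + odds))
        alpha = R::rgamma(alpha_c + K, 1.0 / rate);
      else
        alpha = R::rgamma(alpha_c + K - 1.0, 1.0 / rate);

      if (it >= burn_in) {
        double mmean = 0.0;
        for (int k = 0; k < K; ++k) mmean += (double)nk[k] / N * mu[k];
        double sd = 1.0 / std::sqrt(tau);
        double best = -1.0, bestx = grid[0];
        for (int g = 0; g < G; ++g) {
          double dens = 0.0;
          for (int k = 0; k < K; ++k)
            dens += (double)nk[k] / N * R::dnorm(grid[g], mu[k], sd, 0);
          avg_density[g] += dens;
          if (dens > best) {  // strict: ties resolve to lowest coordinate
            best = dens;
            bestx = grid[g];
          }
        }
        d_mean[keep] = mmean;
        d_mode[keep] = bestx;
        d_alpha[keep] = alpha;
        d_tau[keep] = tau;
        d_btau[keep] = beta_tau;
        d_K[keep] = K;
        ++keep;
      }
    }
  }
  for (int g = 0; g < G; ++g) avg_density[g] /= n_keep;
  return List::create(
      _["per_draw_mean"] = d_mean, _["per_draw_mode"] = d_mode,
      _["alpha"] = d_alpha, _["tau"] = d_tau, _["beta_tau"] = d_btau,
      _["K"] = d_K, _["avg_density"] = avg_density);
}
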