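// Core MCMC sweeps and change-point search.
// All randomness goes through R's RNG (unif_rand) so set.seed() on the R side
// makes every chain fully reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Binary segmentation (Gaussian mean-change SSE cost, additive penalty)
// ---------------------------------------------------------------------------

// Segment cost: sum of squared deviations about the segment mean, from prefix
// sums. s, e are 0-based inclusive.
static inline double seg_cost(const arma::vec& cs, const arma::vec& cs2,
                              int s, int e) {
  double sum  = cs[e + 1] - cs[s];
  double sum2 = cs2[e + 1] - cs2[s];
  int m = e - s + 1;
  return sum2 - sum * sum / m;
}

// Best admissible split of [s, e]: returns (position j, cost reduction).
// j is the 0-based last index of the left part; -1 if no admissible split.
static void best_split(const arma::vec& cs, const arma::vec& cs2,
                       int s, int e, int min_seg, int& j_best, double& red_best) {
  j_best = -1;
  red_best = -1.0;
  double parent = seg_cost(cs, cs2, s, e);
  for (int j = s + min_seg - 1; j <= e - min_seg; ++j) {
    double red = parent - seg_cost(cs, cs2, s, j) - seg_cost(cs, cs2, j + 1, e);
    if (red > red_best + 1e-12) {  // strict improvement; ties keep leftmost
      red_best = red;
      j_best = j;
    }
  }
}

// Greedy binary segmentation: repeatedly take, across all current segments,
// the split with the largest cost reduction; accept while the reduction
// exceeds `penalty`, up to Q change points. Returns 1-based positions of the
// last index of each left segment, sorted ascending.
// [[Rcpp::export]]
IntegerVector binseg_cpp(NumericVector y, int Q, int min_segment,
                         double penalty) {
  int m = y.size();
  std::vector<int> cps;
  if (m < 2 * min_segment || Q < 1) return IntegerVector(0);

  arma::vec cs(m + 1, arma::fill::zeros), cs2(m + 1, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    cs[i + 1]  = cs[i] + y[i];
    cs2[i + 1] = cs2[i] + y[i] * y[i];
  }

  // active segments as (start, end) pairs
  std::vector<std::pair<int, int> > segs;
  segs.push_back(std::make_pair(0, m - 1));

  while ((int)cps.size() < Q) {
    int pick = -1, j_pick = -1;
    double red_pick = -1.0;
    for (size_t k = 0; k < segs.size(); ++k) {
      int j; double red;
      best_split(cs, cs2, segs[k].first, segs[k].second, min_segment, j, red);
      if (j >= 0 && red > red_pick + 1e-12) {
        red_pick = red; pick = (int)k; j_pick = j;
      }
    }
    if (pick < 0 || red_pick <= penalty) break;
    int s = segs[pick].first, e = segs[pick].second;
    segs.erase(segs.begin() + pick);
    segs.push_back(std::make_pair(s, j_pick));
    segs.push_back(std::make_pair(j_pick + 1, e));
    cps.push_back(j_pick + 1);  // 1-based
  }
  std::sort(cps.begin(), cps.end());
  return wrap(cps);
}

// ---------------------------------------------------------------------------
// Normal-Inverse-Wishart posterior predictive (multivariate Student-t)
// ---------------------------------------------------------------------------

struct NIWPrior {
  arma::vec mu0;
  double lambda0;
  arma::mat Psi0;
  double nu0;
};

// log posterior-predictive density of x given cluster sufficient statistics
// (count nk, sum of members, raw second-moment sum S = sum x x').
static double logpred_stats(const arma::vec& x, double nk,
                            const arma::vec& sum, const arma::mat& S,
                            const NIWPrior& pr) {
  int p = x.n_elem;
  arma::vec mu1;
  arma::mat Psi1;
  double lambda1 = pr.lambda0 + nk;
  double nu1 = pr.nu0 + nk;
  if (nk > 0.5) {
    arma::vec xbar = sum / nk;
    mu1 = (pr.lambda0 * pr.mu0 + nk * xbar) / lambda1;
    arma::mat scatter = S - nk * (xbar * xbar.t());
    arma::vec dv = xbar - pr.mu0;
    Psi1 = pr.Psi0 + scatter + (pr.lambda0 * nk / lambda1) * (dv * dv.t());
    Psi1 = 0.5 * (Psi1 + Psi1.t());
  } else {
    mu1 = pr.mu0;
    Psi1 = pr.Psi0;
  }
  double df = nu1 - p + 1.0;
  arma::mat Sigma = Psi1 * ((lambda1 + 1.0) / (lambda1 * df));
  arma::mat R;
  if (!arma::chol(R, Sigma)) {
    // SPD in exact arithmetic; recover from roundoff with a tiny ridge
    double ridge = 1e-10 * (arma::trace(Sigma) / p + 1e-300);
    if (!arma::chol(R, Sigma + ridge * arma::eye(p, p)))
      stop("posterior predictive scale matrix is not positive definite");
  }
  arma::vec z = arma::solve(arma::trimatl(R.t()), x - mu1);
  double quad = arma::dot(z, z);
  double logdet_half = arma::sum(arma::log(R.diag()));
  return R::lgammafn(0.5 * (df + p)) - R::lgammafn(0.5 * df) -
         0.5 * p * std::log(df * M_PI) - logdet_half -
         0.5 * (df + p) * std::log1p(quad / df);
}

// Exported for cross-checking the R-level predictive against the sampler's.
// [[Rcpp::export]]
double logpred_niw_cpp(arma::vec x, arma::mat cluster_data, arma::vec mu0,
                       double lambda0, arma::mat Psi0, double nu0) {
  NIWPrior pr; pr.mu0 = mu0; pr.lambda0 = lambda0; pr.Psi0 = Psi0; pr.nu0 = nu0;
  int nk = cluster_data.n_rows;
  arma::vec sum(x.n_elem, arma::fill::zeros);
  arma::mat S(x.n_elem, x.n_elem, arma::fill::zeros);
  for (int i = 0; i < nk; ++i) {
    arma::vec xi = cluster_data.row(i).t();
    sum += xi;
    S += xi * xi.t();
  }
  return logpred_stats(x, (double)nk, sum, S, pr);
}

// sample index 0..(K-1) from unnormalized log-weights using R's RNG
static int sample_logweights(const arma::vec& logw) {
  double mx = logw.max();
  if (!std::isfinite(mx)) stop("all assignment weights are zero");
  arma::vec w = arma::exp(logw - mx);
  double tot = arma::accu(w);
  double u = unif_rand() * tot;
  double acc = 0.0;
  for (arma::uword k = 0; k < w.n_elem; ++k) {
    acc += w[k];
    if (u <= acc) return (int)k;
  }
  return (int)w.n_elem - 1;
}

// ---------------------------------------------------------------------------
// TIP collapsed Gibbs sweep
// ---------------------------------------------------------------------------
// prop: modified partition (labels 1..Kp) that fixes the prior weights for the
// whole sweep; the likelihood uses the evolving working assignment with the
// current subject held out.
// [[Rcpp::export]]
IntegerVector tip_sweep_cpp(arma::mat X, arma::mat lambda, IntegerVector prop,
                            IntegerVector order, bool exclude_self,
                            bool use_lik, arma::vec mu0, double lambda0,
                            arma::mat Psi0, double nu0) {
  int n = lambda.n_rows;
  int Kp = 0;
  for (int i = 0; i < n; ++i) Kp = std::max(Kp, prop[i]);
  int p = use_lik ? X.n_cols : 1;

  NIWPrior pr; pr.mu0 = mu0; pr.lambda0 = lambda0; pr.Psi0 = Psi0; pr.nu0 = nu0;

  // prior weight matrix W(i,k) = sum_{j : prop_j = k} lambda(i,j), self included
  arma::mat W(n, Kp, arma::fill::zeros);
  for (int j = 0; j < n; ++j)
    W.col(prop[j] - 1) += lambda.col(j);
  if (exclude_self)
    for (int i = 0; i < n; ++i)
      W(i, prop[i] - 1) -= lambda(i, i);

  IntegerVector w = clone(prop);
  std::vector<double> cnt(Kp, 0.0);
  std::vector<arma::vec> sum(Kp, arma::vec(p, arma::fill::zeros));
  std::vector<arma::mat> S(Kp, arma::mat(p, p, arma::fill::zeros));
  if (use_lik) {
    for (int i = 0; i < n; ++i) {
      int k = w[i] - 1;
      arma::vec xi = X.row(i).t();
      cnt[k] += 1.0; sum[k] += xi; S[k] += xi * xi.t();
    }
  }

  arma::vec logw(Kp);
  for (int pos = 0; pos < n; ++pos) {
    int i = order[pos] - 1;
    arma::vec xi;
    if (use_lik) {
      xi = X.row(i).t();
      int k = w[i] - 1;
      cnt[k] -= 1.0; sum[k] -= xi; S[k] -= xi * xi.t();
    }
    for (int k = 0; k < Kp; ++k) {
      double pw = W(i, k);
      if (pw <= 0.0) { logw[k] = -arma::datum::inf; continue; }
      logw[k] = std::log(pw);
      if (use_lik) logw[k] += logpred_stats(xi, cnt[k], sum[k], S[k], pr);
    }
    int knew = sample_logweights(logw);
    w[i] = knew + 1;
    if (use_lik) {
      cnt[knew] += 1.0; sum[knew] += xi; S[knew] += xi * xi.t();
    }
  }
  return w;
}

// ---------------------------------------------------------------------------
// EPA sequential reseating sweep
// ---------------------------------------------------------------------------
// perm: 1-based permutation of subjects; subjects are seated in this order
// from an empty table arrangement, each by the EPA conditional times the NIW
// posterior predictive of the already-seated members.
// [[Rcpp::export]]
IntegerVector epa_sweep_cpp(arma::mat X, arma::mat lambda, IntegerVector perm,
                            double alpha, double delta, bool use_lik,
                            arma::vec mu0, double lambda0, arma::mat Psi0,
                            double nu0) {
  int n = lambda.n_rows;
  int p = use_lik ? X.n_cols : 1;
  NIWPrior pr; pr.mu0 = mu0; pr.lambda0 = lambda0; pr.Psi0 = Psi0; pr.nu0 = nu0;

  IntegerVector assign(n);
  int K = 0;
  std::vector<double> cnt;
  std::vector<arma::vec> sum;
  std::vector<arma::mat> S;
  std::vector<double> simsum;  // per-cluster similarity to the current subject
  arma::vec zero_sum(p, arma::fill::zeros);
  arma::mat zero_S(p, p, arma::fill::zeros);

  for (int pos = 0; pos < n; ++pos) {
    int i = perm[pos] - 1;
    arma::vec xi;
    if (use_lik) xi = X.row(i).t();
    int knew;
    if (pos == 0) {
      knew = 0;
      K = 1;
      cnt.push_back(0.0); sum.push_back(zero_sum); S.push_back(zero_S);
    } else {
      simsum.assign(K, 0.0);
      double denom = 0.0;
      for (int q = 0; q < pos; ++q) {
        int j = perm[q] - 1;
        simsum[assign[j] - 1] += lambda(i, j);
        denom += lambda(i, j);
      }
      double im1 = (double)pos;  // i - 1 in 1-based position terms
      arma::vec logw(K + 1);
      for (int k = 0; k < K; ++k) {
        double pw = ((im1 - delta * K) / (alpha + im1)) * (simsum[k] / denom);
        logw[k] = (pw > 0.0) ? std::log(pw) : -arma::datum::inf;
        if (use_lik && std::isfinite(logw[k]))
          logw[k] += logpred_stats(xi, cnt[k], sum[k], S[k], pr);
      }
      double pw_new = (alpha + delta * K) / (alpha + im1);
      logw[K] = (pw_new > 0.0) ? std::log(pw_new) : -arma::datum::inf;
      if (use_lik && std::isfinite(logw[K]))
        logw[K] += logpred_stats(xi, 0.0, zero_sum, zero_S, pr);
      knew = sample_logweights(logw);
      if (knew == K) {
        K += 1;
        cnt.push_back(0.0); sum.push_back(zero_sum); S.push_back(zero_S);
      }
    }
    assign[i] = knew + 1;
    if (use_lik) {
      cnt[knew] += 1.0; sum[knew] += xi; S[knew] += xi * xi.t();
    }
  }
  return assign;
}
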