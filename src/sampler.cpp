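#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double plogis_f(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// log logistic CDF, stable for large |x|
static inline double log_plogis(double x) {
  if (x < 0.0) return x - log1p(std::exp(x));
  return -log1p(std::exp(-x));
}

// log P(y = j | eta) for the cumulative logit with thresholds alpha.
// Fast path takes the direct difference of cumulative probabilities; when
// that difference underflows, falls back to the identity
// F(b) - F(a) = F(b) * F(-a) * (1 - exp(a - b)), stable in the far tails.
static inline double log_cat_prob(int y, double eta,
                                  const std::vector<double> &alpha, int J) {
  if (y == 1) return log_plogis(alpha[0] - eta);
  if (y == J) return log_plogis(eta - alpha[J - 2]);
  double b = alpha[y - 1] - eta;  // upper cut
  double a = alpha[y - 2] - eta;  // lower cut
  double p = plogis_f(b) - plogis_f(a);
  if (p > 1e-12) return std::log(p);
  return log_plogis(b) + log_plogis(-a) + log1p(-std::exp(a - b));
}

struct AdaptState {
  std::vector<double> ls;     // log proposal SD
  std::vector<long> n_prop, n_acc;
  double target;
  explicit AdaptState(const NumericVector &sd0, double target_)
      : ls(sd0.size()), n_prop(sd0.size(), 0), n_acc(sd0.size(), 0),
        target(target_) {
    for (int m = 0; m < sd0.size(); ++m) ls[m] = std::log(sd0[m]);
  }
  void record(int m, bool acc, bool adapting) {
    n_prop[m]++;
    if (adapting) {
      double rate = std::min(0.25, 1.0 / std::sqrt((double)n_prop[m]));
      ls[m] += rate * ((acc ? 1.0 : 0.0) - target);
    } else if (acc) {
      n_acc[m]++;
    }
  }
};

// One MCMC chain for the multilevel cumulative-logit model
//   logit P(y <= j) = alpha_j - x'beta - z'gamma - u_k,  u_k ~ N(0, sigma_u2)
// Single-site adaptive random-walk Metropolis for alpha, beta, gamma and u;
// conjugate inverse-gamma Gibbs draw for sigma_u2.  Threshold proposals that
// violate the strict ordering are rejected.  Proposal scales adapt by
// Robbins-Monro toward `target_accept` during burn-in only.  Per-observation
// log-likelihood contributions are cached so subset updates (thresholds,
// binary covariates, city effects) only evaluate their affected rows.
// [[Rcpp::export(name = ".mwg_chain")]]
List mwg_chain(IntegerVector y, NumericMatrix X, NumericMatrix Z,
               IntegerVector city, int K, int J,
               NumericVector alpha0, NumericVector beta0,
               NumericVector gamma0, NumericVector u0, double sigma_u2_0,
               double coef_prior_var, double ig_shape, double ig_scale,
               int n_iter, int burn_in, int thin, double target_accept,
               NumericVector prop_sd0, IntegerVector shift_cols) {
  const int n = y.size();
  const int p = X.ncol();
  const int q = Z.ncol();
  const int nA = J - 1;

  std::vector<double> alpha(alpha0.begin(), alpha0.end());
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> gam(gamma0.begin(), gamma0.end());
  std::vector<double> u(u0.begin(), u0.end());
  double sigma_u2 = sigma_u2_0;

  // per-category and per-city observation index lists
  std::vector<std::vector<int> > by_cat(J), by_city(K);
  for (int i = 0; i < n; ++i) {
    by_cat[y[i] - 1].push_back(i);
    by_city[city[i] - 1].push_back(i);
  }

  // two-valued {0, v} individual design columns get subset updates
  std::vector<bool> sparse_col(p, false);
  std::vector<double> sparse_val(p, 0.0);
  std::vector<std::vector<int> > nz(p);
  for (int j = 0; j < p; ++j) {
    double v = 0.0;
    bool two_valued = true;
    for (int i = 0; i < n && two_valued; ++i) {
      double x = X(i, j);
      if (x == 0.0) continue;
      if (v == 0.0) v = x;
      else if (x != v) two_valued = false;
    }
    if (two_valued && v != 0.0) {
      for (int i = 0; i < n; ++i) if (X(i, j) != 0.0) nz[j].push_back(i);
      if ((double)nz[j].size() < 0.95 * n) {
        sparse_col[j] = true;
        sparse_val[j] = v;
      }
    }
  }

  std::vector<double> eta(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    for (int j = 0; j < q; ++j) e += Z(i, j) * gam[j];
    e += u[city[i] - 1];
    eta[i] = e;
  }
  std::vector<double> llobs(n), buf(n), tmp;
  double llcur = 0.0;
  for (int i = 0; i < n; ++i) {
    llobs[i] = log_cat_prob(y[i], eta[i], alpha, J);
    llcur += llobs[i];
  }

  // joint translation move: shift every threshold and an exclusive 0/1
  // dummy block (e.g. health categories against a tiny reference group) by a
  // common delta.  The likelihood changes only where the block sums to zero,
  // so the move is cheap and decorrelates the thresholds from the block.
  const int n_shift = shift_cols.size();
  std::vector<int> shift_ref;        // rows not covered by the block
  if (n_shift > 0) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int t = 0; t < n_shift; ++t) s += X(i, shift_cols[t]);
      if (s == 0.0) shift_ref.push_back(i);
    }
  }

  AdaptState ad(prop_sd0, target_accept);
  const int m_shift = prop_sd0.size() - 1;   // last slot when block present
  const double inv2V = 0.5 / coef_prior_var;
  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_keep, nA + p + q + K + 1);
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool adapting = iter <= burn_in;

    // thresholds: only categories j and j+1 involve alpha_j
    for (int j = 0; j < nA; ++j) {
      const int m = j;
      double prop = alpha[j] + R::rnorm(0.0, 1.0) * std::exp(ad.ls[m]);
      bool ok = (j == 0 || prop > alpha[j - 1]) &&
                (j == nA - 1 || prop < alpha[j + 1]);
      bool acc = false;
      if (ok) {
        std::vector<double> atmp(alpha);
        atmp[j] = prop;
        double lo = 0.0, ln = 0.0;
        size_t n_aff = by_cat[j].size() + by_cat[j + 1].size();
        tmp.resize(n_aff);
        size_t t = 0;
        for (int c = 0; c < 2; ++c) {
          const std::vector<int> &idx = by_cat[j + c];
          for (size_t s = 0; s < idx.size(); ++s, ++t) {
            int i = idx[s];
            lo += llobs[i];
            tmp[t] = log_cat_prob(y[i], eta[i], atmp, J);
            ln += tmp[t];
          }
        }
        double lr = (ln - lo) - inv2V * (prop * prop - alpha[j] * alpha[j]);
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          alpha[j] = prop;
          t = 0;
          for (int c = 0; c < 2; ++c) {
            const std::vector<int> &idx = by_cat[j + c];
            for (size_t s = 0; s < idx.size(); ++s, ++t) llobs[idx[s]] = tmp[t];
          }
          llcur += ln - lo;
          acc = true;
        }
      }
      ad.record(m, acc, adapting);
    }

    // individual-level coefficients
    for (int j = 0; j < p; ++j) {
      const int m = nA + j;
      double prop = beta[j] + R::rnorm(0.0, 1.0) * std::exp(ad.ls[m]);
      double d = prop - beta[j];
      bool acc;
      if (sparse_col[j]) {
        const std::vector<int> &idx = nz[j];
        double dv = d * sparse_val[j];
        double lo = 0.0, ln = 0.0;
        tmp.resize(idx.size());
        for (size_t t = 0; t < idx.size(); ++t) {
          int i = idx[t];
          lo += llobs[i];
          tmp[t] = log_cat_prob(y[i], eta[i] + dv, alpha, J);
          ln += tmp[t];
        }
        double lr = (ln - lo) - inv2V * (prop * prop - beta[j] * beta[j]);
        acc = std::log(R::runif(0.0, 1.0)) < lr;
        if (acc) {
          beta[j] = prop;
          for (size_t t = 0; t < idx.size(); ++t) {
            eta[idx[t]] += dv;
            llobs[idx[t]] = tmp[t];
          }
          llcur += ln - lo;
        }
      } else {
        double ln = 0.0;
        for (int i = 0; i < n; ++i) {
          buf[i] = log_cat_prob(y[i], eta[i] + d * X(i, j), alpha, J);
          ln += buf[i];
        }
        double lr = (ln - llcur) - inv2V * (prop * prop - beta[j] * beta[j]);
        acc = std::log(R::runif(0.0, 1.0)) < lr;
        if (acc) {
          beta[j] = prop;
          for (int i = 0; i < n; ++i) eta[i] += d * X(i, j);
          llobs.swap(buf);
          llcur = ln;
        }
      }
      ad.record(m, acc, adapting);
    }

    // city-level coefficients (vary over all observations through Z)
    for (int j = 0; j < q; ++j) {
      const int m = nA + p + j;
      double prop = gam[j] + R::rnorm(0.0, 1.0) * std::exp(ad.ls[m]);
      double d = prop - gam[j];
      double ln = 0.0;
      for (int i = 0; i < n; ++i) {
        buf[i] = log_cat_prob(y[i], eta[i] + d * Z(i, j), alpha, J);
        ln += buf[i];
      }
      double lr = (ln - llcur) - inv2V * (prop * prop - gam[j] * gam[j]);
      bool acc = std::log(R::runif(0.0, 1.0)) < lr;
      if (acc) {
        gam[j] = prop;
        for (int i = 0; i < n; ++i) eta[i] += d * Z(i, j);
        llobs.swap(buf);
        llcur = ln;
      }
      ad.record(m, acc, adapting);
    }

    // city random effects (city-subset likelihood, N(0, sigma_u2) prior)
    for (int k = 0; k < K; ++k) {
      const int m = nA + p + q + k;
      double prop = u[k] + R::rnorm(0.0, 1.0) * std::exp(ad.ls[m]);
      double d = prop - u[k];
      const std::vector<int> &idx = by_city[k];
      double lo = 0.0, ln = 0.0;
      tmp.resize(idx.size());
      for (size_t t = 0; t < idx.size(); ++t) {
        int i = idx[t];
        lo += llobs[i];
        tmp[t] = log_cat_prob(y[i], eta[i] + d, alpha, J);
        ln += tmp[t];
      }
      double lr = (ln - lo) -
        0.5 * (prop * prop - u[k] * u[k]) / std::max(sigma_u2, 1e-12);
      bool acc = std::log(R::runif(0.0, 1.0)) < lr;
      if (acc) {
        u[k] = prop;
        for (size_t t = 0; t < idx.size(); ++t) {
          eta[idx[t]] += d;
          llobs[idx[t]] = tmp[t];
        }
        llcur += ln - lo;
      }
      ad.record(m, acc, adapting);
    }

    if (n_shift > 0) {
      double delta = R::rnorm(0.0, 1.0) * std::exp(ad.ls[m_shift]);
      double lo = 0.0, ln = 0.0;
      tmp.resize(shift_ref.size());
      std::vector<double> atmp(alpha);
      for (int j = 0; j < nA; ++j) atmp[j] += delta;
      for (size_t t = 0; t < shift_ref.size(); ++t) {
        int i = shift_ref[t];
        lo += llobs[i];
        tmp[t] = log_cat_prob(y[i], eta[i], atmp, J);
        ln += tmp[t];
      }
      double dprior = 0.0;
      for (int j = 0; j < nA; ++j) {
        dprior += (alpha[j] + delta) * (alpha[j] + delta) - alpha[j] * alpha[j];
      }
      for (int t = 0; t < n_shift; ++t) {
        double b = beta[shift_cols[t]];
        dprior += (b + delta) * (b + delta) - b * b;
      }
      double lr = (ln - lo) - inv2V * dprior;
      bool acc = std::log(R::runif(0.0, 1.0)) < lr;
      if (acc) {
        alpha = atmp;
        for (int t = 0; t < n_shift; ++t) beta[shift_cols[t]] += delta;
        for (int i = 0; i < n; ++i) eta[i] += delta;
        for (size_t t = 0; t < shift_ref.size(); ++t) eta[shift_ref[t]] -= delta;
        for (size_t t = 0; t < shift_ref.size(); ++t) llobs[shift_ref[t]] = tmp[t];
        llcur += ln - lo;
      }
      ad.record(m_shift, acc, adapting);
    }

    // conjugate inverse-gamma draw for sigma_u2
    double ssu = 0.0;
    for (int k = 0; k < K; ++k) ssu += u[k] * u[k];
    sigma_u2 = 1.0 / R::rgamma(ig_shape + 0.5 * K,
                               1.0 / (ig_scale + 0.5 * ssu));

    // guard against slow drift in the incrementally tracked values
    if (iter % 1000 == 0) {
      llcur = 0.0;
      for (int i = 0; i < n; ++i) {
        llobs[i] = log_cat_prob(y[i], eta[i], alpha, J);
        llcur += llobs[i];
      }
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0 && kept < n_keep) {
      int c = 0;
      for (int j = 0; j < nA; ++j) draws(kept, c++) = alpha[j];
      for (int j = 0; j < p; ++j) draws(kept, c++) = beta[j];
      for (int j = 0; j < q; ++j) draws(kept, c++) = gam[j];
      for (int k = 0; k < K; ++k) draws(kept, c++) = u[k];
      draws(kept, c) = sigma_u2;
      kept++;
    }
    if (iter % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  const int n_mh = prop_sd0.size();
  NumericVector acc_rate(n_mh), prop_sd(n_mh);
  long post_n = n_iter - burn_in;
  for (int m = 0; m < n_mh; ++m) {
    acc_rate[m] = post_n > 0 ? (double)ad.n_acc[m] / (double)post_n : NA_REAL;
    prop_sd[m] = std::exp(ad.ls[m]);
  }
  return List::create(_["draws"] = draws, _["acceptance"] = acc_rate,
                      _["proposal_sd"] = prop_sd);
}
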