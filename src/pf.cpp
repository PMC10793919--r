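// Sequential Monte Carlo (bootstrap particle filter) over drifting RL
// parameters, in the style of Samejima-type trial-by-trial Bayesian
// estimation. Each particle carries its own parameter vector (in filtering
// space) plus its own learner state (Q-values and, for the Kalman family,
// posterior variances), because the learner state depends on the particle's
// learning-rate history. Systematic resampling every trial; the reported
// per-trial estimate is the reweighted posterior mean before resampling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double KF_PRIOR_VAR = 100.0;
static const double KF_ERR_VAR = 10.0;

static inline double softmax_pL(double qL, double qR, double beta,
                                double kapL, double kapR) {
  double d = beta * ((qL + kapL) - (qR + kapR));
  if (d > 700.0) d = 700.0;
  if (d < -700.0) d = -700.0;
  return 1.0 / (1.0 + std::exp(-d));
}

// model codes as in rl.cpp; th holds native-space parameters
static inline double particle_pL(int model, const double* th, double qL,
                                 double qR, double vL, double vR, int prev) {
  if (model == 0) return softmax_pL(qL, qR, th[1], 0.0, 0.0);
  if (model == 1) {
    double kapL = (prev == 0) ? th[2] : 0.0;
    double kapR = (prev == 1) ? th[2] : 0.0;
    return softmax_pL(qL, qR, th[1], kapL, kapR);
  }
  double tot = vL + vR;
  double z = th[0] * (qL - qR) / std::sqrt(tot) +
             th[1] * (std::sqrt(vL) - std::sqrt(vR));
  return R::pnorm(z, 0.0, 1.0, 1, 0);
}

// [[Rcpp::export]]
List pf_cpp(int model, const arma::ivec& actions, const arma::vec& rewards,
            const arma::ivec& block_id, int n_particles,
            const arma::vec& init_mean, const arma::vec& init_sd,
            const arma::vec& sigma, const arma::vec& lo, const arma::vec& hi,
            const arma::uvec& logistic, const arma::vec& scale) {
  int T = actions.n_elem, m = init_mean.n_elem, P = n_particles;
  arma::mat X(P, m);       // filtering space
  arma::mat nat(P, m);     // native space
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < P; ++i)
      X(i, j) = init_mean[j] + init_sd[j] * norm_rand();

  arma::vec qL(P, arma::fill::zeros), qR(P, arma::fill::zeros);
  arma::vec vL(P), vR(P);
  arma::mat postm(T, m), postv(T, m);
  arma::vec ess(T), predL(T);
  arma::vec w(P), lik(P);
  arma::uvec idx(P);
  int prev = -1;

  for (int t = 0; t < T; ++t) {
    if (t == 0 || block_id[t] != block_id[t - 1]) {
      qL.zeros(); qR.zeros();
      vL.fill(KF_PRIOR_VAR); vR.fill(KF_PRIOR_VAR);
    }
    // propagate by the Gaussian random walk, then map to native space
    for (int j = 0; j < m; ++j) {
      if (sigma[j] > 0)
        for (int i = 0; i < P; ++i) X(i, j) += sigma[j] * norm_rand();
      if (logistic[j]) {
        for (int i = 0; i < P; ++i)
          nat(i, j) = scale[j] / (1.0 + std::exp(-X(i, j)));
      } else {
        for (int i = 0; i < P; ++i) {
          double v = X(i, j);
          if (v < lo[j]) v = lo[j];
          if (v > hi[j]) v = hi[j];
          X(i, j) = v;
          nat(i, j) = v;
        }
      }
    }
    // predictive action probability and per-particle likelihood
    double pl = 0.0;
    double th[3] = {0, 0, 0};
    for (int i = 0; i < P; ++i) {
      for (int j = 0; j < m && j < 3; ++j) th[j] = nat(i, j);
      double p = particle_pL(model, th, qL[i], qR[i], vL[i], vR[i], prev);
      pl += p;
      lik[i] = (actions[t] == 0) ? p : 1.0 - p;
      if (lik[i] < 1e-300) lik[i] = 1e-300;
    }
    predL[t] = pl / P;
    double s = arma::accu(lik);
    if (s <= 0 || !std::isfinite(s)) {
      w.fill(1.0 / P);  // weight underflow: uniform reweight fallback
    } else {
      w = lik / s;
    }
    for (int j = 0; j < m; ++j) {
      double mu = arma::dot(w, nat.col(j));
      postm(t, j) = mu;
      postv(t, j) = arma::dot(w, arma::square(nat.col(j) - mu));
    }
    ess[t] = 1.0 / arma::dot(w, w);

    // systematic resampling
    double u0 = unif_rand() / P;
    double cum = w[0];
    int i2 = 0;
    for (int i = 0; i < P; ++i) {
      double u = u0 + (double)i / P;
      while (u > cum && i2 < P - 1) { ++i2; cum += w[i2]; }
      idx[i] = i2;
    }
    X = X.rows(idx);
    nat = nat.rows(idx);
    qL = qL(idx); qR = qR(idx); vL = vL(idx); vR = vR(idx);

    // per-particle learner update with the observed action/reward
    int a = actions[t];
    double r = rewards[t];
    if (model <= 1) {
      if (a == 0) qL += nat.col(0) % (r - qL);
      else        qR += nat.col(0) % (r - qR);
    } else {
      if (a == 0) {
        arma::vec k = vL / (vL + KF_ERR_VAR);
        qL += k % (r - qL);
        vL -= k % vL;
      } else {
        arma::vec k = vR / (vR + KF_ERR_VAR);
        qR += k % (r - qR);
        vR -= k % vR;
      }
    }
    prev = a;
  }
  return List::create(_["mean"] = postm, _["var"] = postv, _["ess"] = ess,
                      _["pred_left"] = predL);
}
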