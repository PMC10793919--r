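// Agent-family dynamics and likelihoods shared by the simulator, the
// stationary MLE baseline, the particle filter and the oracle predictor.
//
// Model codes: 0 = Q-learning (alpha, beta)
//              1 = Q-learning with perseveration (alpha, beta, kappa)
//              2 = Kalman-filter learner with hybrid exploration (beta, gamma)
//
// Actions are 0 (L) and 1 (R). Q-values reset at block starts; the previous
// action (for the perseveration bonus) carries across block boundaries within
// a session. All random draws use R's RNG so set.seed() governs everything.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double KF_PRIOR_VAR = 100.0;
static const double KF_ERR_VAR = 10.0;

// P(choose L) for the softmax families, overflow-safe.
static inline double softmax_pL(double qL, double qR, double beta,
                                double kapL, double kapR) {
  double d = beta * ((qL + kapL) - (qR + kapR));
  if (d > 700.0) d = 700.0;
  if (d < -700.0) d = -700.0;
  return 1.0 / (1.0 + std::exp(-d));
}

// P(choose L) for the hybrid Thompson/UCB probit policy.
static inline double hybrid_pL(double qL, double qR, double vL, double vR,
                               double beta, double gamma) {
  double tot = vL + vR;
  if (tot <= 0.0) Rcpp::stop("hybrid policy: total posterior variance is zero");
  double z = beta * (qL - qR) / std::sqrt(tot) +
             gamma * (std::sqrt(vL) - std::sqrt(vR));
  return R::pnorm(z, 0.0, 1.0, 1, 0);
}

static inline double policy_pL(int model, const double* th,
                               double qL, double qR, double vL, double vR,
                               int prev) {
  if (model == 0) {
    return softmax_pL(qL, qR, th[1], 0.0, 0.0);
  } else if (model == 1) {
    double kapL = (prev == 0) ? th[2] : 0.0;
    double kapR = (prev == 1) ? th[2] : 0.0;
    return softmax_pL(qL, qR, th[1], kapL, kapR);
  }
  return hybrid_pL(qL, qR, vL, vR, th[0], th[1]);
}

static inline void learn_step(int model, const double* th, int a, double r,
                              double& qL, double& qR, double& vL, double& vR) {
  if (model <= 1) {
    double alpha = th[0];
    if (a == 0) qL += alpha * (r - qL); else qR += alpha * (r - qR);
  } else {
    if (a == 0) {
      double k = vL / (vL + KF_ERR_VAR);
      qL += k * (r - qL);
      vL -= k * vL;
    } else {
      double k = vR / (vR + KF_ERR_VAR);
      qR += k * (r - qR);
      vR -= k * vR;
    }
  }
}

// Simulate one session. theta: T x m matrix of parameter values in force at
// each trial. block_id: length-T integer vector (any values; a change marks a
// block boundary). arm1/arm2: per-trial reward parameter of arm L / R
// (Bernoulli probability or Gaussian mean). gaussian: reward scheme flag.
// [[Rcpp::export]]
List sim_session_cpp(int model, const arma::mat& theta,
                     const arma::ivec& block_id,
                     const arma::vec& arm1, const arma::vec& arm2,
                     bool gaussian, double tau2) {
  int T = theta.n_rows;
  IntegerVector actions(T);
  NumericVector rewards(T), pL(T);
  double qL = 0, qR = 0, vL = KF_PRIOR_VAR, vR = KF_PRIOR_VAR;
  int prev = -1;
  arma::rowvec th;
  for (int t = 0; t < T; ++t) {
    if (t == 0 || block_id[t] != block_id[t - 1]) {
      qL = qR = 0.0;
      vL = vR = KF_PRIOR_VAR;
    }
    th = theta.row(t);
    double p = policy_pL(model, th.memptr(), qL, qR, vL, vR, prev);
    int a = (unif_rand() < p) ? 0 : 1;
    double r;
    double armp = (a == 0) ? arm1[t] : arm2[t];
    if (gaussian) {
      r = armp + std::sqrt(tau2) * norm_rand();
    } else {
      r = (unif_rand() < armp) ? 1.0 : 0.0;
    }
    learn_step(model, th.memptr(), a, r, qL, qR, vL, vR);
    actions[t] = a;
    rewards[t] = r;
    pL[t] = p;
    prev = a;
  }
  return List::create(_["action"] = actions, _["reward"] = rewards,
                      _["p_left"] = pL);
}

// Per-trial probability of choosing L under given (possibly time-varying)
// parameters, replaying the session's learning dynamics.
// [[Rcpp::export]]
NumericVector choice_probs_cpp(int model, const arma::mat& theta,
                               const arma::ivec& actions,
                               const arma::vec& rewards,
                               const arma::ivec& block_id) {
  int T = actions.n_elem;
  NumericVector pL(T);
  double qL = 0, qR = 0, vL = KF_PRIOR_VAR, vR = KF_PRIOR_VAR;
  int prev = -1;
  for (int t = 0; t < T; ++t) {
    if (t == 0 || block_id[t] != block_id[t - 1]) {
      qL = qR = 0.0;
      vL = vR = KF_PRIOR_VAR;
    }
    arma::rowvec th = theta.row(t);
    pL[t] = policy_pL(model, th.memptr(), qL, qR, vL, vR, prev);
    learn_step(model, th.memptr(), actions[t], rewards[t], qL, qR, vL, vR);
    prev = actions[t];
  }
  return pL;
}

// Stationary negative log-likelihood (natural log), probability floored at
// 1e-12. theta is a single parameter vector broadcast over trials.
// [[Rcpp::export]]
double nll_cpp(int model, const arma::vec& theta, const arma::ivec& actions,
               const arma::vec& rewards, const arma::ivec& block_id) {
  int T = actions.n_elem;
  arma::mat th(T, theta.n_elem);
  th.each_row() = theta.t();
  NumericVector pL = choice_probs_cpp(model, th, actions, rewards, block_id);
  double nll = 0.0;
  for (int t = 0; t < T; ++t) {
    double p = (actions[t] == 0) ? pL[t] : 1.0 - pL[t];
    if (p < 1e-12) p = 1e-12;
    nll -= std::log(p);
  }
  return nll;
}
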