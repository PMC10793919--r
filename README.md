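# banditrnn

Trial-by-trial inference of reinforcement-learning (RL) parameters from
two-armed bandit choice behaviour, using a recurrent neural network trained
entirely on simulated agents — plus the classical baselines (stationary
maximum-likelihood fits, Bayesian particle filtering) and a method-agnostic
evaluation layer.

## The problem

Fitting an RL model (learning rate α, inverse temperature β, perseveration
κ, exploration weights β, γ) to a subject usually assumes the parameters are
*fixed* across the session. Behaviour is not: attention lapses, strategies
shift, motivation drifts. This package implements an amortised estimator: a
two-stage gated recurrent network is trained on thousands of simulated
Q-learning (or Kalman-filter) agents whose parameters are known and
time-varying, to predict

* the **next action** `a_{t+1}` from the action–reward history, and
* the **per-trial latent parameters** `θ_t`, via quantised classification
  heads (a stabilising intermediate target) feeding continuous regression
  heads.

The loss is `L = CE_action + Σ_i λ_CE,i CE_θi + Σ_i λ_MSE,i MSE_θi`. After
training, the weights are frozen and the network is run over unseen
sessions; it needs no per-subject fitting. All network code (GRU forward
pass, backpropagation through time, Adam, dropout, early stopping) is
implemented from scratch in RcppArmadillo — no deep-learning framework is
required.

Everything is tidyverse-native: sessions are tibbles
(`subject, block, trial, action, reward`), every estimator returns the same
prediction shape, and fitted objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

Simulate a training cohort of non-stationary Q-learners on the 10×100-trial
Bernoulli task (arm pairs drawn from {(0.1,0.9), (0.5,0.5), (0.9,0.1)};
α ~ U(0,1), β ~ U(0,10); parameters re-sampled with probability 0.005 per
trial, at most 4 times, 100-trial refractory), train the network, and
compare every estimator on the 30-agent test suite (10 stationary, 10
jump, 10 random-walk agents):

```r
library(banditrnn)
set.seed(1)

cohort <- sample_cohort("validation", n_agents = 300)
fit <- trnn_train(cohort, trnn_config("validation"))

test <- make_test_suite(10)
report <- evaluate_methods(
  list(trnn = predict(fit, test),
       mle = predict(fit_mle(test, "validation"), test),
       pf = predict(particle_filter(test, pf_config("validation"))),
       oracle = oracle_predict(test, "validation")),
  test)
report
```

Training runs ~15 minutes on one CPU at this scale. The run above prints:

```
<evaluation_report> mean action BCE by method:
# A tibble: 4 × 2
  method mean_bce
  <chr>     <dbl>
1 mle       0.319
2 oracle    0.291
3 pf        0.321
4 trnn      0.328
paired Wilcoxon vs 'trnn':
# A tibble: 7 × 5
  metric param method statistic    p_value
  <chr>  <chr> <chr>      <dbl>      <dbl>
1 bce    <NA>  mle          324 0.0612
2 mse    alpha mle          263 0.537
3 mse    beta  mle          138 0.0532
4 bce    <NA>  pf           379 0.00267
5 mse    alpha pf           326 0.0558
6 mse    beta  pf            31 0.0000356
7 bce    <NA>  oracle       465 0.00000183
```

Read: per-agent mean binary cross-entropy of next-action prediction (nats;
lower is better — the `oracle` row replays the true generative policy and
bounds what any estimator can achieve), and two-sided paired Wilcoxon
signed-rank tests of the network against each baseline, on action
prediction (`bce`) and on the per-trial parameter-estimation error (`mse`,
broadcast over trials for the stationary MLE). At this reduced 300-agent
training scale the network tracks the inverse-temperature trajectory with
by far the lowest error (mean MSE_β 2.7 vs 4.8 for the stationary fit and
6.8 for the particle filter; p = 4e-5 vs the filter) while predicting
actions at rough parity with the baselines, a few hundredths of a nat
above the oracle bound. Decisive action-prediction superiority is a
property of the full 2000-agent training regime, not of this scaled run;
the methods vignette discusses the gap and where it concentrates.

Useful follow-ups:

```r
autoplot(report)                      # BCE bar chart, mean ± s.e.m.
plot_recovery(predict(fit, test),     # true vs estimated trajectories
              test, subjects = unique(test$subject)[c(1, 11, 21)])
glance(fit)                           # epochs, best validation loss
tidy(fit_mle(test, "validation"))     # per-subject stationary estimates
```

A thin command-line interface over the same functions (subcommands
`simulate`, `train`, `infer`, `fit-baseline`, `evaluate`,
`run-experiment`) is installed at `inst/scripts/banditrnn-cli.R`.

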