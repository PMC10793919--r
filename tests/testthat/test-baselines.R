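# Stationary MLE, particle filter, d-RNN and oracle baselines.

test_that("negative log-likelihood matches closed forms", {
  set.seed(30)
  sim <- simulate_agent(task_validation(), init = c(alpha = 0.3, beta = 0))
  # beta = 0: uniform policy, NLL = T ln 2 regardless of alpha
  expect_equal(negative_log_likelihood(sim, "validation",
                                       c(alpha = 0.9, beta = 0)),
               nrow(sim) * log(2), tolerance = 1e-9)
  # single-trial session at the softmax example probability
  one <- sim[1, ]
  one$action <- "L"; one$reward <- 1
  # replay: first trial has Q = 0 -> p = 0.5 for any beta
  expect_equal(negative_log_likelihood(one, "validation",
                                       c(alpha = 0.5, beta = 2)), log(2))
  # a hand-built two-trial session hitting P(L) = e/(e+1) on trial 2
  two <- tibble::tibble(subject = "s", block = c(1L, 1L), trial = 1:2,
                        action = c("L", "L"), reward = c(1, 1))
  nll <- negative_log_likelihood(two, "validation", c(alpha = 0.5, beta = 2))
  expect_equal(nll, log(2) - log(exp(1) / (exp(1) + 1)), tolerance = 1e-9)
  expect_equal(-log(exp(1) / (exp(1) + 1)), 0.3133, tolerance = 1e-3)
  expect_error(negative_log_likelihood(sim, "validation",
                                       c(alpha = 2, beta = 1)), "support")
})

test_that("the likelihood is consistent: truth beats perturbations on average", {
  set.seed(31)
  diffs <- replicate(60, {
    sim <- simulate_agent(task_validation(), init = c(alpha = 0.4, beta = 4))
    truth <- negative_log_likelihood(sim, "validation",
                                     c(alpha = 0.4, beta = 4))
    pert <- negative_log_likelihood(sim, "validation",
                                    c(alpha = 0.7, beta = 1.5))
    pert - truth
  })
  expect_gt(mean(diffs), 0)
})

test_that("stationary MLE recovers parameters and is deterministic", {
  set.seed(32)
  sims <- dplyr::bind_rows(lapply(1:6, function(i) {
    simulate_agent(task_validation(), init = c(alpha = 0.3, beta = 5),
                   subject = sprintf("s%02d", i))
  }))
  fit <- fit_mle(sims, "validation")
  ok_a <- abs(fit$estimates$alpha - 0.3) < 0.1
  ok_b <- abs(fit$estimates$beta - 5) < 1.5
  expect_gte(mean(ok_a & ok_b), 0.8)
  expect_true(all(fit$estimates$converged))
  # optimum at least as good as the truth's likelihood
  s1 <- dplyr::filter(sims, subject == "s01")
  expect_lte(fit$estimates$nll[1] - 1e-6,
             negative_log_likelihood(s1, "validation",
                                     c(alpha = 0.3, beta = 5)))
  set.seed(99); f1 <- fit_mle(s1, "validation")
  set.seed(99); f2 <- fit_mle(s1, "validation")
  expect_identical(f1$estimates, f2$estimates)
  # beta = 0 data: fitted NLL ~ T ln 2 (no structure to exploit)
  set.seed(33)
  s0 <- simulate_agent(task_validation(), init = c(alpha = 0.5, beta = 0))
  f0 <- fit_mle(s0, "validation")
  expect_lt(abs(f0$estimates$nll - nrow(s0) * log(2)), 5)
})

test_that("MLE predictions broadcast the stationary estimate", {
  set.seed(34)
  sim <- simulate_agent(task_validation(), init = c(alpha = 0.3, beta = 5))
  fit <- fit_mle(sim, "validation")
  pred <- predict(fit, sim)
  expect_equal(nrow(pred), nrow(sim))
  expect_equal(length(unique(pred$beta_hat)), 1L)
  expect_true(all(pred$pred_left >= 0 & pred$pred_left <= 1))
})

test_that("particle filter: no information and no drift leaves the prior", {
  set.seed(35)
  sim <- simulate_agent(task_validation(), init = c(alpha = 0.5, beta = 0))
  cfg <- pf_config("validation", n_particles = 500,
                   sigma = c(alpha = 0, beta = 0))
  fit <- particle_filter(sim, cfg)
  tr <- fit$trajectories
  # the agent chooses uniformly, so the learning rate is unidentified: its
  # posterior mean stays at the (logistic-link) prior mean, 0.5 by symmetry
  expect_lt(abs(mean(tr$alpha_hat) - 0.5), 0.06)
  # trial 1 weights are flat (all particles predict 0.5): the recorded
  # estimate is the prior mean of the clipped Gaussian
  expect_lt(abs(tr$beta_hat[1] - mean(pmax(rnorm(1e5, 0, 1), 0))), 0.1)
  # random behaviour keeps the inverse temperature low
  expect_true(all(tr$beta_hat <= 1))
  expect_true(all(tr$ess > 0 & tr$ess <= 500))
  expect_true(all(tr$alpha_var >= 0 & tr$beta_var >= 0))
})

test_that("particle filter agrees with MLE on stationary agents and clips beta", {
  set.seed(36)
  sim <- simulate_agent(task_validation(), init = c(alpha = 0.4, beta = 5))
  pf <- particle_filter(sim, pf_config("validation"))
  tr <- pf$trajectories
  expect_true(all(tr$beta_hat >= 0 & tr$beta_hat <= 10))
  expect_true(all(tr$alpha_hat >= 0 & tr$alpha_hat <= 1))
  # time-averaged posterior mean in the MLE's recovery ballpark
  late <- dplyr::filter(tr, dplyr::row_number() > 200)
  expect_lt(abs(mean(late$beta_hat) - 5), 1.5)
  expect_lt(abs(mean(late$alpha_hat) - 0.4), 0.15)
})

test_that("particle filter tracks an abrupt inverse-temperature jump", {
  set.seed(37)
  # a jump toward random behaviour (8 -> 2) is identifiable immediately:
  # the posterior mean should cross the midpoint within 50 post-jump trials
  hits <- replicate(6, {
    sim <- pf_jump_session(8, 2, 300)
    tr <- particle_filter(sim, pf_config("validation"))$trajectories
    any(tr$beta_hat[301:350] < (8 + 2) / 2)
  })
  expect_gte(mean(hits), 0.8)
  # a jump toward determinism (2 -> 8) is tracked with lag: the posterior
  # mean moves toward the new value over the following block
  sim <- pf_jump_session(2, 8, 300)
  tr <- particle_filter(sim, pf_config("validation"))$trajectories
  expect_gt(mean(tr$beta_hat[330:500]), mean(tr$beta_hat[250:300]) + 0.5)
})

test_that("d-RNN produces valid predictions and beats chance on learnable data", {
  set.seed(38)
  sims <- dplyr::bind_rows(lapply(1:8, function(i) {
    simulate_agent(task_validation(), init = c(alpha = 0.4, beta = 6),
                   subject = sprintf("d%02d", i))
  }))
  fit <- drnn_train(sims, max_epochs = 150, batch_size = 6, seed = 5,
                    patience = 20)
  pred <- predict(fit, sims)
  expect_true(all(pred$pred_left[-1] >= 0 & pred$pred_left[-1] <= 1,
                  na.rm = TRUE))
  bce <- action_bce(pred, sims)
  expect_lt(mean(bce$bce), log(2))
})

test_that("LOOCV holds out exactly one subject per fold", {
  set.seed(39)
  sims <- dplyr::bind_rows(lapply(1:4, function(i) {
    simulate_agent(task_validation(n_blocks = 2, n_trials = 30),
                   init = c(alpha = 0.4, beta = 6),
                   subject = sprintf("s%d", i))
  }))
  pred <- drnn_loocv(sims, max_epochs = 2, batch_size = 3)
  expect_setequal(unique(pred$subject), unique(sims$subject))
  expect_equal(nrow(pred), nrow(sims))
  one <- dplyr::filter(sims, subject == "s1")
  expect_error(drnn_loocv(one), "2 subjects")
})
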