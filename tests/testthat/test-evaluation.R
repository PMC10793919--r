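# Metrics, paired tests and behavioural analyses.

toy_pred <- function(p, data) {
  tibble::tibble(subject = data$subject, block = data$block,
                 trial = data$trial, pred_left = p)
}

test_that("action BCE matches hand computations", {
  d <- tibble::tibble(subject = "s", block = 1L, trial = 1:3,
                      action = c("L", "L", "R"), reward = c(1, 1, 0))
  # constant 0.5 -> ln 2 (trial 1 excluded)
  expect_equal(action_bce(toy_pred(0.5, d), d)$bce, log(2))
  # perfect predictor -> 0
  expect_equal(action_bce(toy_pred(c(1, 1, 0), d), d)$bce, 0,
               tolerance = 1e-10)
  # probs (0.9, 0.8) on two matching observations
  expect_equal(action_bce(toy_pred(c(0.5, 0.9, 0.2), d), d)$bce,
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-12)
  expect_equal(-(log(0.9) + log(0.8)) / 2, 0.1643, tolerance = 1e-3)
  # out-of-range probabilities are clamped, not fatal
  expect_true(is.finite(action_bce(toy_pred(c(0.5, 0, 1), d), d)$bce))
})

test_that("parameter MSE matches identities and broadcasts", {
  set.seed(40)
  truth <- tibble::tibble(subject = "s", block = 1L, trial = 1:10000,
                          action = "L", reward = 1,
                          beta = rep(4, 10000))
  est <- dplyr::mutate(truth[, 1:3], beta_hat = 4)
  expect_equal(param_mse(est, truth)$mse, 0)
  est2 <- dplyr::mutate(truth[, 1:3], beta_hat = 5.5)
  expect_equal(param_mse(est2, truth)$mse, 1.5^2)
  est3 <- dplyr::mutate(truth[, 1:3], beta_hat = 4 + rnorm(10000, 0, 0.1))
  expect_equal(param_mse(est3, truth)$mse, 0.01, tolerance = 0.05)
  expect_error(param_mse(dplyr::rename(est, gamma_hat = beta_hat), truth),
               "lacks")
})

test_that("Wilcoxon signed-rank matches exact enumeration for small n", {
  # 5 pairs, all positive differences: two-sided exact p = 2/32
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$statistic, 15)
  # brute-force enumeration of sign patterns for n <= 12
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    d <- round(runif(n, 0.1, 5), 3) * sample(c(-1, 1), n, TRUE)
    x <- d; y <- rep(0, n)
    got <- wilcoxon_signed_rank(x, y)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% r
    p_exact <- mean(abs(v_all - n * (n + 1) / 4) >=
                      abs(v_obs - n * (n + 1) / 4) - 1e-9)
    expect_equal(got$p_value, p_exact, tolerance = 1e-9)
  }
  # symmetry under swapping
  a <- c(1, 2, 3, 4, 6); b <- c(2, 1, 5, 1, 2)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               wilcoxon_signed_rank(b, a)$p_value)
  expect_error(wilcoxon_signed_rank(rep(1, 6), rep(1, 6)), "zero")
})

test_that("stay probability moving average matches the worked example", {
  d <- tibble::tibble(subject = "s", block = 1L, trial = 1:5,
                      action = c("L", "L", "L", "R", "R"), reward = 0)
  out <- stay_probability_ma(d, window = 2)
  expect_equal(out$stay, c(NA, 1, 1, 0, 1))
  expect_equal(out$stay_ma, c(NA, NA, 1, 0.5, 0.5))
  # constant actions -> all stays 1; strict alternation -> all stays 0
  cst <- stay_probability_ma(
    tibble::tibble(subject = "s", block = 1L, trial = 1:30,
                   action = "L", reward = 0), window = 5)
  expect_true(all(cst$stay_ma[-(1:5)] == 1))
  alt <- stay_probability_ma(
    tibble::tibble(subject = "s", block = 1L, trial = 1:30,
                   action = rep(c("L", "R"), 15), reward = 0), window = 5)
  expect_true(all(alt$stay_ma[-(1:5)] == 0))
})

test_that("correlation helper handles the edge cases", {
  x <- rnorm(100)
  expect_equal(correlate_estimates(x, 2 * x + 1), 1)
  expect_equal(correlate_estimates(x, -x), -1)
  set.seed(42)
  expect_lt(abs(correlate_estimates(rnorm(1e4), rnorm(1e4))), 0.05)
  expect_error(correlate_estimates(rep(1, 10), rnorm(10)), "variance")
})

test_that("ungreedy switch events follow the run/reward/switch rule", {
  base <- tibble::tibble(
    subject = "s", block = 1L, trial = 1:5,
    action = c("R", "R", "R", "R", "L"),
    reward = c(1, 1, 1, 1, 0),
    arm_left = 0.1, arm_right = 0.9)
  ev <- detect_ungreedy_events(base)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$trial, 5L)
  expect_equal(ev$run_length, 4L)
  # run of 2 before the switch: below min_run
  short <- base
  short$action <- c("L", "L", "R", "R", "L")
  short$reward <- c(0, 0, 1, 1, 0)
  expect_equal(nrow(detect_ungreedy_events(short)), 0L)
  # unrewarded final run trial: no event
  unrew <- base
  unrew$reward <- c(1, 1, 1, 0, 0)
  expect_equal(nrow(detect_ungreedy_events(unrew)), 0L)
  # no switch at all
  none <- base
  none$action <- rep("R", 5)
  expect_equal(nrow(detect_ungreedy_events(none)), 0L)
  # strict mode requires the whole run rewarded
  part <- base
  part$reward <- c(1, 0, 1, 1, 0)
  expect_equal(nrow(detect_ungreedy_events(part)), 1L)
  expect_equal(nrow(detect_ungreedy_events(part, strict = TRUE)), 0L)
})

test_that("block difficulty thresholds follow the value-difference rule", {
  task <- tibble::tibble(block = 1:3, mu_left = c(10, 0.3, 5),
                         mu_right = c(-10, 0, 0))
  lab <- label_block_difficulty(task)
  expect_equal(lab$difficulty, c("easy", "hard", "neither"))
  expect_error(label_block_difficulty(tibble::tibble(p_left = 1)), "gaussian")
})

test_that("aligned aggregation averages correctly and drops edge windows", {
  d <- tibble::tibble(subject = rep(c("a", "b"), each = 6),
                      block = 1L, trial = rep(1:6, 2),
                      v = c(rep(1, 6), rep(3, 6)))
  tr <- aggregate_dynamics(d, "v", align = "trial")
  expect_true(all(tr$mean == 2))
  expect_true(all(tr$n == 2))
  single <- aggregate_dynamics(dplyr::filter(d, subject == "a"), "v", "trial")
  expect_true(all(single$mean == 1))
  expect_true(all(is.na(single$sem) | single$sem == 0))
  # event alignment: window extending past the block edge is dropped
  ev <- tibble::tibble(subject = c("a", "a"), block = 1L, trial = c(2L, 4L))
  ag <- aggregate_dynamics(d, "v", align = "event", events = ev,
                           window = -1:1)
  expect_true(all(ag$n == 2))  # both events fit
  ag2 <- aggregate_dynamics(d, "v", align = "event", events = ev,
                            window = -3:1)
  expect_true(all(ag2$n == 1))  # the trial-2 event lacks a full window
  expect_warning(aggregate_dynamics(d, "v", "event",
                                    events = ev[0, ], window = -1:1),
                 "events")
})

test_that("the evaluation report compares methods pairwise on shared subjects", {
  set.seed(43)
  sims <- dplyr::bind_rows(lapply(1:6, function(i) {
    simulate_agent(task_validation(n_blocks = 2, n_trials = 40),
                   init = c(alpha = 0.3, beta = 6),
                   subject = sprintf("s%d", i))
  }))
  orc <- oracle_predict(sims)
  noisy <- dplyr::mutate(orc, pred_left = 0.5)
  rep <- evaluate_methods(list(oracle = orc, chance = noisy), sims)
  expect_setequal(unique(rep$bce$method), c("oracle", "chance"))
  b <- tidyr::pivot_wider(rep$bce, id_cols = subject, names_from = method,
                          values_from = bce)
  expect_true(all(b$oracle < b$chance))
  expect_lt(rep$tests$p_value[rep$tests$metric == "bce"], 0.05)
  expect_equal(glance(rep)$n, c(6, 6))
})
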