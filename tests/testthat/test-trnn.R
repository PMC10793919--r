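# Network interface: input encoding, loss definition, analytic gradients,
# forward-pass contracts, and training progress at small scale.

test_that("inputs are one-hot action plus raw reward, targets shifted by one", {
  s <- tibble::tibble(subject = "s1", block = c(1, 1, 2), trial = c(1, 2, 1),
                      action = c("L", "R", "L"), reward = c(1, 0, 0.5))
  enc <- encode_inputs(s)
  expect_equal(enc$in_left, c(1, 0, 1))
  expect_equal(enc$in_right, c(0, 1, 0))
  expect_equal(enc$in_reward, c(1, 0, 0.5))
  expect_equal(enc$target_next, c("R", "L", NA))  # last trial unsupervised
  # T trials -> T input rows, T-1 action targets
  expect_equal(sum(!is.na(enc$target_next)), nrow(s) - 1L)
})

test_that("combined loss matches closed forms and reduces correctly", {
  # uniform action predictor: CE = ln 2
  u <- combined_loss(rep(0.5, 10), rep("L", 10))
  expect_equal(u$action_ce, log(2), tolerance = 1e-12)
  expect_equal(u$total, log(2))
  # perfect predictions everywhere -> zero loss
  cp <- matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE)
  perfect <- combined_loss(
    action_probs = c(1, 1), action_targets = c("L", "L"),
    class_probs = list(cp), class_targets = list(c(0L, 1L)),
    estimates = matrix(c(0.3, 0.5)), truth = matrix(c(0.3, 0.5)),
    lambda_ce = 1, lambda_mse = 1)
  expect_equal(perfect$total, 0, tolerance = 1e-9)
  # all lambda zero -> action CE only
  l0 <- combined_loss(c(0.9, 0.8), c("L", "L"),
                      class_probs = list(cp), class_targets = list(c(1L, 0L)),
                      estimates = matrix(c(0, 0)), truth = matrix(c(1, 1)),
                      lambda_ce = 0, lambda_mse = 0)
  expect_equal(l0$total, l0$action_ce)
  expect_gt(l0$param_ce[1], 0)
})

test_that("loss components are non-negative and total bounds the action term", {
  set.seed(20)
  co <- sample_cohort("validation", 4)
  tt <- banditrnn:::.cohort_tensors(co)
  bins <- attr(co, "quantization")$n_bins
  W <- banditrnn:::trnn_init_cpp(bins, 8L, 8L, TRUE, 5L)
  L <- banditrnn:::trnn_loss_cpp(W, tt$X, tt$cls, tt$theta, tt$anext, bins,
                                 c(0.2, 0.2), c(6, 0.1), 8L, 8L, TRUE)
  expect_gte(L$action_ce, 0)
  expect_true(all(L$param_ce >= 0))
  expect_true(all(L$param_mse >= 0))
  expect_gte(L$total, L$action_ce)
  # an untrained network is near the uniform-predictor cross-entropy
  expect_lt(abs(L$action_ce - log(2)), 0.2)
})

test_that("analytic BPTT gradients match finite differences", {
  set.seed(21)
  T_ <- 8; N <- 3; bins <- c(3L, 4L)
  X <- array(0, c(3, T_, N))
  a <- matrix(sample(0:1, T_ * N, TRUE), T_, N)
  for (n in seq_len(N)) {
    X[1, , n] <- as.numeric(a[, n] == 0)
    X[2, , n] <- as.numeric(a[, n] == 1)
    X[3, , n] <- runif(T_)
  }
  cls <- array(sample(0:2, 2 * T_ * N, TRUE), c(2, T_, N))
  th <- array(runif(2 * T_ * N), c(2, T_, N))
  an <- rbind(a[-1, , drop = FALSE], -1L)
  lam_ce <- c(0.3, 0.2); lam_mse <- c(2, 0.5)
  # central differences with a step large enough to dominate single-precision
  # roundoff in the loss; assert close agreement per coordinate plus a tight
  # overall correlation between analytic and numeric gradients
  for (concat in c(TRUE, FALSE)) {
    W <- banditrnn:::trnn_init_cpp(bins, 5L, 4L, concat, 99L)
    res <- banditrnn:::trnn_loss_cpp(W, X, cls, th, an, bins, lam_ce, lam_mse,
                                     5L, 4L, concat, gradients = TRUE)
    eps <- 1e-2
    nums <- anas <- numeric(0)
    for (k in seq_along(W)) {
      for (j in sample(length(W[[k]]), min(2, length(W[[k]])))) {
        Wp <- W; Wp[[k]][j] <- Wp[[k]][j] + eps
        Wm <- W; Wm[[k]][j] <- Wm[[k]][j] - eps
        fp <- banditrnn:::trnn_loss_cpp(Wp, X, cls, th, an, bins, lam_ce,
                                        lam_mse, 5L, 4L, concat)$total
        fm <- banditrnn:::trnn_loss_cpp(Wm, X, cls, th, an, bins, lam_ce,
                                        lam_mse, 5L, 4L, concat)$total
        nums <- c(nums, (fp - fm) / (2 * eps))
        anas <- c(anas, res$gradients[[k]][j])
      }
    }
    expect_true(all(abs(nums - anas) < 0.05 * (abs(nums) + abs(anas)) + 2e-3))
    expect_gt(cor(nums, anas), 0.999)
  }
})

test_that("inference is deterministic, aligned, and support-clipped", {
  set.seed(22)
  co <- sample_cohort("validation", 6)
  fit <- trnn_train(co, trnn_config("validation", max_epochs = 2,
                                   batch_size = 4, seed = 7))
  test <- simulate_agent(task_validation(), init = c(alpha = 0.5, beta = 5),
                         subject = "t1")
  p1 <- predict(fit, test)
  p2 <- predict(fit, test)
  expect_identical(p1, p2)  # dropout off at inference
  expect_equal(nrow(p1), nrow(test))  # estimate for every trial
  expect_true(is.na(p1$pred_left[1]))  # no prediction for trial 1
  expect_true(all(!is.na(p1$pred_left[-1])))
  expect_true(all(p1$pred_left[-1] >= 0 & p1$pred_left[-1] <= 1))
  expect_true(all(p1$alpha_hat >= 0 & p1$alpha_hat <= 1))
  expect_true(all(p1$beta_hat >= 0 & p1$beta_hat <= 10))
})

test_that("the ablation flag rewires the action head input", {
  set.seed(23)
  co <- sample_cohort("validation", 4)
  full <- trnn_train(co, trnn_config("validation", max_epochs = 1,
                                     batch_size = 4, seed = 1))
  abl <- trnn_train(co, trnn_config("validation", max_epochs = 1,
                                    batch_size = 4, seed = 1,
                                    concat_logits = FALSE))
  # stage-2 GRU input: 10 logits + 3 raw inputs with concatenation, 3 without
  expect_equal(ncol(full$weights[[23]]), 13L)
  expect_equal(ncol(abl$weights[[23]]), 3L)
})

test_that("training reduces the validation loss on a small cohort", {
  set.seed(24)
  co <- sample_cohort("validation", 12)
  fit <- trnn_train(co, trnn_config("validation", max_epochs = 15,
                                    batch_size = 10, seed = 3,
                                    eval_every = 1))
  h <- fit$history
  expect_lt(h$val_total[h$epoch == fit$best_epoch], h$val_total[1])
  expect_lte(fit$best_val, min(h$val_total))
  # history records every component every epoch
  expect_true(all(c("val_action_ce", "val_ce_alpha", "val_mse_beta")
                  %in% names(h)))
  # same seed, same data -> identical result
  set.seed(24)
  co2 <- sample_cohort("validation", 12)
  fit2 <- trnn_train(co2, trnn_config("validation", max_epochs = 15,
                                      batch_size = 10, seed = 3))
  expect_equal(fit$best_val, fit2$best_val, tolerance = 1e-12)
})
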