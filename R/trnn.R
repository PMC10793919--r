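# User-facing interface to the two-stage recurrent network: configuration,
# training (BPTT + Adam + early stopping in compiled code), and inference.

#' Network configuration
#'
#' Hyperparameters of the two-stage recurrent network. Defaults follow the
#' reference settings: 32 GRU cells per recurrent layer, dropout 0.2 in both
#' layers, Adam with constant learning rate 0.001, and per-study loss weights
#' chosen so the loss components are of comparable magnitude
#' (validation: `lambda_ce` = (0.2, 0.2), `lambda_mse` = (6, 0.1)).
#' Mini-batches are whole sessions; the default batch size of 25 sessions
#' keeps many gradient updates per epoch on scaled-down cohorts of a few
#' hundred agents (batch size does not change the result on this task
#' family, only the update count per epoch), and the 300-epoch default with
#' patience 30 approaches the early-stopping plateau on a 300-agent cohort
#' within a desk-scale compute budget.
#'
#' @param study Study preset supplying the model, supports, bin counts and
#'   loss weights.
#' @param bins Quantisation override (see [quantization_spec()]).
#' @param hidden,hidden_action GRU cells in the parameter-inference and
#'   action-prediction layers.
#' @param dropout Dropout probability in both recurrent layers.
#' @param learn_rate Adam learning rate.
#' @param batch_size Sessions per mini-batch.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience, counted in validation
#'   evaluations without improvement.
#' @param eval_every Evaluate the validation loss every this many epochs
#'   (evaluation costs about a fifth of an epoch; 2 halves that overhead).
#' @param concat_logits If `FALSE`, the class logits are *not* concatenated
#'   onto the action head's input (ablation variant).
#' @param lambda_ce,lambda_mse Named per-parameter loss weights; `NULL` uses
#'   the study preset.
#' @param seed Integer seed for weight initialisation, shuffling and dropout;
#'   drawn from the session RNG when `NULL`.
#' @return A `trnn_config` list.
#' @export
trnn_config <- function(study = "validation", bins = NULL, hidden = 32,
                        hidden_action = 32, dropout = 0.2, learn_rate = 0.001,
                        batch_size = 25, max_epochs = 300, patience = 30,
                        eval_every = 2, concat_logits = TRUE,
                        lambda_ce = NULL, lambda_mse = NULL, seed = NULL) {
  info <- .study_info(study)
  qspec <- quantization_spec(study, bins)
  if (is.null(lambda_ce)) lambda_ce <- info$lambda_ce
  if (is.null(lambda_mse)) lambda_mse <- info$lambda_mse
  lambda_ce <- lambda_ce[qspec$param]
  lambda_mse <- lambda_mse[qspec$param]
  stopifnot(all(lambda_ce >= 0), all(lambda_mse >= 0), hidden >= 1,
            dropout >= 0, dropout < 1, batch_size >= 1, patience >= 1)
  structure(list(
    study = study, model = info$model, quantization = qspec,
    hidden = as.integer(hidden), hidden_action = as.integer(hidden_action),
    dropout = dropout, learn_rate = learn_rate,
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    patience = as.integer(patience), eval_every = as.integer(eval_every),
    concat_logits = isTRUE(concat_logits),
    lambda_ce = lambda_ce, lambda_mse = lambda_mse, seed = seed
  ), class = "trnn_config")
}

#' Encode a session as network inputs
#'
#' Per trial t the network input is the concatenation of the one-hot coded
#' action and the raw reward: `(1[a_t = L], 1[a_t = R], r_t)`. The prediction
#' target at step t is the *next* action `a_{t+1}`; the last trial of a
#' session has no action target. Rewards are fed unscaled.
#'
#' @param data Sessions tibble (`subject`, `block`, `trial`, `action`,
#'   `reward`).
#' @return Tibble with columns `subject`, `block`, `trial`, `in_left`,
#'   `in_right`, `in_reward`, `target_next`.
#' @export
#' @examples
#' s <- tibble::tibble(subject = "s1", block = 1, trial = 1:2,
#'                     action = c("L", "R"), reward = c(1, 0))
#' encode_inputs(s)
encode_inputs <- function(data) {
  if (nrow(data) == 0) rlang::abort("empty session")
  a <- .action_index(data$action)
  data %>%
    dplyr::transmute(
      .data$subject, .data$block, .data$trial,
      in_left = as.numeric(a == 1L), in_right = as.numeric(a == 2L),
      in_reward = .data$reward,
      target_next = dplyr::if_else(
        .data$subject == dplyr::lead(.data$subject, default = ""),
        dplyr::lead(c("L", "R")[a]), NA_character_)
    )
}

#' Train the network on a simulated cohort
#'
#' Minimises the combined loss — next-action cross-entropy, plus per-parameter
#' weighted classification cross-entropy over quantised bins and regression
#' mean-squared error — over mini-batches of whole sessions, with Adam, early
#' stopping on the validation total loss, and dropout. The best-validation
#' weights are kept.
#'
#' @param cohort A `bandit_cohort` from [sample_cohort()].
#' @param config A [trnn_config()].
#' @param val Optional held-out `bandit_cohort`; when `NULL` the cohort is
#'   split 80/20 at the agent level.
#' @param init_weights Optional weight list from a previous `trnn_fit`
#'   (warm start / continued training); fresh random initialisation when
#'   `NULL`.
#' @return A `trnn_fit` with elements `weights`, `config`, `history` (per
#'   epoch loss components) and `best_epoch`.
#' @export
trnn_train <- function(cohort, config = trnn_config(attr(cohort, "study")),
                       val = NULL, init_weights = NULL) {
  stopifnot(inherits(cohort, "bandit_cohort"))
  if (length(unique(cohort$subject)) < 2 && is.null(val)) {
    rlang::abort("cohort too small to split; supply `val`")
  }
  qspec <- config$quantization
  if (is.null(val)) {
    sp <- split_train_val(cohort, 0.8)
    train <- sp$train
    val <- sp$val
  } else {
    train <- cohort
  }
  tt <- .cohort_tensors(dplyr::bind_rows(tibble::as_tibble(train),
                                         tibble::as_tibble(val)), qspec)
  n_train <- length(unique(train$subject))
  train_idx <- seq_len(n_train) - 1L
  val_idx <- seq(n_train + 1L, length(tt$subjects)) - 1L
  seed <- config$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  res <- trnn_train_cpp(
    tt$X, tt$cls, tt$theta, tt$anext, train_idx, val_idx,
    qspec$n_bins, unname(config$lambda_ce), unname(config$lambda_mse),
    config$hidden, config$hidden_action, config$dropout, config$learn_rate,
    config$batch_size, config$max_epochs, config$patience,
    config$concat_logits, as.integer(seed), 5.0, init_weights,
    config$eval_every
  )
  hist <- tibble::tibble(
    epoch = as.integer(res$history$epoch),
    train_total = res$history$train_total,
    val_total = res$history$val_total,
    val_action_ce = res$history$val_action_ce
  )
  for (i in seq_along(qspec$param)) {
    hist[[paste0("val_ce_", qspec$param[i])]] <- res$history$val_param_ce[[i]]
    hist[[paste0("val_mse_", qspec$param[i])]] <- res$history$val_param_mse[[i]]
  }
  structure(list(
    weights = res$weights, config = config, history = hist,
    best_epoch = res$best_epoch, best_val = res$best_val,
    n_train = n_train, n_val = length(val_idx), seed = seed
  ), class = "trnn_fit")
}

#' @export
print.trnn_fit <- function(x, ...) {
  cat(sprintf(
    "<trnn_fit> study %s (%s model); %d+%d agents; best epoch %d (val loss %.4f)\n",
    x$config$study, x$config$model, x$n_train, x$n_val, x$best_epoch,
    x$best_val))
  invisible(x)
}

#' Trial-by-trial inference with a trained network
#'
#' Freezes the weights and runs the network over unseen sessions (dropout
#' off; no weight updates). The output at step t, produced from the input
#' `(a_t, r_t)`, is the parameter estimate for trial t and the probability
#' distribution of the action at trial t+1. Predictions are re-aligned so
#' that `pred_left` at trial t is the probability that the action *observed
#' at trial t* is `L` (undefined at the first trial of each session);
#' parameter estimates are clipped to their supports.
#'
#' @param object A `trnn_fit`.
#' @param newdata Sessions tibble; only `subject`, `block`, `trial`,
#'   `action`, `reward` are used.
#' @param ... Unused.
#' @return Tibble `subject`, `block`, `trial`, `pred_left`, and one
#'   `<param>_hat` column per parameter.
#' @export
predict.trnn_fit <- function(object, newdata, ...) {
  qspec <- object$config$quantization
  nd <- sessions_only(newdata)
  tt <- .cohort_tensors(nd, qspec, params = character(0))
  out <- trnn_predict_cpp(object$weights, tt$X, qspec$n_bins,
                          object$config$hidden, object$config$hidden_action,
                          object$config$concat_logits)
  T_ <- tt$n_trials
  nd <- nd[order(match(nd$subject, tt$subjects)), ]
  pred <- dplyr::select(nd, dplyr::all_of(c("subject", "block", "trial")))
  # step t predicts trial t+1: shift down one trial within each session
  pl <- out$p_next_left
  pred$pred_left <- as.vector(rbind(NA_real_, pl[-T_, , drop = FALSE]))
  for (i in seq_along(qspec$param)) {
    est <- pmin(pmax(as.vector(out$theta_hat[[i]]), qspec$lower[i]),
                qspec$upper[i])
    pred[[paste0(qspec$param[i], "_hat")]] <- est
  }
  pred
}

#' @rdname predict.trnn_fit
#' @param fit A `trnn_fit`.
#' @export
trnn_infer <- function(fit, newdata) predict(fit, newdata)

#' Combined training loss of the network
#'
#' `L_total = L_action_CE + sum_i lambda_ce_i L_ce_i + sum_i lambda_mse_i
#' L_mse_i`, with all cross-entropies and squared errors averaged over
#' supervised trials (natural log). Exposed for diagnostics and testing;
#' training uses the compiled implementation of the same quantity.
#'
#' @param action_probs Matrix (trials x 2) of predicted next-action
#'   probabilities, or vector of P(next = L).
#' @param action_targets Next actions (`"L"`/`"R"`), `NA` where unsupervised.
#' @param class_probs List (per parameter) of matrices (trials x bins) of
#'   class probabilities.
#' @param class_targets List (per parameter) of 0-based true class labels.
#' @param estimates,truth Matrices (trials x m) of continuous estimates and
#'   true values.
#' @param lambda_ce,lambda_mse Per-parameter loss weights.
#' @return List with `total`, `action_ce`, `param_ce`, `param_mse`.
#' @export
combined_loss <- function(action_probs, action_targets, class_probs = list(),
                          class_targets = list(), estimates = NULL,
                          truth = NULL, lambda_ce = numeric(0),
                          lambda_mse = numeric(0)) {
  if (is.null(dim(action_probs))) {
    action_probs <- cbind(action_probs, 1 - action_probs)
  }
  keep <- !is.na(action_targets)
  a <- .action_index(action_targets[keep])
  p <- action_probs[keep, , drop = FALSE][cbind(seq_along(a), a)]
  action_ce <- mean(-log(pmax(p, 1e-12)))
  m <- length(class_probs)
  param_ce <- param_mse <- numeric(m)
  for (i in seq_len(m)) {
    cp <- class_probs[[i]]
    cl <- class_targets[[i]] + 1L
    param_ce[i] <- mean(-log(pmax(cp[cbind(seq_along(cl), cl)], 1e-12)))
    if (!is.null(estimates)) {
      param_mse[i] <- mean((estimates[, i] - truth[, i])^2)
    }
  }
  total <- action_ce + sum(lambda_ce * param_ce) + sum(lambda_mse * param_mse)
  list(total = total, action_ce = action_ce, param_ce = param_ce,
       param_mse = param_mse)
}
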