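# Comparison methods: stationary maximum-likelihood fitting, Bayesian
# particle filtering with random-walk parameter dynamics, the data-driven
# action-only recurrent network (d-RNN), and the ground-truth oracle.

.split_sessions <- function(data) {
  data <- tibble::as_tibble(data)
  split(data, factor(data$subject, levels = unique(data$subject)))
}

.session_arrays <- function(session) {
  list(actions = .action_index(session$action) - 1L,
       rewards = as.numeric(session$reward),
       block = as.integer(session$block))
}

#' Stationary negative log-likelihood of a session
#'
#' `-sum_t log P(a_t | history, theta)` under the named agent family with a
#' single parameter vector, natural log, per-block learner resets, and the
#' first trial included with its model probability (uniform for Q-models
#' with zero-initialised values). Probabilities are floored at 1e-12.
#'
#' @param session A single subject's session tibble.
#' @param study Study preset naming the agent family.
#' @param theta Named parameter vector within the supports.
#' @return The scalar negative log-likelihood.
#' @export
#' @examples
#' set.seed(1)
#' s <- simulate_agent(task_validation(), init = c(alpha = 0.3, beta = 5))
#' negative_log_likelihood(s, "validation", c(alpha = 0.3, beta = 5))
negative_log_likelihood <- function(session, study = "validation", theta) {
  if (length(unique(session$subject)) > 1) {
    rlang::abort("negative_log_likelihood() takes a single session")
  }
  spec <- param_spec(study)
  .check_params_in_support(as.list(theta), spec)
  ar <- .session_arrays(session)
  nll_cpp(.model_info(.model_for_study(study))$code,
          unname(theta[spec$param]), ar$actions, ar$rewards, ar$block)
}

#' Stationary maximum-likelihood fits
#'
#' Fits a single, fixed parameter vector per subject by box-constrained
#' quasi-Newton (L-BFGS-B) minimisation of the negative log-likelihood from
#' `n_starts` random starting locations within the supports (to avoid local
#' maxima); the best optimum is kept.
#'
#' @param data Sessions tibble (one or more subjects).
#' @param study Study preset naming the agent family and supports.
#' @param n_starts Number of random starts (default 5).
#' @return An `mle_fit` with `$estimates`: one row per subject with the
#'   fitted parameters, `nll`, and a convergence flag.
#' @export
fit_mle <- function(data, study = "validation", n_starts = 5) {
  spec <- param_spec(study)
  code <- .model_info(.model_for_study(study))$code
  eps <- 1e-9
  fits <- lapply(.split_sessions(data), function(ss) {
    ar <- .session_arrays(ss)
    fn <- function(th) nll_cpp(code, th, ar$actions, ar$rewards, ar$block)
    best <- NULL
    conv <- FALSE
    for (k in seq_len(n_starts)) {
      start <- stats::runif(nrow(spec), spec$lower, spec$upper)
      opt <- tryCatch(
        stats::optim(start, fn, method = "L-BFGS-B",
                     lower = spec$lower + eps, upper = spec$upper - eps),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (is.null(best) || opt$value < best$value) best <- opt
      if (opt$convergence == 0) conv <- TRUE
    }
    if (is.null(best)) {
      rlang::abort(sprintf("all starts failed for subject %s", ss$subject[1]))
    }
    est <- as.list(best$par)
    names(est) <- spec$param
    tibble::tibble(subject = ss$subject[1], !!!est, nll = best$value,
                   converged = conv)
  })
  structure(list(estimates = dplyr::bind_rows(fits), study = study,
                 n_starts = n_starts),
            class = "mle_fit")
}

#' @export
print.mle_fit <- function(x, ...) {
  cat(sprintf("<mle_fit> %s model, %d subjects, %d starts\n",
              .model_for_study(x$study), nrow(x$estimates), x$n_starts))
  print(x$estimates)
  invisible(x)
}

#' Per-trial predictions from a stationary fit
#'
#' Replays each session under the fitted (fixed) parameters to produce the
#' per-trial probability of the observed arm choices; the single parameter
#' vector is broadcast over trials in the `<param>_hat` columns.
#'
#' @param object An `mle_fit`.
#' @param newdata Sessions tibble (subjects must be present in the fit).
#' @param ... Unused.
#' @return Tibble `subject`, `block`, `trial`, `pred_left`, `<param>_hat`.
#' @export
predict.mle_fit <- function(object, newdata, ...) {
  spec <- param_spec(object$study)
  code <- .model_info(.model_for_study(object$study))$code
  out <- lapply(.split_sessions(newdata), function(ss) {
    row <- object$estimates[object$estimates$subject == ss$subject[1], ]
    if (nrow(row) != 1) {
      rlang::abort(sprintf("no fit for subject %s", ss$subject[1]))
    }
    th <- unlist(row[spec$param])
    ar <- .session_arrays(ss)
    theta <- matrix(th, nrow(ss), length(th), byrow = TRUE)
    pl <- choice_probs_cpp(code, theta, ar$actions, ar$rewards, ar$block)
    res <- dplyr::select(ss, dplyr::all_of(c("subject", "block", "trial")))
    res$pred_left <- pl
    for (p in spec$param) res[[paste0(p, "_hat")]] <- row[[p]]
    res
  })
  dplyr::bind_rows(out)
}

#' Particle-filter configuration
#'
#' Study presets for the sequential Monte Carlo baseline (1000 particles).
#' Learning rates (`alpha`) are filtered on the log-odds scale through a
#' logistic link (their printed initial means/variances are only sensible on
#' an unbounded scale) and mapped back to the support; the remaining
#' parameters are filtered in native space and clipped to their printed
#' ranges after each propagation. Presets: validation — initial Gaussians
#' means (0, 0), variances (3, 1), drift `sigma` = (0.1, 0.05), `beta`
#' clipped to (0, 10); psychiatric — means (-2, 1, 0), variances
#' (1.5, 1, 1.5), `sigma` = (0.05, 0.005, 0.05); exploration — means
#' (0, -2), variances (1, 1), `sigma` = (0.1, 0.1), `beta` clipped to
#' (0, 4).
#'
#' @param study Study preset.
#' @param n_particles Number of particles.
#' @param sigma Optional named override of the per-parameter drift s.d.
#' @return A `pf_config` list.
#' @export
pf_config <- function(study = "validation", n_particles = 1000, sigma = NULL) {
  spec <- param_spec(study)
  preset <- switch(study,
    validation = list(mean = c(0, 0), var = c(3, 1), sigma = c(0.1, 0.05),
                      logistic = c(TRUE, FALSE)),
    psychiatric = list(mean = c(-2, 1, 0), var = c(1.5, 1, 1.5),
                       sigma = c(0.05, 0.005, 0.05),
                       logistic = c(TRUE, FALSE, FALSE)),
    exploration = list(mean = c(0, -2), var = c(1, 1), sigma = c(0.1, 0.1),
                       logistic = c(FALSE, FALSE)),
    rlang::abort(sprintf("unknown study '%s'", study))
  )
  if (!is.null(sigma)) preset$sigma[match(names(sigma), spec$param)] <- sigma
  structure(list(
    study = study, params = spec$param, n_particles = as.integer(n_particles),
    init_mean = preset$mean, init_var = preset$var, sigma = preset$sigma,
    lower = spec$lower, upper = spec$upper, logistic = preset$logistic,
    scale = spec$upper  # logistic link maps to (0, upper)
  ), class = "pf_config")
}

#' Bayesian particle filtering of drifting parameters
#'
#' Trial-by-trial posterior estimation under the assumption that the latent
#' parameters drift as a Gaussian random walk. Per trial the particles are
#' propagated by the walk, weighted by the model's likelihood of the observed
#' action, and systematically resampled; each particle carries its own
#' learner state. The reported per-trial estimate is the reweighted posterior
#' mean before resampling; `pred_left` is the predictive probability of arm L
#' before observing the trial's action.
#'
#' @param data Sessions tibble.
#' @param config A [pf_config()].
#' @return A `pf_fit`; `$trajectories` holds per-trial posterior means
#'   (`<param>_hat`), variances (`<param>_var`), the effective sample size
#'   `ess`, and `pred_left`.
#' @export
particle_filter <- function(data, config = pf_config("validation")) {
  stopifnot(inherits(config, "pf_config"))
  code <- .model_info(.model_for_study(config$study))$code
  out <- lapply(.split_sessions(data), function(ss) {
    ar <- .session_arrays(ss)
    res <- pf_cpp(code, ar$actions, ar$rewards, ar$block, config$n_particles,
                  config$init_mean, sqrt(config$init_var), config$sigma,
                  config$lower, config$upper, as.integer(config$logistic),
                  config$scale)
    tr <- dplyr::select(ss, dplyr::all_of(c("subject", "block", "trial")))
    for (i in seq_along(config$params)) {
      tr[[paste0(config$params[i], "_hat")]] <- res$mean[, i]
      tr[[paste0(config$params[i], "_var")]] <- res$var[, i]
    }
    tr$ess <- as.vector(res$ess)
    tr$pred_left <- as.vector(res$pred_left)
    tr
  })
  structure(list(trajectories = dplyr::bind_rows(out), config = config),
            class = "pf_fit")
}

#' @export
print.pf_fit <- function(x, ...) {
  cat(sprintf("<pf_fit> %s preset, %d particles, %d subjects\n",
              x$config$study, x$config$n_particles,
              length(unique(x$trajectories$subject))))
  invisible(x)
}

#' @export
predict.pf_fit <- function(object, newdata = NULL, ...) {
  tr <- object$trajectories
  dplyr::select(tr, -dplyr::ends_with("_var"), -"ess")
}

#' Oracle predictions from the true generative model
#'
#' Replays each simulated session under the *true* per-trial parameters,
#' yielding the generative policy's choice probabilities — a lower bound on
#' the achievable action prediction error for any estimator.
#'
#' @param data A `bandit_sim`/`bandit_cohort` containing the true parameter
#'   columns.
#' @param study Study preset naming the agent family.
#' @return Tibble `subject`, `block`, `trial`, `pred_left`.
#' @export
oracle_predict <- function(data, study = "validation") {
  spec <- param_spec(study)
  if (!all(spec$param %in% names(data))) {
    rlang::abort("oracle_predict() needs the true parameter columns")
  }
  code <- .model_info(.model_for_study(study))$code
  out <- lapply(.split_sessions(data), function(ss) {
    ar <- .session_arrays(ss)
    theta <- as.matrix(ss[spec$param])
    res <- dplyr::select(ss, dplyr::all_of(c("subject", "block", "trial")))
    res$pred_left <- choice_probs_cpp(code, theta, ar$actions, ar$rewards,
                                      ar$block)
    res
  })
  dplyr::bind_rows(out)
}

#' Data-driven recurrent network (action prediction only)
#'
#' A single GRU layer (default 10 hidden units) over the `(a_t, r_t)` stream
#' with a softmax head predicting the next action — no theoretical-parameter
#' heads. Trained with Adam (learning rate 0.001) and next-action
#' cross-entropy.
#'
#' @param data Sessions tibble (>= 2 subjects; equal session lengths).
#' @param hidden GRU cells.
#' @param learn_rate,batch_size,max_epochs,patience,val_fraction Training
#'   controls; early stopping uses an agent-level validation split.
#' @param seed Integer seed; drawn from the session RNG when `NULL`.
#' @return A `drnn_fit` usable with `predict()`.
#' @export
drnn_train <- function(data, hidden = 10, learn_rate = 0.001,
                       batch_size = 1000, max_epochs = 100, patience = 5,
                       val_fraction = 0.2, seed = NULL) {
  data <- sessions_only(data)
  subjects <- unique(data$subject)
  tt <- .cohort_tensors(data, params = character(0),
                        spec = quantization_spec("validation"))
  n <- length(subjects)
  n_val <- max(1L, round(val_fraction * n))
  if (n - n_val < 1) rlang::abort("need at least 2 subjects")
  val_set <- sample(n, n_val)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  res <- trnn_train_cpp(
    tt$X, tt$cls, tt$theta,
    tt$anext, setdiff(seq_len(n), val_set) - 1L, val_set - 1L,
    integer(0), numeric(0), numeric(0), 1L, as.integer(hidden), 0,
    learn_rate, as.integer(batch_size), as.integer(max_epochs),
    as.integer(patience), FALSE, as.integer(seed)
  )
  structure(list(weights = res$weights, hidden = as.integer(hidden),
                 best_epoch = res$best_epoch, best_val = res$best_val),
            class = "drnn_fit")
}

#' @export
predict.drnn_fit <- function(object, newdata, ...) {
  nd <- sessions_only(newdata)
  tt <- .cohort_tensors(nd, params = character(0),
                        spec = quantization_spec("validation"))
  out <- trnn_predict_cpp(object$weights, tt$X, integer(0), 1L,
                          object$hidden, FALSE)
  T_ <- tt$n_trials
  nd <- nd[order(match(nd$subject, tt$subjects)), ]
  pred <- dplyr::select(nd, dplyr::all_of(c("subject", "block", "trial")))
  pl <- out$p_next_left
  pred$pred_left <- as.vector(rbind(NA_real_, pl[-T_, , drop = FALSE]))
  pred
}

#' Leave-one-subject-out cross-validated d-RNN predictions
#'
#' For each subject (optionally within a grouping label, e.g. diagnostic
#' group), trains on all other subjects (of the same group) and predicts the
#' withheld subject.
#'
#' @param data Sessions tibble.
#' @param group Optional named character vector mapping subject to group; the
#'   fold then trains only within the withheld subject's group.
#' @param ... Passed to [drnn_train()].
#' @return Tibble of out-of-fold predictions for every subject.
#' @export
drnn_loocv <- function(data, group = NULL, ...) {
  data <- sessions_only(data)
  subjects <- unique(data$subject)
  if (length(subjects) < 2) rlang::abort("LOOCV needs at least 2 subjects")
  preds <- lapply(subjects, function(s) {
    pool <- if (is.null(group)) setdiff(subjects, s) else
      setdiff(subjects[group[subjects] == group[[s]]], s)
    if (length(pool) < 2) rlang::abort("each fold needs >= 2 training subjects")
    fit <- drnn_train(dplyr::filter(data, .data$subject %in% pool), ...)
    predict(fit, dplyr::filter(data, .data$subject == s))
  })
  dplyr::bind_rows(preds)
}
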