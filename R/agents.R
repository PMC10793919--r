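# Theoretical agent families: value-learning updates, choice policies,
# parameter dynamics, and full-session simulation with known ground-truth
# parameter trajectories.

#' Q-learning value update
#'
#' Moves the chosen arm's value toward the received reward by the learning
#' rate: \code{Q(a) <- Q(a) + alpha * (r - Q(a))}. The other arm is
#' unchanged. The prediction error (TD error, reward minus current value) is
#' returned for diagnostics.
#'
#' @param q Numeric length-2 vector of Q-values, ordered (L, R).
#' @param action `"L"` or `"R"` (or 1/2).
#' @param reward Numeric reward.
#' @param alpha Learning rate in \[0, 1\].
#' @return List with `q` (updated values) and `td_error`.
#' @export
#' @examples
#' q_update(c(0, 0), "L", 1, alpha = 0.5)
q_update <- function(q, action, reward, alpha) {
  stopifnot(length(q) == 2, alpha >= 0, alpha <= 1)
  a <- .action_index(action)
  delta <- reward - q[a]
  q[a] <- q[a] + alpha * delta
  list(q = q, td_error = delta)
}

#' Boltzmann (softmax) choice policy
#'
#' `P(a) proportional to exp(beta * Q(a))`. `beta = 0` gives uniform choice;
#' large `beta` approaches greedy selection. Overflow-safe via max
#' subtraction.
#'
#' @param q Numeric length-2 vector of Q-values, ordered (L, R).
#' @param beta Inverse temperature, `beta >= 0`.
#' @return Named probability vector `c(L = , R = )` summing to 1.
#' @export
#' @examples
#' boltzmann_policy(c(0.5, 0), beta = 2)
boltzmann_policy <- function(q, beta) {
  stopifnot(length(q) == 2, beta >= 0)
  z <- beta * q
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  c(L = p[1], R = p[2])
}

#' Softmax policy with a perseveration bonus
#'
#' Adds a bonus `kappa` to the arm chosen on the previous trial before the
#' softmax: `P(a) proportional to exp(beta * (Q(a) + kappa * [a == prev]))`.
#' Positive `kappa` favours staying, negative favours switching. With no
#' previous action (first trial of a session) the bonus is zero for both
#' arms, and the policy reduces to [boltzmann_policy()]; the same holds for
#' `kappa = 0`.
#'
#' @inheritParams boltzmann_policy
#' @param kappa Perseveration bonus in \[-0.5, 0.5\].
#' @param prev_action Previous action (`"L"`/`"R"`) or `NULL`.
#' @return Named probability vector `c(L = , R = )`.
#' @export
perseveration_policy <- function(q, beta, kappa, prev_action = NULL) {
  stopifnot(length(q) == 2, beta >= 0, kappa >= -0.5, kappa <= 0.5)
  bonus <- c(0, 0)
  if (!is.null(prev_action) && !is.na(prev_action)) {
    bonus[.action_index(prev_action)] <- kappa
  }
  boltzmann_policy(q + bonus, beta)
}

#' Kalman-filter value update
#'
#' Posterior mean and variance update for the chosen arm:
#' `K = sigma2 / (sigma2 + tau2)`, `Q <- Q + K (r - Q)`,
#' `sigma2 <- sigma2 - K sigma2`. Block starts reset `Q = 0`,
#' `sigma2 = 100`.
#'
#' @param q Length-2 posterior means (L, R).
#' @param variance Length-2 posterior variances, strictly positive.
#' @param action,reward Chosen arm and observed reward.
#' @param error_variance Observation noise variance `tau2` (default 10).
#' @return List with `q`, `variance`, and the Kalman `gain` used.
#' @export
#' @examples
#' kalman_step(c(0, 0), c(100, 100), "L", 5)
kalman_step <- function(q, variance, action, reward, error_variance = 10) {
  stopifnot(length(q) == 2, length(variance) == 2, all(variance > 0))
  a <- .action_index(action)
  k <- variance[a] / (variance[a] + error_variance)
  q[a] <- q[a] + k * (reward - q[a])
  variance[a] <- variance[a] - k * variance[a]
  list(q = q, variance = variance, gain = k)
}

#' Hybrid random/directed exploration policy
#'
#' Probit policy combining Thompson-sampling-like random exploration and a
#' UCB-like information bonus:
#' `P(L) = Phi(beta * (Q_L - Q_R) / sqrt(s2_L + s2_R) + gamma * (s_L - s_R))`
#' where `s` denotes posterior standard deviations.
#'
#' @param q Length-2 posterior means.
#' @param variance Length-2 posterior variances; their sum must be positive.
#' @param beta Random-exploration weight in \[0, 4\].
#' @param gamma Directed-exploration (information bonus) weight in \[0, 1\].
#' @return Named probability vector `c(L = , R = )`.
#' @export
hybrid_policy <- function(q, variance, beta, gamma) {
  stopifnot(length(q) == 2, length(variance) == 2)
  if (sum(variance) <= 0) rlang::abort("total posterior variance is zero")
  z <- beta * (q[1] - q[2]) / sqrt(sum(variance)) +
    gamma * (sqrt(variance[1]) - sqrt(variance[2]))
  p <- stats::pnorm(z)
  c(L = p, R = 1 - p)
}

#' Parameter dynamics specification
#'
#' Describes how an agent's parameters evolve over trials:
#' * `"stationary"`: constant.
#' * `"jump"`: with probability `jump_prob` per trial all parameters are
#'   re-sampled from their uniform priors; at most `max_jumps` events per
#'   session, and after each event the jump probability is held at zero for
#'   `refractory` trials.
#' * `"walk"`: Gaussian random walk, `theta <- theta + Normal(0, walk_sd)`
#'   per parameter, clipped to the support after each step.
#'
#' @param kind One of `"stationary"`, `"jump"`, `"walk"`.
#' @param jump_prob Per-trial re-sampling probability.
#' @param max_jumps Cap on jump events per session.
#' @param refractory Trials with jump probability forced to zero after an
#'   event.
#' @param walk_sd Named per-parameter step standard deviations.
#' @return A `dynamics_spec` list.
#' @export
#' @examples
#' dynamics_spec("jump", jump_prob = 0.005)
#' dynamics_spec("walk", walk_sd = c(alpha = 0.1, beta = 0.05))
dynamics_spec <- function(kind = c("stationary", "jump", "walk"),
                          jump_prob = 0.005, max_jumps = 4, refractory = 100,
                          walk_sd = NULL) {
  kind <- match.arg(kind)
  stopifnot(jump_prob >= 0, jump_prob <= 1, max_jumps >= 0, refractory >= 0)
  if (kind == "walk") {
    if (is.null(walk_sd) || is.null(names(walk_sd)))
      rlang::abort("walk dynamics need a named `walk_sd` vector")
    stopifnot(all(walk_sd >= 0))
  }
  structure(list(kind = kind, jump_prob = jump_prob,
                 max_jumps = as.integer(max_jumps),
                 refractory = as.integer(refractory), walk_sd = walk_sd),
            class = "dynamics_spec")
}

#' Advance parameters by one trial
#'
#' One step of the parameter process of [dynamics_spec()]. `state` carries
#' the jump bookkeeping (`n_jumps`, `cooldown`) across calls; pass the
#' returned `state` back in.
#'
#' @param values Named parameter vector.
#' @param spec A [dynamics_spec()].
#' @param priors Parameter tibble as from [param_spec()] (uniform priors over
#'   support; also the clipping range for walks).
#' @param state Internal jump state, or `NULL` at the first trial.
#' @return List with `values`, `state`, and `jumped` (logical).
#' @export
advance_params <- function(values, spec, priors, state = NULL) {
  if (is.null(state)) state <- list(n_jumps = 0L, cooldown = 0L)
  jumped <- FALSE
  if (spec$kind == "jump") {
    if (state$cooldown > 0L) {
      state$cooldown <- state$cooldown - 1L
    } else if (state$n_jumps < spec$max_jumps &&
               stats::runif(1) < spec$jump_prob) {
      values[priors$param] <- stats::runif(nrow(priors), priors$lower,
                                           priors$upper)
      state$n_jumps <- state$n_jumps + 1L
      state$cooldown <- spec$refractory
      jumped <- TRUE
    }
  } else if (spec$kind == "walk") {
    for (p in priors$param) {
      sdp <- spec$walk_sd[[p]]
      if (is.null(sdp)) sdp <- 0
      row <- priors[priors$param == p, ]
      values[[p]] <- min(max(values[[p]] + stats::rnorm(1, 0, sdp), row$lower),
                         row$upper)
    }
  }
  list(values = values, state = state, jumped = jumped)
}

#' Ground-truth parameter trajectory for one session
#'
#' Applies [advance_params()] trial by trial. The values in force *during*
#' trial t (used to generate that trial's action) are row t; a jump takes
#' effect from the trial at which it is drawn. Trial 1 holds the initial
#' values.
#'
#' @param init Named initial parameter vector.
#' @param spec A [dynamics_spec()].
#' @param priors Parameter tibble as from [param_spec()].
#' @param n_trials Session length.
#' @return Matrix `n_trials x m` with parameter columns; attribute `jumps`
#'   lists the trials at which re-sampling events occurred.
#' @export
param_trajectory <- function(init, spec, priors, n_trials) {
  .check_params_in_support(as.list(init), priors)
  m <- nrow(priors)
  out <- matrix(NA_real_, n_trials, m, dimnames = list(NULL, priors$param))
  values <- init[priors$param]
  state <- NULL
  jumps <- integer(0)
  out[1, ] <- values
  for (t in seq_len(n_trials)[-1]) {
    step <- advance_params(values, spec, priors, state)
    values <- step$values
    state <- step$state
    if (step$jumped) jumps <- c(jumps, t)
    out[t, ] <- values
  }
  attr(out, "jumps") <- jumps
  out
}

#' Simulate one agent on a bandit task
#'
#' Runs a full session of a theoretical agent: learner state (Q-values, and
#' posterior variances for the Kalman family) resets at every block start,
#' parameters evolve per the dynamics every trial, actions are sampled from
#' the model's policy, and rewards from the task's scheme. The previous
#' action used by the perseveration bonus carries across block boundaries.
#'
#' @param task A `bandit_task`.
#' @param study Study preset naming the agent family and parameter supports.
#' @param init Named initial parameter values; drawn from the uniform priors
#'   when `NULL`.
#' @param dynamics A [dynamics_spec()].
#' @param subject Subject label.
#' @return A `bandit_sim` tibble with one row per trial: `subject`, `block`,
#'   `trial`, `action`, `reward`, the true per-trial parameter columns, the
#'   per-trial arm reward parameters (`arm_left`, `arm_right`) and the
#'   policy's true choice probability `p_left_true`.
#' @export
#' @examples
#' set.seed(7)
#' sim <- simulate_agent(task_validation(), init = c(alpha = 0.3, beta = 5))
#' head(sim)
simulate_agent <- function(task, study = "validation", init = NULL,
                           dynamics = dynamics_spec("stationary"),
                           subject = "agent01") {
  stopifnot(inherits(task, "bandit_task"))
  info <- .study_info(study)
  priors <- param_spec(study)
  if (is.null(init)) {
    init <- stats::runif(nrow(priors), priors$lower, priors$upper)
    names(init) <- priors$param
  }
  ex <- .expand_task(task)
  n <- length(ex$block_id)
  theta <- param_trajectory(init, dynamics, priors, n)
  res <- sim_session_cpp(.model_info(info$model)$code, theta,
                         as.integer(ex$block_id), ex$arm_left, ex$arm_right,
                         ex$gaussian, ex$tau2)
  out <- tibble::tibble(
    subject = subject, block = as.integer(ex$block_id),
    trial = as.integer(ex$trial),
    action = c("L", "R")[res$action + 1L], reward = res$reward
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(theta))
  out$arm_left <- ex$arm_left
  out$arm_right <- ex$arm_right
  out$p_left_true <- res$p_left
  class(out) <- c("bandit_sim", class(out))
  attr(out, "study") <- study
  attr(out, "model") <- info$model
  out
}

#' Strip ground-truth columns from simulated data
#'
#' Returns only the observable session record (`subject`, `block`, `trial`,
#' `action`, `reward`) — what an estimator is allowed to see.
#'
#' @param data A `bandit_sim` or sessions tibble.
#' @return A tibble of observables.
#' @export
sessions_only <- function(data) {
  dplyr::select(tibble::as_tibble(data),
                dplyr::all_of(c("subject", "block", "trial", "action", "reward")))
}
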