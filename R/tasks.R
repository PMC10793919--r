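# Two-armed bandit task structures: block schedules and reward-generation
# processes for the three study designs plus the volatile (random-walk) variant.

.new_task <- function(blocks, study, scheme, walk = NULL, pool = NULL) {
  out <- tibble::as_tibble(blocks)
  class(out) <- c("bandit_task", class(out))
  attr(out, "study") <- study
  attr(out, "scheme") <- scheme
  attr(out, "walk") <- walk
  attr(out, "pool") <- pool
  out
}

#' Bandit task of the validation study
#'
#' Ten blocks of 100 trials. At the start of each block the pair of Bernoulli
#' reward probabilities is drawn uniformly from the three-element pool
#' \{(0.1, 0.9), (0.5, 0.5), (0.9, 0.1)\}. Binary rewards (r = 1 or 0).
#'
#' @param n_blocks,n_trials Block count and trials per block.
#' @param pool List of length-2 numeric vectors `(Pr_L, Pr_R)` sampled
#'   uniformly per block. Restricting the pool to one setting yields identical
#'   blocks.
#' @return A `bandit_task` tibble with columns `block`, `n_trials`, `p_left`,
#'   `p_right`.
#' @export
#' @examples
#' set.seed(1)
#' task_validation()
task_validation <- function(n_blocks = 10, n_trials = 100,
                            pool = list(c(0.1, 0.9), c(0.5, 0.5), c(0.9, 0.1))) {
  stopifnot(n_blocks >= 1, n_trials >= 1, length(pool) >= 1)
  idx <- sample.int(length(pool), n_blocks, replace = TRUE)
  arms <- do.call(rbind, pool[idx])
  .new_task(
    tibble::tibble(block = seq_len(n_blocks), n_trials = as.integer(n_trials),
                   p_left = arms[, 1], p_right = arms[, 2]),
    study = "validation", scheme = "bernoulli", pool = pool
  )
}

#' Bandit task of the psychiatric study
#'
#' Twelve blocks with Bernoulli arm pairs drawn from six possible settings,
#' all of which place one arm at probability 0.05. With `balanced = TRUE`
#' (the empirical regime) each setting occurs exactly twice in shuffled
#' order; otherwise settings are drawn uniformly at random per block (the
#' synthetic-training regime, 100 trials per block).
#'
#' @param n_trials Trials per block (the synthetic training regime uses 100).
#' @param balanced If `TRUE`, each of the six settings appears exactly twice.
#' @return A `bandit_task` tibble.
#' @export
task_psychiatric <- function(n_trials = 100, balanced = FALSE) {
  pool <- list(c(0.25, 0.05), c(0.125, 0.05), c(0.08, 0.05),
               c(0.05, 0.25), c(0.05, 0.125), c(0.05, 0.08))
  idx <- if (balanced) sample(rep(seq_along(pool), 2L)) else
    sample.int(length(pool), 12L, replace = TRUE)
  arms <- do.call(rbind, pool[idx])
  .new_task(
    tibble::tibble(block = seq_len(12L), n_trials = as.integer(n_trials),
                   p_left = arms[, 1], p_right = arms[, 2]),
    study = "psychiatric", scheme = "bernoulli", pool = pool
  )
}

#' Bandit task of the exploration study
#'
#' Twenty blocks of 10 trials. Each arm's mean reward is drawn independently
#' per block from Normal(0, variance 100); rewards are Gaussian around the
#' arm mean with error variance `tau2` = 10.
#'
#' @param n_blocks,n_trials Block count and trials per block.
#' @param mean_variance Prior variance of the per-block arm means.
#' @param tau2 Reward (error) variance, shared by both arms.
#' @return A `bandit_task` tibble with columns `mu_left`, `mu_right`, `tau2`.
#' @export
task_exploration <- function(n_blocks = 20, n_trials = 10,
                             mean_variance = 100, tau2 = 10) {
  stopifnot(tau2 > 0, mean_variance >= 0)
  .new_task(
    tibble::tibble(
      block = seq_len(n_blocks), n_trials = as.integer(n_trials),
      mu_left = stats::rnorm(n_blocks, 0, sqrt(mean_variance)),
      mu_right = stats::rnorm(n_blocks, 0, sqrt(mean_variance)),
      tau2 = tau2
    ),
    study = "exploration", scheme = "gaussian"
  )
}

#' Volatile bandit task (bounded random-walk reward probabilities)
#'
#' Like the validation task, but instead of fixed per-block probabilities the
#' per-trial reward probability of each arm follows a Gaussian random walk
#' with step s.d. `drift`, clipped after each step into
#' `[bounds[1], bounds[2]]`. Starting probabilities are drawn uniformly
#' within the bounds at each block start.
#'
#' @param n_blocks,n_trials Block count and trials per block.
#' @param drift Per-trial step standard deviation of the walk.
#' @param bounds Lower and upper bounds the probabilities are clipped to.
#' @return A `bandit_task` tibble; the walk itself is realised per agent at
#'   simulation time (see [simulate_agent()]).
#' @export
task_volatile <- function(n_blocks = 10, n_trials = 100, drift = 0.025,
                          bounds = c(0.15, 0.85)) {
  stopifnot(bounds[1] < bounds[2], drift >= 0)
  .new_task(
    tibble::tibble(
      block = seq_len(n_blocks), n_trials = as.integer(n_trials),
      p_left = stats::runif(n_blocks, bounds[1], bounds[2]),
      p_right = stats::runif(n_blocks, bounds[1], bounds[2])
    ),
    study = "volatile", scheme = "bernoulli_walk",
    walk = list(drift = drift, bounds = bounds)
  )
}

#' Bounded Gaussian random-walk path
#'
#' The per-trial reward-probability schedule of the volatile task: a Gaussian
#' random walk with step s.d. `drift`, clipped to `[lower, upper]` after
#' every step.
#'
#' @param n Number of steps (path length, including the start).
#' @param start Starting value.
#' @param drift Step standard deviation.
#' @param lower,upper Clipping bounds.
#' @return Numeric vector of length `n`.
#' @export
random_walk_path <- function(n, start, drift, lower, upper) {
  stopifnot(lower < upper)
  x <- numeric(n)
  x[1] <- min(max(start, lower), upper)
  if (n > 1) {
    steps <- stats::rnorm(n - 1, 0, drift)
    for (i in 2:n) x[i] <- min(max(x[i - 1] + steps[i - 1], lower), upper)
  }
  x
}

.action_index <- function(action) {
  if (is.character(action) || is.factor(action)) {
    a <- match(as.character(action), c("L", "R"))
    if (anyNA(a)) rlang::abort("actions must be 'L' or 'R'")
    return(a)
  }
  a <- as.integer(action)
  if (any(!a %in% c(1L, 2L))) rlang::abort("numeric actions must be 1 (L) or 2 (R)")
  a
}

#' Draw rewards from a task block
#'
#' Bernoulli blocks return r in \{0, 1\} with the arm's reward probability;
#' Gaussian blocks return r ~ Normal(arm mean, `tau2`). Vectorised over
#' `action`. Blocks of the volatile scheme have per-trial probabilities that
#' are realised inside [simulate_agent()] and cannot be drawn from here.
#'
#' @param task A `bandit_task`.
#' @param block Block number.
#' @param action `"L"`/`"R"` (or 1/2).
#' @return Numeric vector of rewards, one per element of `action`.
#' @export
#' @examples
#' set.seed(1)
#' t <- task_validation()
#' draw_reward(t, 1, c("L", "R", "L"))
draw_reward <- function(task, block, action) {
  stopifnot(inherits(task, "bandit_task"))
  scheme <- attr(task, "scheme")
  if (scheme == "bernoulli_walk") {
    rlang::abort("volatile blocks have per-trial probabilities; use simulate_agent()")
  }
  row <- task[task$block == block, ]
  if (nrow(row) != 1) rlang::abort(sprintf("no block %s in task", block))
  a <- .action_index(action)
  if (scheme == "gaussian") {
    mu <- c(row$mu_left, row$mu_right)[a]
    stats::rnorm(length(a), mu, sqrt(row$tau2))
  } else {
    p <- c(row$p_left, row$p_right)[a]
    as.numeric(stats::runif(length(a)) < p)
  }
}

#' Serialise / read a task configuration
#'
#' Tasks round-trip through a YAML text file holding the scheme, the block
#' table and any walk parameters.
#'
#' @param task A `bandit_task`.
#' @param path File path.
#' @return `read_task()` returns a `bandit_task`; `write_task()` returns
#'   `path` invisibly.
#' @export
write_task <- function(task, path) {
  stopifnot(inherits(task, "bandit_task"))
  obj <- list(
    study = attr(task, "study"), scheme = attr(task, "scheme"),
    walk = attr(task, "walk"),
    pool = lapply(attr(task, "pool"), as.numeric),
    blocks = lapply(seq_len(nrow(task)), function(i) as.list(task[i, ]))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_task
#' @export
read_task <- function(path) {
  obj <- yaml::read_yaml(path)
  blocks <- dplyr::bind_rows(lapply(obj$blocks, tibble::as_tibble))
  walk <- obj$walk
  if (!is.null(walk)) walk$bounds <- as.numeric(unlist(walk$bounds))
  pool <- if (length(obj$pool) > 0) lapply(obj$pool, as.numeric) else NULL
  .new_task(blocks, study = obj$study, scheme = obj$scheme, walk = walk,
            pool = pool)
}

.total_trials <- function(task) sum(task$n_trials)

# Expand a task into per-trial arm parameters (realising walks if present).
# Returns list(block_id, trial, arm_left, arm_right, gaussian, tau2).
.expand_task <- function(task) {
  scheme <- attr(task, "scheme")
  block_id <- rep(task$block, task$n_trials)
  trial <- unlist(lapply(task$n_trials, seq_len), use.names = FALSE)
  if (scheme == "gaussian") {
    list(block_id = block_id, trial = trial,
         arm_left = rep(task$mu_left, task$n_trials),
         arm_right = rep(task$mu_right, task$n_trials),
         gaussian = TRUE, tau2 = task$tau2[1])
  } else if (scheme == "bernoulli_walk") {
    w <- attr(task, "walk")
    aL <- unlist(lapply(seq_len(nrow(task)), function(i) {
      random_walk_path(task$n_trials[i], task$p_left[i], w$drift,
                       w$bounds[1], w$bounds[2])
    }), use.names = FALSE)
    aR <- unlist(lapply(seq_len(nrow(task)), function(i) {
      random_walk_path(task$n_trials[i], task$p_right[i], w$drift,
                       w$bounds[1], w$bounds[2])
    }), use.names = FALSE)
    list(block_id = block_id, trial = trial, arm_left = aL, arm_right = aR,
         gaussian = FALSE, tau2 = 0)
  } else {
    list(block_id = block_id, trial = trial,
         arm_left = rep(task$p_left, task$n_trials),
         arm_right = rep(task$p_right, task$n_trials),
         gaussian = FALSE, tau2 = 0)
  }
}
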