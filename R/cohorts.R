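# Training/validation/test cohorts of simulated agents with study priors,
# non-stationary dynamics and quantised class labels.

#' Quantisation specification for latent parameters
#'
#' Each parameter's support is divided into `bins` evenly spaced bins used as
#' intermediate classification targets during network training. Bins are
#' half-open `[edge_i, edge_{i+1})`; the top bin is closed at the upper
#' support edge. Class labels are 0-based.
#'
#' @param study Study preset providing parameters and supports.
#' @param bins Bin count: a single integer applied to every parameter, or a
#'   named per-parameter vector. `NULL` uses the study's printed bin counts
#'   (validation 5/5; psychiatric 3/5/5; exploration 5/5).
#' @return A `quantization_spec` tibble with columns `param`, `lower`,
#'   `upper`, `n_bins`, `width`.
#' @export
#' @examples
#' quantization_spec("validation")
#' quantization_spec("psychiatric")$width  # alpha bin size 0.2/3
quantization_spec <- function(study = "validation", bins = NULL) {
  info <- .study_info(study)
  spec <- param_spec(study)
  if (is.null(bins)) {
    nb <- info$bins[spec$param]
  } else if (length(bins) == 1 && is.null(names(bins))) {
    nb <- rep(as.integer(bins), nrow(spec))
  } else {
    nb <- as.integer(bins[spec$param])
  }
  if (anyNA(nb) || any(nb < 2)) rlang::abort("need >= 2 bins per parameter")
  out <- spec
  out$n_bins <- as.integer(nb)
  out$width <- (out$upper - out$lower) / out$n_bins
  class(out) <- c("quantization_spec", class(out))
  out
}

#' Quantise parameter values to class labels
#'
#' @param values Numeric values within the parameter's support.
#' @param spec A [quantization_spec()].
#' @param param Parameter name.
#' @return Integer 0-based class labels in `[0, n_bins)`.
#' @export
#' @examples
#' quantize(0.35, quantization_spec("validation"), "alpha")  # bin 1
quantize <- function(values, spec, param) {
  row <- spec[spec$param == param, ]
  if (nrow(row) != 1) rlang::abort(sprintf("unknown parameter '%s'", param))
  if (any(values < row$lower - 1e-12 | values > row$upper + 1e-12)) {
    rlang::abort(sprintf("values outside the support of '%s'", param))
  }
  cls <- floor((values - row$lower) / row$width)
  as.integer(pmin(pmax(cls, 0), row$n_bins - 1L))
}

#' @rdname quantize
#' @param class Integer 0-based class labels.
#' @return `dequantize()` returns the bin-centre values.
#' @export
dequantize <- function(class, spec, param) {
  row <- spec[spec$param == param, ]
  if (nrow(row) != 1) rlang::abort(sprintf("unknown parameter '%s'", param))
  if (any(class < 0 | class >= row$n_bins)) rlang::abort("class out of range")
  row$lower + (class + 0.5) * row$width
}

.study_task <- function(study) {
  switch(study,
    validation = task_validation(),
    psychiatric = task_psychiatric(),
    exploration = task_exploration(),
    volatile = task_volatile(),
    rlang::abort(sprintf("unknown study '%s'", study))
  )
}

.study_jump_dynamics <- function(info) {
  dynamics_spec("jump", jump_prob = info$jump_prob, max_jumps = 4,
                refractory = info$refractory)
}

.new_cohort <- function(data, study, qspec) {
  info <- .study_info(study)
  out <- tibble::as_tibble(data)
  class(out) <- c("bandit_cohort", class(out))
  attr(out, "study") <- study
  attr(out, "model") <- info$model
  attr(out, "quantization") <- qspec
  out
}

#' Sample a cohort of simulated agents
#'
#' Simulates `n_agents` sessions under a study preset: each agent gets a
#' fresh task draw, initial parameters from the uniform priors, and
#' jump-resampled ("abruptly changing") parameter dynamics with the study's
#' per-trial probability (0.005, or 0.02 for the exploration study), a cap of
#' four events and a refractory window (100 trials; 10 for exploration).
#'
#' @param study `"validation"`, `"psychiatric"` or `"exploration"`.
#' @param n_agents Number of agents (>= 1).
#' @param bins Optional quantisation override passed to
#'   [quantization_spec()].
#' @param dynamics Optional [dynamics_spec()] override.
#' @return A `bandit_cohort` tibble (per-trial rows for all agents) carrying
#'   the study, model and quantisation spec as attributes. Class labels are
#'   derived on demand with [cohort_labels()], never stored.
#' @export
#' @examples
#' set.seed(1)
#' co <- sample_cohort("validation", n_agents = 2)
#' dplyr::count(co, subject)
sample_cohort <- function(study = c("validation", "psychiatric", "exploration"),
                          n_agents, bins = NULL, dynamics = NULL) {
  study <- match.arg(study)
  stopifnot(n_agents >= 1)
  info <- .study_info(study)
  qspec <- quantization_spec(study, bins)
  if (is.null(dynamics)) dynamics <- .study_jump_dynamics(info)
  ids <- sprintf("agent%04d", seq_len(n_agents))
  sims <- lapply(ids, function(id) {
    simulate_agent(.study_task(study), study = study, dynamics = dynamics,
                   subject = id)
  })
  .new_cohort(dplyr::bind_rows(sims), study, qspec)
}

#' Per-trial quantised class labels of a cohort
#'
#' Labels are recomputed from the stored continuous trajectories and the
#' cohort's quantisation spec (full-precision trajectories are authoritative).
#'
#' @param cohort A `bandit_cohort`.
#' @param spec Optional [quantization_spec()] override.
#' @return Tibble `subject`, `block`, `trial`, one `class_<param>` column per
#'   parameter (0-based labels).
#' @export
cohort_labels <- function(cohort, spec = NULL) {
  if (is.null(spec)) spec <- attr(cohort, "quantization")
  out <- dplyr::select(tibble::as_tibble(cohort),
                       dplyr::all_of(c("subject", "block", "trial")))
  for (p in spec$param) {
    out[[paste0("class_", p)]] <- quantize(cohort[[p]], spec, p)
  }
  out
}

#' Agent-level train/validation split
#'
#' Splits a cohort by subject (never by trial, to avoid leakage between the
#' two sets).
#'
#' @param cohort A `bandit_cohort`.
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @return List with `train` and `val` cohorts (disjoint subjects).
#' @export
split_train_val <- function(cohort, fraction = 0.8) {
  if (fraction <= 0 || fraction >= 1) rlang::abort("fraction must be in (0, 1)")
  subjects <- unique(cohort$subject)
  if (length(subjects) < 2) rlang::abort("need at least 2 agents to split")
  n_train <- round(fraction * length(subjects))
  n_train <- min(max(n_train, 1L), length(subjects) - 1L)
  train_ids <- sample(subjects, n_train)
  st <- attr(cohort, "study")
  qs <- attr(cohort, "quantization")
  list(
    train = .new_cohort(dplyr::filter(cohort, .data$subject %in% train_ids), st, qs),
    val = .new_cohort(dplyr::filter(cohort, !.data$subject %in% train_ids), st, qs)
  )
}

#' The 30-agent validation test suite
#'
#' Three groups of `n_per_group` agents on the validation task: stationary
#' parameters; jump dynamics (p = 0.005, cap 4, refractory 100); and
#' Gaussian-random-walk drift with `sigma_alpha` = 0.1, `sigma_beta` = 0.05.
#'
#' @param n_per_group Agents per group (default 10).
#' @param walk_sd Named step s.d. of the walk group.
#' @return A `bandit_cohort` with an extra `group` column
#'   (`"stationary"`, `"jump"`, `"walk"`).
#' @export
make_test_suite <- function(n_per_group = 10,
                            walk_sd = c(alpha = 0.1, beta = 0.05)) {
  info <- .study_info("validation")
  dyn <- list(
    stationary = dynamics_spec("stationary"),
    jump = .study_jump_dynamics(info),
    walk = dynamics_spec("walk", walk_sd = walk_sd)
  )
  sims <- list()
  k <- 0
  for (g in names(dyn)) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1
      s <- simulate_agent(task_validation(), study = "validation",
                          dynamics = dyn[[g]],
                          subject = sprintf("test_%s_%02d", g, i))
      s$group <- g
      sims[[k]] <- s
    }
  }
  .new_cohort(dplyr::bind_rows(sims), "validation",
              quantization_spec("validation"))
}

# Pack a cohort into the dense arrays consumed by the compiled network.
# Sessions must all have equal length. Returns X (3,T,N), cls (m,T,N),
# theta (m,T,N), anext (T,N with -1 at the last trial), subjects.
.cohort_tensors <- function(cohort, spec = NULL, params = NULL) {
  if (is.null(spec)) spec <- attr(cohort, "quantization")
  if (is.null(params)) params <- spec$param
  subjects <- unique(cohort$subject)
  lens <- dplyr::count(cohort, .data$subject)$n
  if (length(unique(lens)) != 1) {
    rlang::abort("all sessions must have the same length for batching")
  }
  T_ <- lens[1]
  N <- length(subjects)
  a <- .action_index(cohort$action)
  X <- array(0, c(3, T_, N))
  has_truth <- length(params) > 0 && all(params %in% names(cohort))
  m <- if (has_truth) length(params) else 0L
  cls <- array(0L, c(m, T_, N))
  theta <- array(0, c(m, T_, N))
  anext <- matrix(-1L, T_, N)
  for (j in seq_len(N)) {
    idx <- which(cohort$subject == subjects[j])
    X[1, , j] <- as.numeric(a[idx] == 1L)
    X[2, , j] <- as.numeric(a[idx] == 2L)
    X[3, , j] <- cohort$reward[idx]
    anext[seq_len(T_ - 1), j] <- a[idx][-1] - 1L
    if (has_truth) {
      for (i in seq_along(params)) {
        theta[i, , j] <- cohort[[params[i]]][idx]
        cls[i, , j] <- quantize(cohort[[params[i]]][idx], spec, params[i])
      }
    }
  }
  list(X = X, cls = cls, theta = theta, anext = anext, subjects = subjects,
       n_trials = T_)
}
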