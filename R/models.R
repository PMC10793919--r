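# Registry of the three theoretical agent families and the study presets.
# Internal model codes (shared with the compiled code):
#   0 = "q"  Q-learning (alpha, beta)
#   1 = "qp" Q-learning with perseveration (alpha, beta, kappa)
#   2 = "kf" Kalman-filter learner with hybrid exploration policy (beta, gamma)

.models <- list(
  q = list(code = 0L, params = c("alpha", "beta")),
  qp = list(code = 1L, params = c("alpha", "beta", "kappa")),
  kf = list(code = 2L, params = c("beta", "gamma"))
)

.studies <- list(
  validation = list(
    model = "q",
    supports = list(alpha = c(0, 1), beta = c(0, 10)),
    bins = c(alpha = 5L, beta = 5L),
    lambda_ce = c(alpha = 0.2, beta = 0.2),
    lambda_mse = c(alpha = 6, beta = 0.1),
    jump_prob = 0.005, refractory = 100L,
    n_train_agents = 2000L
  ),
  psychiatric = list(
    model = "qp",
    supports = list(alpha = c(0, 0.2), beta = c(0, 10), kappa = c(-0.5, 0.5)),
    bins = c(alpha = 3L, beta = 5L, kappa = 5L),
    lambda_ce = c(alpha = 0.3, beta = 0.25, kappa = 0.3),
    lambda_mse = c(alpha = 10, beta = 0.05, kappa = 10),
    jump_prob = 0.005, refractory = 100L,
    n_train_agents = 2000L
  ),
  exploration = list(
    model = "kf",
    supports = list(beta = c(0, 4), gamma = c(0, 1)),
    bins = c(beta = 5L, gamma = 5L),
    lambda_ce = c(beta = 0.25, gamma = 0.25),
    lambda_mse = c(beta = 1, gamma = 10),
    jump_prob = 0.02, refractory = 10L,
    n_train_agents = 10000L
  )
)

.study_info <- function(study) {
  study <- match.arg(study, names(.studies))
  .studies[[study]]
}

.model_info <- function(model) {
  model <- match.arg(model, names(.models))
  .models[[model]]
}

.model_for_study <- function(study) .study_info(study)$model

#' Parameter specification of an agent family
#'
#' Returns the free parameters of a theoretical model together with their
#' supports. Priors over parameters are uniform over the support. The supports
#' follow the study conventions: the validation study uses the Q-learning
#' model with `alpha` in \[0, 1\] and `beta` in \[0, 10\]; the psychiatric
#' study restricts `alpha` to \[0, 0.2\] and adds a perseveration bonus
#' `kappa` in \[-0.5, 0.5\]; the exploration study uses the Kalman/hybrid
#' model with `beta` in \[0, 4\] and `gamma` in \[0, 1\].
#'
#' @param study One of `"validation"`, `"psychiatric"`, `"exploration"`.
#' @return A tibble with columns `param`, `lower`, `upper`.
#' @export
#' @examples
#' param_spec("validation")
param_spec <- function(study = "validation") {
  info <- .study_info(study)
  tibble::tibble(
    param = names(info$supports),
    lower = vapply(info$supports, `[`, numeric(1), 1),
    upper = vapply(info$supports, `[`, numeric(1), 2)
  )
}

.check_params_in_support <- function(values, spec) {
  if (is.null(values)) return(invisible(NULL))
  for (p in names(values)) {
    row <- spec[spec$param == p, ]
    if (nrow(row) == 0) {
      rlang::abort(sprintf("unknown parameter '%s'", p))
    }
    if (any(values[[p]] < row$lower - 1e-12 | values[[p]] > row$upper + 1e-12)) {
      rlang::abort(sprintf("parameter '%s' outside its support [%g, %g]",
                           p, row$lower, row$upper))
    }
  }
  invisible(NULL)
}
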