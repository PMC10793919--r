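# broom-style tidiers for fitted objects.

#' Tidy a stationary maximum-likelihood fit
#'
#' @param x An `mle_fit`.
#' @param ... Unused.
#' @return Tibble with `subject`, `term`, `estimate`.
#' @export
tidy.mle_fit <- function(x, ...) {
  params <- param_spec(x$study)$param
  tidyr::pivot_longer(x$estimates, dplyr::all_of(params),
                      names_to = "term", values_to = "estimate") %>%
    dplyr::select(dplyr::all_of(c("subject", "term", "estimate")))
}

#' @rdname tidy.mle_fit
#' @return `glance()`: one row per subject with `nll`, `converged`,
#'   `n_starts`.
#' @export
glance.mle_fit <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$estimates, dplyr::all_of(c("subject", "nll", "converged"))),
    n_starts = x$n_starts)
}

#' Tidy a trained network
#'
#' @param x A `trnn_fit`.
#' @param ... Unused.
#' @return The per-epoch training history in long form (`epoch`, `series`,
#'   `value`).
#' @export
tidy.trnn_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "series",
                      values_to = "value")
}

#' @rdname tidy.trnn_fit
#' @export
glance.trnn_fit <- function(x, ...) {
  tibble::tibble(study = x$config$study, n_train = x$n_train,
                 n_val = x$n_val, epochs_run = nrow(x$history),
                 best_epoch = x$best_epoch, best_val_loss = x$best_val)
}

#' Tidy a particle-filter fit
#'
#' @param x A `pf_fit`.
#' @param ... Unused.
#' @return Posterior trajectories in long form: `subject`, `block`, `trial`,
#'   `param`, `estimate`, `variance`.
#' @export
tidy.pf_fit <- function(x, ...) {
  params <- x$config$params
  est <- tidyr::pivot_longer(
    dplyr::select(x$trajectories, dplyr::all_of(
      c("subject", "block", "trial", paste0(params, "_hat")))),
    dplyr::ends_with("_hat"), names_to = "param", values_to = "estimate") %>%
    dplyr::mutate(param = sub("_hat$", "", .data$param))
  var <- tidyr::pivot_longer(
    dplyr::select(x$trajectories, dplyr::all_of(
      c("subject", "block", "trial", paste0(params, "_var")))),
    dplyr::ends_with("_var"), names_to = "param", values_to = "variance") %>%
    dplyr::mutate(param = sub("_var$", "", .data$param))
  dplyr::left_join(est, var, by = c("subject", "block", "trial", "param"))
}

#' @rdname tidy.pf_fit
#' @export
glance.pf_fit <- function(x, ...) {
  x$trajectories %>%
    dplyr::group_by(.data$subject) %>%
    dplyr::summarise(mean_ess = mean(.data$ess), min_ess = min(.data$ess),
                     .groups = "drop") %>%
    dplyr::mutate(n_particles = x$config$n_particles)
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return The paired-test table.
#' @export
tidy.evaluation_report <- function(x, ...) x$tests

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  x$bce %>%
    dplyr::group_by(.data$method) %>%
    dplyr::summarise(mean_bce = mean(.data$bce),
                     sem_bce = stats::sd(.data$bce) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}
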