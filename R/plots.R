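# ggplot2 graphics for fitted objects and recovery diagnostics.

#' Training-history curves
#'
#' @param object A `trnn_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation total loss by epoch.
#' @export
autoplot.trnn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object$history,
                  dplyr::all_of(c("epoch", "train_total", "val_total"))),
    -"epoch", names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "total loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Posterior parameter trajectories of a particle filter
#'
#' @param object A `pf_fit`.
#' @param subjects Optional subset of subjects.
#' @param ... Unused.
#' @return A ggplot of posterior means with +-1 s.d. ribbons.
#' @export
autoplot.pf_fit <- function(object, subjects = NULL, ...) {
  df <- tidy(object)
  if (!is.null(subjects)) df <- dplyr::filter(df, .data$subject %in% subjects)
  df <- df %>%
    dplyr::group_by(.data$subject, .data$param) %>%
    dplyr::mutate(t = dplyr::row_number()) %>%
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$estimate - sqrt(.data$variance),
      ymax = .data$estimate + sqrt(.data$variance)), alpha = 0.2) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_grid(param ~ subject, scales = "free_y") +
    ggplot2::labs(x = "trial", y = "posterior mean") +
    ggplot2::theme_minimal()
}

#' True vs estimated parameter trajectories
#'
#' Overlay of the ground-truth parameter trajectory and a method's per-trial
#' estimates for selected subjects — the standard visual check of
#' time-varying parameter recovery.
#'
#' @param est Estimate tibble with `<param>_hat` columns.
#' @param truth Simulated data with the true parameter columns.
#' @param params Parameters to show (default: all estimated).
#' @param subjects Optional subset of subjects.
#' @return A ggplot.
#' @export
plot_recovery <- function(est, truth, params = NULL, subjects = NULL) {
  est <- tibble::as_tibble(est)
  if (is.null(params)) {
    params <- sub("_hat$", "", grep("_hat$", names(est), value = TRUE))
  }
  if (!is.null(subjects)) {
    est <- dplyr::filter(est, .data$subject %in% subjects)
    truth <- dplyr::filter(truth, .data$subject %in% subjects)
  }
  joined <- dplyr::inner_join(
    dplyr::select(est, dplyr::all_of(c("subject", "block", "trial",
                                       paste0(params, "_hat")))),
    dplyr::select(tibble::as_tibble(truth),
                  dplyr::all_of(c("subject", "block", "trial", params))),
    by = c("subject", "block", "trial")) %>%
    dplyr::group_by(.data$subject) %>%
    dplyr::mutate(t = dplyr::row_number()) %>%
    dplyr::ungroup()
  long <- dplyr::bind_rows(lapply(params, function(p) {
    tibble::tibble(subject = joined$subject, t = joined$t, param = p,
                   truth = joined[[p]], estimate = joined[[paste0(p, "_hat")]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(.data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$truth), colour = "#d7301f") +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate), colour = "#2c7fb8",
                       linetype = 2) +
    ggplot2::facet_grid(param ~ subject, scales = "free_y") +
    ggplot2::labs(x = "trial", y = "parameter value (truth solid, estimate dashed)") +
    ggplot2::theme_minimal()
}

#' Mean action-prediction error by method
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot bar chart (mean +- s.e.m. per method).
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$mean_bce)) +
    ggplot2::geom_col(fill = "#2c7fb8", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_bce - .data$sem_bce,
      ymax = .data$mean_bce + .data$sem_bce), width = 0.15) +
    ggplot2::labs(x = NULL, y = "action BCE (nats)") +
    ggplot2::theme_minimal()
}
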