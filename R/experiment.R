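# End-to-end experiment orchestration: cohort -> network training -> test
# suite -> all estimators -> evaluation report, with every artifact written
# as tabular text plus the resolved configuration for regeneration.

#' Experiment configuration
#'
#' Bundles every knob of a full simulation experiment under one master seed.
#' All stochastic stages draw from the single R RNG stream seeded once at the
#' start of [run_experiment()], so a configuration regenerates its artifacts
#' exactly.
#'
#' @param study Study preset.
#' @param n_train_agents Training-cohort size (the reference setting is
#'   2000; scaled-down runs commonly use 300).
#' @param n_test_per_group Test agents per dynamics group.
#' @param trnn Named list of [trnn_config()] overrides.
#' @param pf Named list of [pf_config()] overrides.
#' @param mle_starts Random starts for the stationary fits.
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(study = "validation", n_train_agents = 300,
                              n_test_per_group = 10, trnn = list(),
                              pf = list(), mle_starts = 5, seed = 1) {
  structure(list(study = study, n_train_agents = as.integer(n_train_agents),
                 n_test_per_group = as.integer(n_test_per_group),
                 trnn = trnn, pf = pf, mle_starts = as.integer(mle_starts),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML file path.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(experiment_config, obj)
}

#' Run a full validation experiment
#'
#' Simulates a training cohort, trains the network, simulates the
#' stationary/jump/walk test suite, runs every estimator (network,
#' stationary MLE, particle filter, ground-truth oracle), evaluates them,
#' and writes all intermediate tables, the resolved configuration and a log
#' to `out_dir`.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if missing).
#' @return The `evaluation_report`, invisibly; artifacts on disk.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  logfile <- file.path(out_dir, "log.txt")
  say <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    cat(msg, "\n", file = logfile, append = TRUE)
    message(msg)
  }
  set.seed(config$seed)
  say("stage simulate: %d training agents (seed %d)", config$n_train_agents,
      config$seed)
  cohort <- sample_cohort(config$study, config$n_train_agents)
  write_sessions(cohort, file.path(out_dir, "train_cohort.csv"))

  say("stage train: fitting the network")
  tc <- do.call(trnn_config, modifyList(list(study = config$study),
                                        config$trnn))
  fit <- trnn_train(cohort, tc)
  write_sessions(fit$history, file.path(out_dir, "train_history.csv"))
  say("stage train: stopped at epoch %d (val loss %.4f)", fit$best_epoch,
      fit$best_val)

  say("stage test-suite: 3 x %d agents", config$n_test_per_group)
  test <- make_test_suite(config$n_test_per_group)
  write_sessions(test, file.path(out_dir, "test_suite.csv"))

  say("stage infer: network predictions")
  pred_trnn <- predict(fit, test)
  write_sessions(pred_trnn, file.path(out_dir, "estimates_trnn.csv"))

  say("stage fit-baseline: stationary MLE (%d starts)", config$mle_starts)
  mle <- fit_mle(test, config$study, n_starts = config$mle_starts)
  pred_mle <- predict(mle, test)
  write_sessions(pred_mle, file.path(out_dir, "estimates_mle.csv"))

  say("stage fit-baseline: particle filter")
  pfc <- do.call(pf_config, modifyList(list(study = config$study), config$pf))
  pf <- particle_filter(test, pfc)
  pred_pf <- predict(pf)
  write_sessions(pred_pf, file.path(out_dir, "estimates_pf.csv"))

  say("stage evaluate")
  report <- evaluate_methods(
    list(trnn = pred_trnn, mle = pred_mle, pf = pred_pf,
         oracle = oracle_predict(test, config$study)),
    test)
  write_sessions(report$bce, file.path(out_dir, "report_bce.csv"))
  if (!is.null(report$mse) && nrow(report$mse) > 0) {
    write_sessions(report$mse, file.path(out_dir, "report_mse.csv"))
  }
  write_sessions(report$tests, file.path(out_dir, "report_tests.csv"))
  write_experiment_config(config, file.path(out_dir, "config.yaml"))
  meta <- list(package_version = as.character(utils::packageVersion("banditrnn")),
               seed = config$seed, trnn_seed = fit$seed,
               best_epoch = fit$best_epoch)
  yaml::write_yaml(meta, file.path(out_dir, "metadata.yaml"))
  say("done")
  invisible(report)
}
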