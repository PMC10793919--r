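# Metrics, statistical comparisons, and the behavioural analyses
# (stay probability, ungreedy-switch events, block-difficulty dynamics).
# Evaluation is method-agnostic: every estimator emits the same prediction
# shape (subject / block / trial / pred_left [/ <param>_hat]).

#' Per-subject action prediction error (binary cross-entropy)
#'
#' Mean over evaluated trials of `-ln P(observed action)`, natural log.
#' The first trial of each session is excluded for all methods (the network
#' cannot predict it), so estimators are compared on identical trial sets.
#' Probabilities are clamped to `[1e-12, 1 - 1e-12]`.
#'
#' @param pred Prediction tibble with `subject`, `block`, `trial`,
#'   `pred_left`.
#' @param data Sessions tibble with the observed actions.
#' @param drop_first_trial Exclude each session's first trial (default TRUE).
#' @return Tibble `subject`, `n`, `bce`.
#' @export
action_bce <- function(pred, data, drop_first_trial = TRUE) {
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(pred),
                  dplyr::all_of(c("subject", "block", "trial", "pred_left"))),
    sessions_only(data), by = c("subject", "block", "trial"))
  joined <- dplyr::group_by(joined, .data$subject)
  if (drop_first_trial) joined <- dplyr::filter(joined, dplyr::row_number() > 1)
  joined %>%
    dplyr::filter(!is.na(.data$pred_left)) %>%
    dplyr::mutate(p = ifelse(.data$action == "L", .data$pred_left,
                             1 - .data$pred_left),
                  p = pmin(pmax(.data$p, 1e-12), 1 - 1e-12)) %>%
    dplyr::summarise(n = dplyr::n(), bce = mean(-log(.data$p)), .groups = "drop")
}

#' Per-subject, per-parameter estimation error (mean squared error)
#'
#' Mean over trials of the squared deviation between a method's per-trial
#' estimate (`<param>_hat`) and the true trajectory, in native parameter
#' units. Stationary estimates are broadcast across trials by their
#' `predict()` methods, so the same function serves every estimator.
#'
#' @param est Estimate tibble with `<param>_hat` columns.
#' @param truth Simulated data carrying the true parameter columns.
#' @param params Parameters to score; default every `<param>_hat` present.
#' @return Tibble `subject`, `param`, `mse`.
#' @export
param_mse <- function(est, truth, params = NULL) {
  est <- tibble::as_tibble(est)
  if (is.null(params)) {
    params <- sub("_hat$", "", grep("_hat$", names(est), value = TRUE))
  }
  missing <- setdiff(params, names(truth))
  if (length(missing) > 0) {
    rlang::abort(paste0("truth lacks parameter column(s): ",
                        paste(missing, collapse = ", ")))
  }
  joined <- dplyr::inner_join(
    dplyr::select(est, dplyr::all_of(c("subject", "block", "trial",
                                       paste0(params, "_hat")))),
    dplyr::select(tibble::as_tibble(truth),
                  dplyr::all_of(c("subject", "block", "trial", params))),
    by = c("subject", "block", "trial"))
  purrr::map_dfr(params, function(p) {
    joined %>%
      dplyr::group_by(.data$subject) %>%
      dplyr::summarise(
        param = p,
        mse = mean((.data[[paste0(p, "_hat")]] - .data[[p]])^2),
        .groups = "drop")
  }) %>% dplyr::arrange(.data$subject, .data$param)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' (Wilcoxon's convention) and tied ranks averaged; the exact distribution is
#' used for n <= 25 pairs (without ties), the normal approximation above.
#'
#' @param x,y Paired numeric vectors.
#' @return Tibble with `statistic` (V, the positive-rank sum of `x - y`),
#'   `p_value` and `n` (non-zero pairs).
#' @export
#' @examples
#' wilcoxon_signed_rank(1:6, c(0, 1, 2, 3, 4, 4.5))
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) rlang::abort("all paired differences are zero")
  if (length(x) < 5) rlang::abort("need at least 5 pairs")
  exact <- n <= 25 && !any(duplicated(abs(d)))
  res <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = res$p.value, n = n)
}

#' Trailing moving average of the stay probability
#'
#' The stay indicator at trial t is 1 iff the action repeats the previous
#' trial's action (within a session; undefined at trial 1). The moving
#' average is trailing — it uses only the current and past `window - 1` stay
#' values — matching the online spirit of trial-by-trial estimation, and is
#' `NA` until the window is full.
#'
#' @param data Sessions tibble.
#' @param window Window length in trials (default 10).
#' @return Input columns plus `stay` and `stay_ma`.
#' @export
stay_probability_ma <- function(data, window = 10) {
  data <- tibble::as_tibble(data)
  data %>%
    dplyr::group_by(.data$subject) %>%
    dplyr::mutate(
      stay = as.numeric(.data$action == dplyr::lag(.data$action)),
      stay_ma = {
        s <- .data$stay
        k <- numeric(length(s))
        for (i in seq_along(s)) {
          w <- s[max(1, i - window + 1):i]
          k[i] <- if (i <= window || anyNA(w)) NA_real_ else mean(w)
        }
        k
      }
    ) %>%
    dplyr::ungroup()
}

#' Pearson correlation between two aligned series
#'
#' @param x,y Equal-length finite numeric series with non-zero variance.
#' @return The Pearson correlation coefficient.
#' @export
correlate_estimates <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("correlation undefined: a series has zero variance")
  }
  stats::cor(x, y)
}

#' Detect ungreedy switches away from the better arm
#'
#' Finds trials where the subject chose the better-rewarding arm for
#' `min_run` or more consecutive trials, was rewarded on the final run trial,
#' and then switched to the poorer arm. With `strict = TRUE` every trial of
#' the run must have been rewarded. The better arm per block comes from the
#' true arm parameters (`arm_left`/`arm_right` columns of simulated data) or
#' from a user-supplied `better` tibble (`subject`, `block`, `better`) for
#' empirical data.
#'
#' @param data Sessions tibble (with arm columns, or `better` supplied).
#' @param better Optional tibble mapping (subject, block) to the better arm.
#' @param min_run Minimum run length before the switch (default 3).
#' @param strict Require every run trial rewarded, not just the last.
#' @param rewarded Predicate deciding whether a reward counts as rewarded;
#'   default \code{r > 0} (which is \code{r == 1} for binary tasks).
#' @return Event tibble `subject`, `block`, `trial` (the switch trial) and
#'   `run_length`.
#' @export
detect_ungreedy_events <- function(data, better = NULL, min_run = 3,
                                   strict = FALSE,
                                   rewarded = function(r) r > 0) {
  data <- tibble::as_tibble(data)
  if (is.null(better)) {
    if (!all(c("arm_left", "arm_right") %in% names(data))) {
      rlang::abort("supply `better` or data with arm_left/arm_right columns")
    }
    data <- dplyr::mutate(data,
                          better = ifelse(.data$arm_left >= .data$arm_right,
                                          "L", "R"))
  } else {
    data <- dplyr::left_join(data, better, by = c("subject", "block"))
  }
  data %>%
    dplyr::group_by(.data$subject, .data$block) %>%
    dplyr::group_modify(function(df, key) {
      a <- df$action
      good <- a == df$better
      rew <- rewarded(df$reward)
      ev <- integer(0)
      run <- integer(0)
      streak <- 0
      all_rew <- TRUE
      for (t in seq_along(a)) {
        if (t > 1 && streak >= min_run && !good[t] && rew[t - 1] &&
            (!strict || all_rew)) {
          ev <- c(ev, t)
          run <- c(run, streak)
        }
        if (good[t]) {
          all_rew <- if (streak == 0) rew[t] else all_rew && rew[t]
          streak <- streak + 1
        } else {
          streak <- 0
          all_rew <- TRUE
        }
      }
      tibble::tibble(trial = df$trial[ev], run_length = run)
    }) %>%
    dplyr::ungroup()
}

#' Label Gaussian blocks as easy or hard
#'
#' A block is "easy" when the absolute difference of the true arm means is at
#' least `easy` (default 19), "hard" when it is at most `hard` (default 1),
#' otherwise "neither".
#'
#' @param task A gaussian-scheme `bandit_task` (or its block tibble with
#'   `mu_left`/`mu_right`).
#' @param easy,hard Thresholds on `|mu_L - mu_R|`.
#' @return The block tibble plus `value_diff` and `difficulty`.
#' @export
label_block_difficulty <- function(task, easy = 19, hard = 1) {
  if (!all(c("mu_left", "mu_right") %in% names(task))) {
    rlang::abort("difficulty labels need gaussian blocks (mu_left/mu_right)")
  }
  task %>%
    tibble::as_tibble() %>%
    dplyr::mutate(
      value_diff = abs(.data$mu_left - .data$mu_right),
      difficulty = dplyr::case_when(
        .data$value_diff >= easy ~ "easy",
        .data$value_diff <= hard ~ "hard",
        TRUE ~ "neither"))
}

#' Aligned mean and standard error of trial-level series
#'
#' Aggregates a per-trial variable either by trial-within-block position
#' (block-phase dynamics) or in windows aligned to supplied events; event
#' windows truncated by session edges are dropped so every offset averages
#' the same events.
#'
#' @param data Tibble holding the variable and `subject`, `block`, `trial`.
#' @param var Name of the variable to aggregate.
#' @param align `"trial"` or `"event"`.
#' @param events Event tibble from [detect_ungreedy_events()] (required for
#'   `align = "event"`).
#' @param window Integer vector of offsets around the event, e.g. `-3:3`.
#' @return Tibble with the aligned index (`trial` or `offset`), `mean`,
#'   `sem`, `n`.
#' @export
aggregate_dynamics <- function(data, var, align = c("trial", "event"),
                               events = NULL, window = -3:3) {
  align <- match.arg(align)
  data <- tibble::as_tibble(data)
  if (align == "trial") {
    out <- data %>%
      dplyr::group_by(.data$trial) %>%
      dplyr::summarise(
        mean = mean(.data[[var]], na.rm = TRUE),
        sem = stats::sd(.data[[var]], na.rm = TRUE) /
          sqrt(sum(!is.na(.data[[var]]))),
        n = sum(!is.na(.data[[var]])), .groups = "drop")
    if (nrow(out) == 0) rlang::warn("empty selection")
    return(out)
  }
  if (is.null(events) || nrow(events) == 0) {
    rlang::warn("no events supplied; empty output")
    return(tibble::tibble(offset = integer(0), mean = numeric(0),
                          sem = numeric(0), n = integer(0)))
  }
  rows <- purrr::pmap_dfr(
    dplyr::select(events, dplyr::all_of(c("subject", "block", "trial"))),
    function(subject, block, trial) {
      blk <- data[data$subject == subject & data$block == block, ]
      pos <- match(trial, blk$trial)
      idx <- pos + window
      if (any(idx < 1 | idx > nrow(blk))) return(NULL)  # incomplete window
      tibble::tibble(offset = window, value = blk[[var]][idx])
    })
  if (nrow(rows) == 0) {
    rlang::warn("no complete event windows")
    return(tibble::tibble(offset = integer(0), mean = numeric(0),
                          sem = numeric(0), n = integer(0)))
  }
  rows %>%
    dplyr::group_by(.data$offset) %>%
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sem = stats::sd(.data$value, na.rm = TRUE) /
                       sqrt(sum(!is.na(.data$value))),
                     n = sum(!is.na(.data$value)), .groups = "drop")
}

#' Compare estimators on action prediction and parameter recovery
#'
#' Computes per-subject action BCE for every supplied prediction table (and
#' per-parameter MSE where estimates and ground truth exist), then paired
#' Wilcoxon signed-rank tests of the reference method (the first element)
#' against each other method.
#'
#' @param predictions Named list of prediction tibbles (first = reference).
#' @param data Sessions tibble with observed actions (and true parameters
#'   for the MSE comparisons, if simulated).
#' @param params Parameters to score with MSE; `NULL` scores whatever
#'   `<param>_hat` columns each method provides (skipped if the truth lacks
#'   them).
#' @return An `evaluation_report` list with tibbles `bce` (subject, method,
#'   bce), `mse` (subject, method, param, mse) and `tests` (metric, param,
#'   method, statistic, p_value).
#' @export
evaluate_methods <- function(predictions, data, params = NULL) {
  stopifnot(length(predictions) >= 1, !is.null(names(predictions)))
  bce <- purrr::imap_dfr(predictions, function(p, nm) {
    dplyr::mutate(action_bce(p, data), method = nm)
  })
  mse <- purrr::imap_dfr(predictions, function(p, nm) {
    has <- grep("_hat$", names(p), value = TRUE)
    ps <- if (is.null(params)) sub("_hat$", "", has) else params
    ps <- intersect(ps, names(data))
    ps <- intersect(ps, sub("_hat$", "", has))
    if (length(ps) == 0) return(NULL)
    dplyr::mutate(param_mse(p, data, ps), method = nm)
  })
  ref <- names(predictions)[1]
  others <- setdiff(names(predictions), ref)
  tests <- purrr::map_dfr(others, function(m) {
    wide <- tidyr::pivot_wider(bce, id_cols = "subject",
                               names_from = "method", values_from = "bce")
    out <- dplyr::mutate(wilcoxon_signed_rank(wide[[ref]], wide[[m]]),
                         metric = "bce", param = NA_character_, method = m)
    if (!is.null(mse) && nrow(mse) > 0) {
      shared <- intersect(unique(mse$param[mse$method == ref]),
                          unique(mse$param[mse$method == m]))
      for (p in shared) {
        widep <- tidyr::pivot_wider(
          dplyr::filter(mse, .data$param == p), id_cols = "subject",
          names_from = "method", values_from = "mse")
        out <- dplyr::bind_rows(
          out, dplyr::mutate(wilcoxon_signed_rank(widep[[ref]], widep[[m]]),
                             metric = "mse", param = p, method = m))
      }
    }
    out
  })
  structure(list(bce = bce, mse = mse, tests = tests, reference = ref),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> mean action BCE by method:\n")
  print(dplyr::summarise(dplyr::group_by(x$bce, .data$method),
                         mean_bce = mean(.data$bce), .groups = "drop"))
  if (!is.null(x$tests) && nrow(x$tests) > 0) {
    cat(sprintf("paired Wilcoxon vs '%s':\n", x$reference))
    print(dplyr::select(x$tests, dplyr::all_of(
      c("metric", "param", "method", "statistic", "p_value"))))
  }
  invisible(x)
}
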