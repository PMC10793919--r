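# Tabular text I/O. One dialect everywhere: comma-separated, header required,
# UTF-8, "." decimal.

#' Read behavioural session tables
#'
#' Reads a CSV with header columns `subject`, `block`, `trial`, `action`,
#' `reward` (extra columns preserved), validates it, and returns the rows
#' grouped by subject and sorted by (block, trial). Parse failures name the
#' offending data row.
#'
#' @param path CSV file path.
#' @return A sessions tibble.
#' @export
read_sessions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("subject", "block", "trial", "action", "reward")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- which(!df$action %in% c("L", "R"))
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown action symbol '%s' at row %d",
                         df$action[bad[1]], bad[1]))
  }
  if (!is.numeric(df$reward)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$reward))))
    rlang::abort(sprintf("non-numeric reward at row %d", bad[1]))
  }
  dup <- duplicated(df[c("subject", "block", "trial")])
  if (any(dup)) {
    rlang::abort(sprintf("duplicate (subject, block, trial) at row %d",
                         which(dup)[1]))
  }
  df %>%
    tibble::as_tibble() %>%
    dplyr::mutate(block = as.integer(.data$block),
                  trial = as.integer(.data$trial),
                  reward = as.numeric(.data$reward)) %>%
    dplyr::arrange(match(.data$subject, unique(.data$subject)),
                   .data$block, .data$trial)
}

#' Write a sessions (or any per-trial) table
#'
#' @param data Tibble to write.
#' @param path Output CSV path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(data, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tibble::as_tibble(data), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}
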