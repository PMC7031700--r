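trial_required_cols <- c("trial", "block_id", "signed_contrast", "side",
                         "reward_if_correct_L", "reward_if_correct_R",
                         "choice")

#' Read a trial table from CSV
#'
#' One row per trial with the documented column names; unknown columns are
#' preserved.  A missing mandatory column raises a schema error naming it.
#'
#' @param path CSV path.
#' @return A trial tibble.
#' @export
read_trials <- function(path) {
  known <- list(
    trial = readr::col_integer(), block_id = readr::col_integer(),
    side = readr::col_character(), choice = readr::col_character(),
    laser_epoch = readr::col_character(),
    laser_side = readr::col_character(), correct = readr::col_logical(),
    laser_on = readr::col_logical(), session = readr::col_integer())
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  schema <- do.call(readr::cols,
                    c(known[intersect(names(known), hdr)],
                      .default = readr::col_guess()))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"), col_types = schema)
  assert_columns(out, trial_required_cols,
                 sprintf("trial table '%s'", path))
  out
}

#' Write a trial table to CSV
#'
#' Missing values are written as empty fields; the round trip
#' `read_trials(write_trials(x, p))` is lossless for the documented schema.
#'
#' @param trials Trial tibble.
#' @param path Output CSV path.
#' @return `trials`, invisibly.
#' @export
write_trials <- function(trials, path) {
  assert_columns(trials, trial_required_cols)
  readr::write_csv(trials, path, na = "")
  invisible(trials)
}
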