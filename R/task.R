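#' Generate a block schedule for the asymmetric-reward 2AFC task
#'
#' Divides a session of `n_trials` trials into consecutive reward blocks whose
#' lengths are drawn iid from a discrete uniform distribution.  When reward
#' asymmetry is enabled, the side carrying the large water drop alternates
#' between consecutive blocks; the small drop is normalised to 1 model unit
#' and the large drop is worth `1 + reward_x`.  The final block is truncated
#' at `n_trials`.
#'
#' Laser plans describe where optogenetic manipulation is scheduled:
#' `"stim_random"` tags a random fraction `laser_prob` of trials with
#' stimulus-time laser; `"stim_blocks"` cycles through the four combinations
#' of reward side and stimulus-time laser on/off; `"outcome_blocks"`
#' alternates, block by block, the response side whose rewarded choices are
#' paired with outcome-time laser.
#'
#' @param n_trials Number of trials the schedule must cover.
#' @param block_len_range Integer vector `c(min, max)` of block lengths in
#'   trials (default 50--350, uniform).
#' @param reward_asymmetry If `TRUE` (default) one side per block carries the
#'   large reward and consecutive blocks alternate sides.
#' @param reward_x Subjective value of the extra water drop; the large-side
#'   payoff is `1 + reward_x` model units.
#' @param laser_plan One of `"none"`, `"stim_random"`, `"stim_blocks"`,
#'   `"outcome_blocks"`.
#' @param laser_prob Trial fraction for `"stim_random"` (default 0.4).
#' @param first_large_side Side of the large reward in the first block
#'   (`"L"` or `"R"`); drawn at random when `NULL`.
#' @param seed Optional integer seed; all schedule randomness flows from it.
#'
#' @return A tibble with one row per block: `block_id`, `block_start`,
#'   `block_end`, `n_trials`, `large_side`, `reward_small`, `reward_large`,
#'   `laser`, `laser_side`.
#' @export
sim_block_schedule <- function(n_trials, block_len_range = c(50, 350),
                               reward_asymmetry = TRUE, reward_x = 1,
                               laser_plan = c("none", "stim_random",
                                              "stim_blocks", "outcome_blocks"),
                               laser_prob = 0.4, first_large_side = NULL,
                               seed = NULL) {
  laser_plan <- match.arg(laser_plan)
  if (length(n_trials) != 1 || is.na(n_trials) || n_trials < 1)
    abort("`n_trials` must be a positive integer.")
  lo <- block_len_range[1]; hi <- block_len_range[2]
  if (lo < 1 || hi < lo) abort("`block_len_range` must satisfy 1 <= min <= max.")

  with_seed(seed, {
    # draw more blocks than could ever be needed, then truncate
    n_max <- ceiling(n_trials / lo) + 1L
    lens <- sample.int(hi - lo + 1L, n_max, replace = TRUE) + lo - 1L
    ends <- cumsum(lens)
    n_blocks <- which(ends >= n_trials)[1]
    lens <- lens[seq_len(n_blocks)]
    starts <- c(1L, utils::head(cumsum(lens), -1L) + 1L)
    ends <- pmin(cumsum(lens), n_trials)

    first <- first_large_side %||% sample(c("L", "R"), 1)
    sides <- rep_len(if (first == "L") c("L", "R") else c("R", "L"), n_blocks)
    if (!reward_asymmetry) sides <- rep(NA_character_, n_blocks)

    laser <- rep(FALSE, n_blocks)
    laser_side <- rep(NA_character_, n_blocks)
    if (laser_plan == "stim_blocks") {
      # cycle the four block types: reward side x laser on/off
      laser <- rep_len(c(FALSE, TRUE, TRUE, FALSE), n_blocks)
    } else if (laser_plan == "outcome_blocks") {
      first_laser <- sample(c("L", "R"), 1)
      laser_side <- rep_len(if (first_laser == "L") c("L", "R") else c("R", "L"),
                            n_blocks)
      laser <- TRUE
    }

    out <- tibble::tibble(
      block_id = seq_len(n_blocks),
      block_start = starts,
      block_end = ends,
      n_trials = ends - starts + 1L,
      large_side = sides,
      reward_small = 1,
      reward_large = 1 + reward_x,
      laser = laser,
      laser_side = laser_side
    )
    attr(out, "laser_plan") <- laser_plan
    attr(out, "laser_prob") <- laser_prob
    out
  })
}

#' Generate the trial table for a block schedule
#'
#' Draws one stimulus per trial uniformly at random from the signed-contrast
#' set built from `contrast_set` (each nonzero contrast appears on both
#' sides; zero contrast is one level).  The "correct" side of zero-contrast
#' trials is pre-assigned uniformly at random so that adjudication is
#' deterministic given the record.  Event times are laid out on a common
#' session clock (`trial_start`, seconds) with within-trial offsets
#' `t_stim < t_action < t_outcome`.
#'
#' @param schedule A block schedule from [sim_block_schedule()].
#' @param contrast_set Nonnegative contrasts including 0; default
#'   `c(0, 0.125, 0.25, 0.5)` (7 signed levels).
#' @param iti Inter-trial interval in seconds appended after each outcome.
#' @param seed Optional integer seed.
#'
#' @return A tibble with one row per trial; `choice`, `correct` and
#'   `reward_delivered` are `NA` until filled by [run_agent()],
#'   [run_observer()] or [adjudicate()].
#' @export
sim_trials <- function(schedule, contrast_set = c(0, 0.125, 0.25, 0.5),
                       iti = 3, seed = NULL) {
  if (length(contrast_set) == 0) abort("`contrast_set` must be non-empty.")
  if (any(contrast_set < 0)) abort("`contrast_set` must be nonnegative.")
  signed_set <- sort(unique(c(-contrast_set, contrast_set)))
  n <- max(schedule$block_end)
  laser_plan <- attr(schedule, "laser_plan") %||% "none"
  laser_prob <- attr(schedule, "laser_prob") %||% 0.4

  with_seed(seed, {
    contrast <- sample(signed_set, n, replace = TRUE)
    side <- ifelse(contrast > 0, "R", ifelse(contrast < 0, "L", NA))
    n0 <- sum(is.na(side))
    side[is.na(side)] <- sample(c("L", "R"), n0, replace = TRUE)

    block_id <- rep.int(schedule$block_id, schedule$n_trials)
    large <- rep.int(schedule$large_side, schedule$n_trials)
    r_large <- rep.int(schedule$reward_large, schedule$n_trials)
    r_small <- rep.int(schedule$reward_small, schedule$n_trials)
    rL <- ifelse(!is.na(large) & large == "L", r_large, r_small)
    rR <- ifelse(!is.na(large) & large == "R", r_large, r_small)

    laser_on <- rep(FALSE, n)
    laser_epoch <- rep("none", n)
    laser_side <- rep(NA_character_, n)
    if (laser_plan == "stim_random") {
      laser_on <- runif(n) < laser_prob
      laser_epoch[laser_on] <- "stimulus"
    } else if (laser_plan == "stim_blocks") {
      laser_on <- rep.int(schedule$laser, schedule$n_trials)
      laser_epoch[laser_on] <- "stimulus"
    } else if (laser_plan == "outcome_blocks") {
      laser_side <- rep.int(schedule$laser_side, schedule$n_trials)
      laser_epoch <- ifelse(is.na(laser_side), "none", "outcome")
    }

    t_stim <- 0.5
    rt <- exp(rnorm(n, log(0.35), 0.45))          # right-skewed reaction times
    t_action <- t_stim + rt
    t_outcome <- t_action + 0.05
    trial_start <- c(0, cumsum(t_outcome + iti)[-n])

    tibble::tibble(
      trial = seq_len(n),
      block_id = block_id,
      signed_contrast = contrast,
      side = side,
      reward_if_correct_L = rL,
      reward_if_correct_R = rR,
      laser_on = laser_on,
      laser_epoch = laser_epoch,
      laser_side = laser_side,
      trial_start = trial_start,
      t_stim = t_stim,
      t_action = t_action,
      t_outcome = t_outcome,
      choice = NA_character_,
      correct = NA,
      reward_delivered = NA_real_
    )
  })
}

#' Adjudicate choices against the trial contingencies
#'
#' Correct choices (choice equal to the trial's stimulus side, which for
#' zero-contrast trials is the pre-assigned random side) earn the chosen
#' side's block reward; errors earn zero.
#'
#' @param trials A trial table.
#' @param choice Character vector of `"L"`/`"R"` choices, one per trial
#'   (defaults to the table's own `choice` column).
#' @return The trial table with `choice`, `correct` and `reward_delivered`
#'   filled in.
#' @export
adjudicate <- function(trials, choice = trials$choice) {
  assert_columns(trials, c("side", "reward_if_correct_L", "reward_if_correct_R"))
  if (length(choice) != nrow(trials))
    abort("`choice` must have one entry per trial.")
  correct <- choice == trials$side
  r_choice <- ifelse(choice == "R", trials$reward_if_correct_R,
                     trials$reward_if_correct_L)
  trials$choice <- choice
  trials$correct <- correct
  trials$reward_delivered <- ifelse(correct, r_choice, 0)
  trials
}
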