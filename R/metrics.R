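#' Psychometric proportions
#'
#' Proportion of rightward choices per signed contrast, optionally within
#' grouping conditions.
#'
#' @param trials Trial table with choices.
#' @param ... Optional grouping columns (tidy-selected), e.g. block side or
#'   laser condition.
#' @return A tibble with `n`, `n_right`, `p_right` and binomial `se` per
#'   signed contrast (and condition).
#' @export
psychometric <- function(trials, ...) {
  trials %>%
    dplyr::filter(!is.na(.data$choice)) %>%
    dplyr::group_by(..., .data$signed_contrast) %>%
    dplyr::summarise(n = dplyr::n(),
                     n_right = sum(.data$choice == "R"),
                     .groups = "drop") %>%
    dplyr::mutate(p_right = .data$n_right / .data$n,
                  se = binom_se(.data$p_right, .data$n))
}

# negative binomial log-likelihood of a lapse-sigmoid psychometric model
psy_negll <- function(par, x, n, k, link) {
  bias <- par[1]; slope <- par[2]; lapL <- par[3]; lapR <- par[4]
  f <- if (link == "probit") pnorm(slope * (x - bias)) else
    stats::plogis(slope * (x - bias))
  p <- lapL + (1 - lapL - lapR) * f
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

#' Maximum-likelihood psychometric fit
#'
#' Fits `P(R) = lapse_left + (1 - lapse_left - lapse_right) * F(slope * (x -
#' bias))` to binomial rightward counts, with `F` a cumulative Gaussian
#' (default) or logistic.  Degenerate data (all choices one side) and fits
#' with the slope at the optimiser bound are flagged rather than silently
#' returned.
#'
#' @param data Output of [psychometric()] (columns `signed_contrast`, `n`,
#'   `n_right`), for a single condition.
#' @param link `"probit"` (cumulative Gaussian) or `"logit"`.
#' @param slope_max Upper optimiser bound for the slope.
#' @return An object of class `psych_fit`; `tidy()` returns the parameter
#'   table, `glance()` the log-likelihood and flags.
#' @export
fit_psychometric <- function(data, link = c("probit", "logit"),
                             slope_max = 100) {
  link <- match.arg(link)
  assert_columns(data, c("signed_contrast", "n", "n_right"),
                 "psychometric data")
  if (length(unique(data$signed_contrast)) < 3)
    abort("need at least 3 contrast levels to fit a psychometric function.")
  x <- data$signed_contrast; n <- data$n; k <- data$n_right
  non_identifiable <- sum(k) == 0 || sum(k) == sum(n)

  start <- c(bias = 0, slope = 2 / max(diff(range(x)), 1e-6),
             lapse_left = 0.02, lapse_right = 0.02)
  lower <- c(min(x), 1e-3, 0, 0)
  upper <- c(max(x), slope_max, 0.5, 0.5)
  opt <- optim(start, psy_negll, x = x, n = n, k = k, link = link,
               method = "L-BFGS-B", lower = lower, upper = upper)
  est <- opt$par
  at_bound <- est[2] >= slope_max * (1 - 1e-6)
  structure(list(
    coef = tibble::tibble(
      term = c("bias", "slope", "lapse_left", "lapse_right"),
      estimate = unname(est)),
    logLik = -opt$value, link = link,
    non_identifiable = non_identifiable, slope_at_bound = at_bound,
    convergence = opt$convergence), class = "psych_fit")
}

#' @method print psych_fit
#' @export
print.psych_fit <- function(x, ...) {
  cat("<psych_fit>", x$link, "link; bias =",
      signif(x$coef$estimate[1], 3), " slope =", signif(x$coef$estimate[2], 3),
      " lapses =", signif(x$coef$estimate[3], 3), "/",
      signif(x$coef$estimate[4], 3), "\n")
  if (x$non_identifiable) cat("  flag: non-identifiable (one-sided choices)\n")
  if (x$slope_at_bound) cat("  flag: slope at optimiser bound\n")
  invisible(x)
}

#' @export
tidy.psych_fit <- function(x, ...) x$coef

#' @export
glance.psych_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, link = x$link,
                 non_identifiable = x$non_identifiable,
                 slope_at_bound = x$slope_at_bound)
}

# Lateral psychometric shift conditional on a neighbouring rewarded trial:
# mean over current-contrast levels of P(R | neighbour side R) minus
# P(R | neighbour side L), restricted to neighbour trials that were rewarded
# and in the given difficulty tier.  Returns the shift (in percent) and a
# delta-method SE.
conditional_shift <- function(data, nb_side, nb_ok) {
  keep <- !is.na(nb_ok) & nb_ok & !is.na(data$choice)
  df <- tibble::tibble(contrast = data$signed_contrast[keep],
                       right = data$choice[keep] == "R",
                       nb = nb_side[keep])
  tab <- df %>%
    dplyr::group_by(.data$contrast, .data$nb) %>%
    dplyr::summarise(p = mean(.data$right), n = dplyr::n(), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "nb", values_from = c("p", "n"))
  if (!all(c("p_L", "p_R") %in% names(tab))) {
    return(list(shift = NA_real_, se = NA_real_, n_levels = 0L))
  }
  incomplete <- !complete.cases(tab[, c("p_L", "p_R")])
  if (any(incomplete)) {
    warn(sprintf("dropping %d contrast level(s) missing one condition",
                 sum(incomplete)))
    tab <- tab[!incomplete, ]
  }
  d <- tab$p_R - tab$p_L
  v <- tab$p_R * (1 - tab$p_R) / tab$n_R + tab$p_L * (1 - tab$p_L) / tab$n_L
  list(shift = 100 * mean(d), se = 100 * sqrt(sum(v)) / nrow(tab),
       n_levels = nrow(tab))
}

#' Confidence-history shift with slow-bias correction
#'
#' Measures how the previous trial's sensory difficulty gates its influence
#' on the current choice.  Rightward-choice curves are computed conditional
#' on the preceding trial being rewarded with a difficult (low-contrast) or
#' easy (high-contrast) stimulus on the left or right; the L/R difference,
#' averaged over current contrast levels, is the shift
#' `\eqn{\Delta} Rightward (%)`.  The same quantity computed conditional on
#' the *following* trial is subtracted, which cancels slowly drifting side
#' bias (slower than one trial, hence shared by both neighbours) and leaves
#' the causal influence of the past trial.
#'
#' Trial pairs must be consecutive within a session and, when block
#' structure is present, must not straddle a block switch.
#'
#' @param trials Trial table with choices (and rewards).
#' @param difficult Absolute contrasts of the difficult tier; default: zero
#'   plus the lowest nonzero tier.
#' @param easy Absolute contrasts of the easy tier; default: the highest
#'   tier.
#' @return A tibble with one row per difficulty tier: `shift_prev`
#'   (conditioned on the preceding trial), `shift_next` (on the following
#'   trial), the corrected `shift = shift_prev - shift_next`, a delta-method
#'   `se`, and the number of contrast levels entering each average.  Shifts
#'   are in percentage points of rightward choice.
#' @export
confidence_history_shift <- function(trials, difficult = NULL, easy = NULL) {
  assert_columns(trials, c("signed_contrast", "choice", "reward_delivered"))
  ac <- sort(unique(abs(trials$signed_contrast)))
  nonzero <- ac[ac > 0]
  difficult <- difficult %||% c(0, nonzero[1])
  easy <- easy %||% max(nonzero)

  n <- nrow(trials)
  session <- col_or(trials, "session", rep(1L, n))
  block <- col_or(trials, "block_id", rep(1L, n))
  same_prev <- c(FALSE, session[-1] == session[-n] & block[-1] == block[-n])
  same_next <- c(same_prev[-1], FALSE)

  rewarded <- !is.na(trials$reward_delivered) & trials$reward_delivered > 0
  tier <- abs(trials$signed_contrast)
  # rewarded trials have choice == side, so the neighbour's stimulus side and
  # chosen side coincide
  nb_side <- trials$side

  lag1 <- function(x) c(NA, x[-n])
  lead1 <- function(x) c(x[-1], NA)

  res <- purrr::map(list(difficult = difficult, easy = easy), function(tierset) {
    prev_ok <- same_prev & lag1(rewarded) & lag1(tier) %in% tierset
    next_ok <- same_next & lead1(rewarded) & lead1(tier) %in% tierset
    fw <- conditional_shift(trials, lag1(nb_side), prev_ok)
    bw <- conditional_shift(trials, lead1(nb_side), next_ok)
    tibble::tibble(shift_prev = fw$shift, shift_next = bw$shift,
                   shift = fw$shift - bw$shift,
                   se = sqrt(fw$se^2 + bw$se^2),
                   n_levels = min(fw$n_levels, bw$n_levels))
  })
  dplyr::bind_rows(res, .id = "difficulty")
}

#' Choice learning curve around block switches
#'
#' Causal moving average of the rightward-choice indicator, aligned to block
#' switches and averaged across switches, split by the side that carries the
#' large reward after the switch.
#'
#' @param trials Trial table with choices and block structure.
#' @param window Width (trials) of the causal moving average.
#' @param before,after Trials shown before/after the switch.
#' @return A tibble with `rel_trial`, `new_large_side`, `p_right`,
#'   `n_switches`.
#' @export
learning_curve <- function(trials, window = 10, before = 20, after = 60) {
  assert_columns(trials, c("choice", "block_id", "reward_if_correct_L",
                           "reward_if_correct_R"))
  n <- nrow(trials)
  session <- col_or(trials, "session", rep(1L, n))
  right <- as.numeric(trials$choice == "R")
  # causal running mean within session
  smooth <- unlist(purrr::map(split(right, factor(session, unique(session))),
                              function(r) {
    cs <- cumsum(r)
    k <- seq_along(r)
    lo <- pmax(k - window + 1, 1)
    (cs - c(0, cs)[lo]) / (k - lo + 1)
  }), use.names = FALSE)

  large_side <- dplyr::case_when(
    trials$reward_if_correct_L > trials$reward_if_correct_R ~ "L",
    trials$reward_if_correct_R > trials$reward_if_correct_L ~ "R",
    TRUE ~ NA_character_)
  switch_at <- which(c(FALSE, diff(trials$block_id) != 0 &
                         session[-1] == session[-n]))
  rows <- purrr::map(switch_at, function(s) {
    idx <- (s - before):(s + after)
    ok <- idx >= 1 & idx <= n & session[pmin(pmax(idx, 1), n)] == session[s]
    tibble::tibble(rel_trial = idx[ok] - s, p = smooth[idx[ok]],
                   new_large_side = large_side[s])
  }) %>% dplyr::bind_rows()
  rows %>%
    dplyr::group_by(.data$new_large_side, .data$rel_trial) %>%
    dplyr::summarise(p_right = mean(.data$p), n_switches = dplyr::n(),
                     .groups = "drop")
}

#' Next-trial psychometric shift split by outcome-response size
#'
#' Splits rewarded trials by whether a per-trial neural outcome response is
#' above or below a percentile, then measures the shift of the *next*
#' trial's choices toward the rewarded side, separately per previous
#' stimulus tier (and block side when present), and averages.
#'
#' @param trials Trial table with choices.
#' @param response Numeric vector of per-trial outcome responses (aligned to
#'   `trials`).
#' @param percentile Split percentile (default 65).
#' @return A tibble with one row per group (`high`, `low`): `shift` (in
#'   percentage points), `n_pairs`.
#' @export
split_by_outcome_response <- function(trials, response, percentile = 65) {
  assert_columns(trials, c("signed_contrast", "choice", "side",
                           "reward_delivered"))
  n <- nrow(trials)
  if (length(response) != n) abort("`response` must align with `trials`.")
  session <- col_or(trials, "session", rep(1L, n))
  block <- col_or(trials, "block_id", rep(1L, n))
  same_prev <- c(FALSE, session[-1] == session[-n] & block[-1] == block[-n])
  lag1 <- function(x) c(NA, x[-n])
  # condition on the block's large-reward side (one level when rewards equal)
  rl <- col_or(trials, "reward_if_correct_L", rep(1, n))
  rr <- col_or(trials, "reward_if_correct_R", rep(1, n))
  large_side <- dplyr::case_when(rl > rr ~ "L", rr > rl ~ "R",
                                 TRUE ~ "equal")

  rewarded <- !is.na(trials$reward_delivered) & trials$reward_delivered > 0
  thr <- quantile(response[rewarded], percentile / 100, na.rm = TRUE,
                  names = FALSE)
  prev_ok <- same_prev & lag1(rewarded) & !is.na(lag1(response)) &
    !is.na(trials$choice)
  df <- tibble::tibble(
    right = trials$choice == "R",
    prev_side = lag1(trials$side),
    prev_tier = abs(lag1(trials$signed_contrast)),
    block = large_side,
    group = ifelse(lag1(response) > thr, "high", "low"))[prev_ok, ]

  df %>%
    dplyr::group_by(.data$group, .data$prev_tier, .data$block,
                    .data$prev_side) %>%
    dplyr::summarise(p = mean(.data$right), n = dplyr::n(),
                     .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "prev_side", values_from = c("p", "n")) %>%
    dplyr::filter(!is.na(.data$p_L) & !is.na(.data$p_R)) %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(shift = 100 * mean(.data$p_R - .data$p_L),
                     n_pairs = sum(.data$n_L + .data$n_R), .groups = "drop")
}

#' Z-score reaction times within sessions
#'
#' Each session's reaction times are standardised to mean 0 and SD 1 before
#' any cross-session averaging; z-scores are invariant to per-session affine
#' transforms of the raw times.
#'
#' @param rt Numeric reaction times.
#' @param session Session identifier per element.
#' @return Numeric vector of z-scored reaction times.
#' @export
zscore_rt <- function(rt, session = rep(1L, length(rt))) {
  if (length(session) != length(rt)) abort("`session` must align with `rt`.")
  out <- rep(NA_real_, length(rt))
  for (s in unique(session)) {
    i <- session == s
    v <- rt[i]
    fin <- is.finite(v)
    if (sum(fin) < 2) abort(sprintf("session '%s' has fewer than 2 finite reaction times.", s))
    if (sd(v[fin]) == 0) abort(sprintf("session '%s' has constant reaction times (zero SD).", s))
    out[i] <- (v - mean(v[fin])) / sd(v[fin])
  }
  out
}

#' Mean model latents by contrast and trial type
#'
#' Group means (with SE) of the predicted value QC and the prediction error
#' delta by absolute contrast, correctness, and whether the chosen side
#' carried the large reward -- the groupings of the model-latent summary
#' figures.
#'
#' @param trials Trial table with latent columns (`QC`, `delta`) filled by
#'   [run_agent()].
#' @return A tibble with `abs_contrast`, `correct`, `chosen_large`,
#'   `mean_qc`, `mean_delta`, `se_qc`, `se_delta`, `n`.
#' @export
latent_summaries <- function(trials) {
  assert_columns(trials, c("signed_contrast", "choice", "correct", "QC",
                           "delta", "reward_if_correct_L",
                           "reward_if_correct_R"))
  trials %>%
    dplyr::filter(!is.na(.data$choice)) %>%
    dplyr::mutate(
      abs_contrast = abs(.data$signed_contrast),
      r_choice = ifelse(.data$choice == "R", .data$reward_if_correct_R,
                        .data$reward_if_correct_L),
      r_other = ifelse(.data$choice == "R", .data$reward_if_correct_L,
                       .data$reward_if_correct_R),
      chosen_large = dplyr::case_when(
        .data$r_choice > .data$r_other ~ TRUE,
        .data$r_choice < .data$r_other ~ FALSE,
        TRUE ~ NA)) %>%
    dplyr::group_by(.data$abs_contrast, .data$correct, .data$chosen_large) %>%
    dplyr::summarise(mean_qc = mean(.data$QC), mean_delta = mean(.data$delta),
                     se_qc = sd(.data$QC) / sqrt(dplyr::n()),
                     se_delta = sd(.data$delta) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}
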