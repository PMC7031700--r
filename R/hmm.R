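#' Per-trial block-switch probability from a schedule
#'
#' The two-state transition matrix of the block HMM has off-diagonal entries
#' equal to the empirical switch rate, the number of block switches divided
#' by the number of trials.
#'
#' @param n_switches Number of block switches observed.
#' @param n_trials Number of trials.
#' @return `p_switch` in `[0, 1]`.
#' @export
switch_rate <- function(n_switches, n_trials) {
  if (n_trials <= 0) abort("`n_trials` must be positive.")
  if (n_switches > n_trials) abort("more switches than trials.")
  n_switches / n_trials
}

#' Action-conditional outcome emission probabilities
#'
#' In the left block the left action carries the large drop; a noisy
#' observer confuses the two reward sizes with probability `beta`, so e.g.
#' `p(r = large | a = R, s = L) = beta`.  No-reward outcomes are
#' state-uninformative (their probability reflects the sensory error, not
#' the block) and carry probability `p_unrewarded` in both states; the
#' default 0 returns the distribution conditional on reward delivery.
#'
#' @param state Block state, `"L"` or `"R"`.
#' @param action Taken action, `"L"` or `"R"`.
#' @param beta Size-confusion probability in `[0, 0.5]`.
#' @param p_unrewarded State-independent probability of the no-reward
#'   symbol.
#' @return A named numeric vector over `c(no_reward, small, large)`.
#' @export
emission_probs <- function(state, action, beta, p_unrewarded = 0) {
  if (beta < 0 || beta > 0.5) abort("`beta` must lie in [0, 0.5].")
  a_large <- state == action        # the action holding the large drop
  p_large <- if (a_large) 1 - beta else beta
  rew <- 1 - p_unrewarded
  c(no_reward = p_unrewarded, small = rew * (1 - p_large),
    large = rew * p_large)
}

#' One forward-filtering step of the block posterior
#'
#' Standard forward recursion: the posterior is first mixed through the
#' symmetric transition matrix (`p_switch` off-diagonal), then multiplied by
#' the action-conditional emission likelihood of the observed outcome and
#' renormalised.  At `beta = 0` an outcome that is impossible under one
#' state collapses the posterior onto the other; if no state is consistent
#' an error is raised.
#'
#' @param posterior Numeric `c(pL, pR)` summing to 1.
#' @param action Taken action, `"L"` or `"R"`.
#' @param outcome One of `"no_reward"`, `"small"`, `"large"`.
#' @param p_switch Per-trial block-switch probability.
#' @param beta Size-confusion probability.
#' @return Updated posterior `c(pL, pR)`.
#' @export
hmm_forward_update <- function(posterior, action, outcome, p_switch, beta) {
  stopifnot(length(posterior) == 2)
  pL <- posterior[1] * (1 - p_switch) + posterior[2] * p_switch
  pR <- 1 - pL
  lik <- c(emission_probs("L", action, beta)[outcome],
           emission_probs("R", action, beta)[outcome])
  if (outcome == "no_reward") lik <- c(1, 1)   # uninformative symbol
  num <- c(pL, pR) * lik
  if (sum(num) <= 0)
    abort("degenerate observation: outcome impossible under both block states")
  unname(num / sum(num))
}

#' Expected values and choice of the block-inference observer
#'
#' `QL = pL (p(S=L) r(L,L) + p(S=R) r(L,R))` and symmetrically for `QR`:
#' the sensory belief multiplies the posterior-weighted reward available for
#' each action.  The argmax action is chosen, with exact ties broken at
#' random.
#'
#' @param pL,pR Sensory beliefs.
#' @param posterior Block posterior `c(p(S=L), p(S=R))`.
#' @param reward_matrix 2x2 matrix `r[action, state]` with rows/cols ordered
#'   L, R.
#' @return A list with `choice`, `QL`, `QR`.
#' @export
observer_choice <- function(pL, pR, posterior, reward_matrix) {
  QL <- pL * sum(posterior * reward_matrix[1, ])
  QR <- pR * sum(posterior * reward_matrix[2, ])
  choice <- if (QR > QL) "R" else if (QL > QR) "L" else
    if (runif(1) < 0.5) "R" else "L"
  list(choice = choice, QL = QL, QR = QR)
}

#' Simulate the HMM ideal observer over a trial table
#'
#' The observer infers the current reward block by forward-filtering the
#' outcome sequence of its own choices, and combines the block posterior
#' with the trial's sensory belief to value the two actions.  The posterior
#' starts at `(0.5, 0.5)` and resets at session boundaries.
#'
#' @param trials Trial table (choices are generated, not read).
#' @param beta Size-confusion probability in `[0, 0.5]`.
#' @param sigma2 Sensory noise variance used for the percept and belief.
#' @param p_switch Per-trial switch probability; computed from the table's
#'   block structure via [switch_rate()] when `NULL`.
#' @param seed Optional integer seed.
#' @return The trial table with `choice`, `correct`, `reward_delivered`,
#'   sensory latents and the decision-time block posterior (`post_L`,
#'   `post_R`) appended.
#' @export
run_observer <- function(trials, beta, sigma2, p_switch = NULL, seed = NULL) {
  assert_columns(trials, c("signed_contrast", "side", "reward_if_correct_L",
                           "reward_if_correct_R"))
  n <- nrow(trials)
  sess_raw <- col_or(trials, "session", rep(1L, n))
  session <- as.integer(factor(sess_raw, levels = unique(sess_raw)))
  if (is.null(p_switch)) {
    blk <- col_or(trials, "block_id", rep(1L, n))
    n_switch <- sum(diff(blk) != 0 & diff(session) == 0)
    p_switch <- switch_rate(n_switch, n)
  }
  r_small <- min(c(trials$reward_if_correct_L, trials$reward_if_correct_R))
  r_large <- max(c(trials$reward_if_correct_L, trials$reward_if_correct_R))

  res <- with_seed(seed, cpp_run_observer(
    trials$signed_contrast, side_to_int(trials$side),
    trials$reward_if_correct_L, trials$reward_if_correct_R, session,
    sigma2, p_switch, beta, r_small, r_large))

  trials$choice <- int_to_side(res$choice)
  trials$correct <- res$correct
  trials$reward_delivered <- res$reward
  trials$s_hat <- res$s_hat
  trials$pL <- res$p_l
  trials$pR <- res$p_r
  trials$QL <- res$q_l
  trials$QR <- res$q_r
  trials$pC <- res$p_c
  trials$post_L <- res$post_l
  trials$post_R <- res$post_r
  attr(trials, "p_switch") <- p_switch
  trials
}

#' Fit the observer's emission noise by exhaustive search
#'
#' For each candidate `beta` the observer is simulated `n_iter` times over
#' the fixed stimulus sequence; per-trial choice probabilities are the
#' across-iteration frequencies and the negative log-likelihood of the
#' recorded choices is their floored mean `-log` (see [choice_nll()]).
#'
#' @param trials Trial table with recorded choices.
#' @param betas Candidate `beta` grid.
#' @param sigma2 Sensory noise variance of the observer.
#' @param p_switch Per-trial switch probability (`NULL`: from the table).
#' @param n_iter Simulation iterations per candidate.
#' @param seed Integer seed; common random numbers are used across
#'   candidates.
#' @return An object of class `beta_fit` with the NLL curve and the
#'   minimising `beta`.
#' @export
fit_beta <- function(trials, betas = seq(0, 0.5, by = 0.05), sigma2,
                     p_switch = NULL, n_iter = 200, seed = 1) {
  if (length(betas) == 0) abort("`betas` must be non-empty.")
  assert_columns(trials, "choice")
  floor_p <- 1 / (n_iter + 1)
  nll <- purrr::map_dbl(betas, function(b) {
    probs <- observer_choice_probs(trials, beta = b, sigma2 = sigma2,
                                   p_switch = p_switch, n_iter = n_iter,
                                   seed = seed)
    choice_nll(trials$choice, probs$p_right, floor = floor_p)
  })
  structure(list(curve = tibble::tibble(beta = betas, nll = nll),
                 best_beta = betas[which.min(nll)],
                 n_iter = n_iter),
            class = "beta_fit")
}

#' Observer choice probabilities by Monte-Carlo simulation
#'
#' @inheritParams fit_beta
#' @param beta Size-confusion probability.
#' @return A tibble with per-trial `p_left`, `p_right`.
#' @export
observer_choice_probs <- function(trials, beta, sigma2, p_switch = NULL,
                                  n_iter = 200, seed = NULL) {
  n <- nrow(trials)
  sess_raw <- col_or(trials, "session", rep(1L, n))
  session <- as.integer(factor(sess_raw, levels = unique(sess_raw)))
  if (is.null(p_switch)) {
    blk <- col_or(trials, "block_id", rep(1L, n))
    n_switch <- sum(diff(blk) != 0 & diff(session) == 0)
    p_switch <- switch_rate(n_switch, n)
  }
  r_small <- min(c(trials$reward_if_correct_L, trials$reward_if_correct_R))
  r_large <- max(c(trials$reward_if_correct_L, trials$reward_if_correct_R))
  p_r <- with_seed(seed, cpp_observer_probs(
    trials$signed_contrast, side_to_int(trials$side),
    trials$reward_if_correct_L, trials$reward_if_correct_R, session,
    sigma2, p_switch, beta, r_small, r_large, n_iter))
  tibble::tibble(p_left = 1 - p_r, p_right = p_r)
}

#' @method print beta_fit
#' @export
print.beta_fit <- function(x, ...) {
  cat("<beta_fit>  best beta =", x$best_beta, " (grid of",
      nrow(x$curve), "values, n_iter =", x$n_iter, ")\n")
  invisible(x)
}

#' @export
tidy.beta_fit <- function(x, ...) x$curve

#' @export
glance.beta_fit <- function(x, ...) {
  tibble::tibble(best_beta = x$best_beta, min_nll = min(x$curve$nll),
                 n_grid = nrow(x$curve), n_iter = x$n_iter)
}
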