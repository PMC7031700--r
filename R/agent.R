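#' Parameters of the belief-state reinforcement-learning agent
#'
#' @param alpha Learning rate in `[0, 1)`.
#' @param sigma2 Sensory noise variance in squared contrast units; `0` means
#'   a noiseless percept and `Inf` an uninformative one (belief pinned at
#'   0.5).
#' @param x Subjective value of the extra water drop: the small drop is worth
#'   1 and the large drop `1 + x`.
#' @param q_offset Constant added to the predicted value of the choice QC
#'   inside the prediction-error computation on stimulus-time laser trials
#'   (models mPFC suppression; typically negative).  It never affects the
#'   ongoing choice, because QC is determined only after the choice.
#' @param d_offset Constant added to the prediction error on laser-paired
#'   outcomes (models dopamine activation/suppression by its sign).
#' @param v_init Initial stored value of both actions at session start; the
#'   default 1 equals the normalised small reward.
#'
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(alpha = 0.25, sigma2 = 0.2, x = 3, q_offset = 0,
                         d_offset = 0, v_init = 1) {
  if (is.na(alpha) || alpha < 0 || alpha >= 1)
    abort("`alpha` must lie in [0, 1).")
  if (is.na(sigma2) || sigma2 < 0)
    abort("`sigma2` must be nonnegative (possibly Inf).")
  structure(list(alpha = alpha, sigma2 = sigma2, x = x, q_offset = q_offset,
                 d_offset = d_offset, v_init = v_init),
            class = "agent_params")
}

#' @method print agent_params
#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params>  alpha =", x$alpha, " sigma2 =", x$sigma2, " x =", x$x,
      "\n  q_offset =", x$q_offset, " d_offset =", x$d_offset,
      " v_init =", x$v_init, "\n")
  invisible(x)
}

#' Reduced model variants
#'
#' Pins one model component: `sigma2_zero` removes sensory noise
#' (`sigma2 = 0`), `sigma2_inf` makes the percept uninformative
#' (`sigma2 = Inf`), `no_x` equalises the two drop values (`x = 0`), and
#' `no_alpha` freezes learning (`alpha = 0`).  `"full"` returns the
#' parameters unchanged.
#'
#' @param params An [agent_params()] object.
#' @param variant One of `"full"`, `"sigma2_zero"`, `"sigma2_inf"`, `"no_x"`,
#'   `"no_alpha"`.
#' @return An [agent_params()] object with the named component pinned.
#' @export
reduced_variant <- function(params, variant) {
  if (!variant %in% c("full", "sigma2_zero", "sigma2_inf", "no_x", "no_alpha"))
    abort(sprintf("unknown model variant '%s'", variant))
  switch(variant,
         full = params,
         sigma2_zero = { params$sigma2 <- 0; params },
         sigma2_inf = { params$sigma2 <- Inf; params },
         no_x = { params$x <- 0; params },
         no_alpha = { params$alpha <- 0; params })
}

#' Draw a noisy internal percept of the stimulus
#'
#' The internal estimate is normally distributed with constant variance
#' around the true signed contrast; `sigma2 = 0` returns the contrast
#' exactly.
#'
#' @param signed_contrast Signed contrast(s) in `[-1, 1]`.
#' @param sigma2 Sensory noise variance (scalar).
#' @return Numeric vector of percepts.
#' @export
sample_percept <- function(signed_contrast, sigma2) {
  if (is.na(sigma2) || sigma2 < 0) abort("`sigma2` must be nonnegative.")
  if (sigma2 == 0 || is.infinite(sigma2)) return(signed_contrast)
  signed_contrast + sqrt(sigma2) * rnorm(length(signed_contrast))
}

#' Posterior belief that the stimulus is on the right
#'
#' With a flat prior the posterior over the true contrast is Gaussian around
#' the percept with the sensory variance, so the probability that the
#' stimulus sits right of zero is `pnorm(s_hat / sqrt(sigma2))`.  Edge
#' cases: `sigma2 = 0` collapses to the sign of the percept (0.5 at zero);
#' `sigma2 = Inf` returns 0.5.
#'
#' @param s_hat Percept(s).
#' @param sigma2 Sensory noise variance (scalar).
#' @return `pR` in `[0, 1]`; the left belief is `1 - pR`.
#' @export
belief_right <- function(s_hat, sigma2) {
  if (is.infinite(sigma2)) return(rep(0.5, length(s_hat)))
  if (sigma2 == 0) return(0.5 * (sign(s_hat) + 1))
  pnorm(s_hat / sqrt(sigma2))
}

#' Choose between left and right given beliefs and stored values
#'
#' Expected values are `QL = pL * VL` and `QR = pR * VR`; the action with
#' the higher expected value is selected deterministically, with exact ties
#' broken by a fair coin.  The chosen side's belief is the decision
#' confidence `pC` and its expected value the predicted value `QC`.
#'
#' @param pL,pR Beliefs (must sum to 1).
#' @param VL,VR Stored action values.
#' @return A tibble with columns `choice`, `pC`, `QC`, `QL`, `QR`.
#' @export
choose_action <- function(pL, pR, VL, VR) {
  QL <- pL * VL
  QR <- pR * VR
  n <- length(QL)
  choice <- ifelse(QR > QL, "R", "L")
  tie <- QR == QL
  if (any(tie)) choice[tie] <- ifelse(runif(sum(tie)) < 0.5, "R", "L")
  tibble::tibble(choice = choice,
                 pC = ifelse(choice == "R", pR, pL),
                 QC = ifelse(choice == "R", QR, QL),
                 QL = QL, QR = QR)
}

#' Confidence-scaled reward prediction error
#'
#' `delta = r - (QC + q_offset) + d_offset`.  Pass nonzero offsets only on
#' the manipulation trials they apply to: `q_offset` on stimulus-time laser
#' trials (it lowers the effective predicted value, so a reward is
#' over-credited), `d_offset` on laser-paired outcomes.
#'
#' @param reward Delivered reward in model units (0 on errors).
#' @param QC Predicted value of the choice.
#' @param q_offset,d_offset Manipulation constants (default 0).
#' @return The prediction error `delta`.
#' @export
prediction_error <- function(reward, QC, q_offset = 0, d_offset = 0) {
  reward - (QC + q_offset) + d_offset
}

#' Update the stored value of the chosen action
#'
#' `V_choice <- V_choice + alpha * delta`; the unchosen value is untouched.
#'
#' @param VL,VR Stored values.
#' @param choice `"L"` or `"R"`.
#' @param alpha Learning rate in `[0, 1)`.
#' @param delta Prediction error.
#' @return Named numeric vector `c(VL, VR)` after the update.
#' @export
update_values <- function(VL, VR, choice, alpha, delta) {
  if (alpha < 0 || alpha >= 1) abort("`alpha` must lie in [0, 1).")
  if (choice == "R") VR <- VR + alpha * delta else VL <- VL + alpha * delta
  c(VL = VL, VR = VR)
}

#' Simulate the belief-RL agent over a trial table
#'
#' Runs the full sequential loop: percept, belief, expected values, argmax
#' choice, outcome adjudication, confidence-scaled prediction error and
#' value update, with values carried across trials within a session and
#' reset to `v_init` at session boundaries (a `session` column, if present,
#' marks boundaries; otherwise the table is one session).  Optogenetic
#' offsets are applied according to the table's laser columns: `q_offset`
#' enters the prediction error on `laser_epoch == "stimulus"` trials and
#' `d_offset` on rewarded choices paired with outcome-time laser (matching
#' `laser_side`, or any rewarded choice on `laser_on` outcome trials).
#'
#' The delivered reward is recorded in the table's units, while the value
#' update uses the agent's subjective payoff: 1 for the small drop,
#' `1 + x` for the large, 0 for errors.
#'
#' @param trials Trial table from [sim_trials()] (or [read_trials()]).
#' @param params An [agent_params()] object.
#' @param seed Optional integer seed; the run is deterministic given it.
#' @param softmax If `TRUE` use a softmax decision rule with temperature
#'   `temp` instead of argmax (argmax is the default and the tested
#'   configuration).
#' @param temp Softmax temperature.
#' @return The trial table with `choice`, `correct`, `reward_delivered`
#'   filled and latent columns appended: `s_hat`, `pL`, `pR`, `QL`, `QR`,
#'   `pC`, `QC`, `v_tone`, `delta`, `VL`, `VR` (stored values before the
#'   update), `laser_fired`.
#' @export
run_agent <- function(trials, params, seed = NULL, softmax = FALSE,
                      temp = 0.1) {
  assert_columns(trials, c("signed_contrast", "side", "reward_if_correct_L",
                           "reward_if_correct_R"))
  stopifnot(inherits(params, "agent_params"))
  n <- nrow(trials)
  sess_raw <- col_or(trials, "session", rep(1L, n))
  session <- as.integer(factor(sess_raw, levels = unique(sess_raw)))
  epoch <- col_or(trials, "laser_epoch", rep("none", n))
  laser_stim <- epoch == "stimulus" & col_or(trials, "laser_on", rep(TRUE, n))
  laser_side <- col_or(trials, "laser_side", rep(NA_character_, n))
  out_side <- ifelse(is.na(laser_side), -1L, side_to_int(laser_side))
  out_trial <- epoch == "outcome" & is.na(laser_side) &
    col_or(trials, "laser_on", rep(FALSE, n))

  res <- with_seed(seed, cpp_run_agent(
    trials$signed_contrast, side_to_int(trials$side),
    trials$reward_if_correct_L, trials$reward_if_correct_R, session,
    laser_stim, as.integer(out_side), out_trial,
    params$alpha, params$sigma2, params$x, params$q_offset, params$d_offset,
    params$v_init, softmax, temp))

  trials$choice <- int_to_side(res$choice)
  trials$correct <- res$correct
  trials$reward_delivered <- res$reward
  trials$s_hat <- res$s_hat
  trials$pL <- res$p_l
  trials$pR <- res$p_r
  trials$QL <- res$q_l
  trials$QR <- res$q_r
  trials$pC <- res$p_c
  trials$QC <- res$q_c
  trials$v_tone <- res$v_tone
  trials$delta <- res$delta
  trials$VL <- res$v_l
  trials$VR <- res$v_r
  trials$laser_fired <- res$laser_fired
  trials
}
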