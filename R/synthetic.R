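#' Unit-norm ground-truth kernel shapes
#'
#' Smooth stereotyped event responses used by the synthetic generators: a
#' gamma-shaped bump for stimulus and outcome (the photometry versions decay
#' over roughly a second, standing in for a slow calcium indicator) and a
#' biphasic movement-locked shape for the action.  Each kernel is normalised
#' to unit Euclidean norm so that gain rules carry all amplitude.
#'
#' @param modality `"spikes"` or `"photometry"`.
#' @param bin_width Bin width in seconds (defaults: 0.020 spikes, 0.050
#'   photometry).
#' @param supports Kernel supports (default by modality).
#' @return Named list of kernel vectors.
#' @export
default_kernels <- function(modality = c("spikes", "photometry"),
                            bin_width = NULL, supports = NULL) {
  modality <- match.arg(modality)
  bin_width <- bin_width %||% if (modality == "spikes") 0.02 else 0.05
  supports <- supports %||% default_supports(modality)
  times <- purrr::map(supports, function(s)
    seq.int(round(s[1] / bin_width), round(s[2] / bin_width)) * bin_width)
  scale_s <- if (modality == "spikes") 0.06 else 0.35
  unit <- function(k) if (sum(k^2) > 0) k / sqrt(sum(k^2)) else k
  list(
    stim = unit(stats::dgamma(pmax(times$stim, 0), shape = 2,
                              scale = scale_s)),
    action = unit(exp(-(times$action + 0.05)^2 / (2 * (scale_s * 1.2)^2)) -
                    0.4 * exp(-(times$action + 3 * scale_s)^2 /
                                (2 * scale_s^2))),
    outcome = unit(stats::dgamma(pmax(times$outcome, 0), shape = 2,
                                 scale = scale_s * 1.6))
  )
}

#' Generate a multi-session behavioral dataset from a known agent
#'
#' Builds block schedules and trial tables for `n_sessions` sessions and
#' fills choices and latents by running the belief-RL agent, so that every
#' downstream analysis can be checked against known ground truth.  The
#' generating parameters, plan and seed are stored in the `"ground_truth"`
#' attribute; regenerating with the same seed reproduces the dataset
#' exactly.
#'
#' @param params Generating [agent_params()]; the defaults sit on the
#'   fitting grid so exact grid recovery is well defined.
#' @param n_sessions,trials_per_session Dataset size.
#' @param contrast_set Nonnegative contrast levels including zero.
#' @param block_len_range Uniform block-length range in trials.
#' @param reward_asymmetry Alternate a large-reward side across blocks?
#' @param laser_plan Optogenetic plan passed to [sim_block_schedule()].
#' @param iti Inter-trial interval in seconds.
#' @param seed Integer seed governing all randomness.
#' @return Trial tibble across sessions (with a `session` column and latent
#'   columns), carrying the `"ground_truth"` attribute.
#' @export
sim_behavior_dataset <- function(params = agent_params(),
                                 n_sessions = 10, trials_per_session = 500,
                                 contrast_set = c(0, 0.125, 0.25, 0.5),
                                 block_len_range = c(50, 350),
                                 reward_asymmetry = TRUE,
                                 laser_plan = "none", iti = 3, seed = 1) {
  sessions <- with_seed(seed, purrr::map(seq_len(n_sessions), function(s) {
    sched <- sim_block_schedule(trials_per_session,
                                block_len_range = block_len_range,
                                reward_asymmetry = reward_asymmetry,
                                reward_x = params$x, laser_plan = laser_plan)
    tr <- sim_trials(sched, contrast_set = contrast_set, iti = iti)
    tr$session <- s
    run_agent(tr, params)
  }))
  out <- dplyr::bind_rows(sessions)
  attr(out, "ground_truth") <- list(params = params, seed = seed,
                                    laser_plan = laser_plan,
                                    contrast_set = contrast_set,
                                    reward_asymmetry = reward_asymmetry)
  out
}

# absolute event-time table for a session's trials
event_table <- function(trials) {
  tibble::tibble(trial = seq_len(nrow(trials)),
                 t_stim = trials$trial_start + trials$t_stim,
                 t_action = trials$trial_start + trials$t_action,
                 t_outcome = trials$trial_start + trials$t_outcome)
}

synth_intensity <- function(trials, kernels, gains, bin_width, supports,
                            modality) {
  events <- event_table(trials)
  n_bins <- ceiling((max(events$t_outcome) + max(supports$outcome) + 1) /
                      bin_width)
  session <- neural_session(numeric(n_bins), bin_width, events, modality)
  design <- build_design(session, supports = supports)
  list(session = session, design = design,
       signal = predict_trace(design, kernels, gains))
}

#' Synthetic Poisson spike session tied to model latents
#'
#' Spike counts in 20 ms bins follow an inhomogeneous Poisson process whose
#' intensity is a constant base rate plus the kernel model's prediction
#' (gains times kernels at the trial's events), floored at zero; the stored
#' trace is z-scored.  Gains default to an action response scaling linearly
#' with the trial's predicted value QC.
#'
#' @param trials One session's trial table with latents from [run_agent()].
#' @param kernels Named list of true kernels (default
#'   [default_kernels()]`("spikes")`).
#' @param stim_gain,action_gain,outcome_gain Per-trial gain vectors; the
#'   defaults are `4`, `3 + 5 * QC` and `3` (trace-signal units per
#'   unit-norm kernel).
#' @param base_rate Baseline firing rate in Hz.
#' @param bin_width Bin width in seconds.
#' @param seed Optional integer seed.
#' @return A list with the z-scored `session` ([neural_session()]) and a
#'   `truth` list (kernels, gain matrix, base rate, seed).
#' @export
sim_spike_session <- function(trials, kernels = NULL, stim_gain = NULL,
                              action_gain = NULL, outcome_gain = NULL,
                              base_rate = 20, bin_width = 0.02, seed = NULL) {
  supports <- default_supports("spikes")
  kernels <- kernels %||% default_kernels("spikes", bin_width)
  J <- nrow(trials)
  gains <- cbind(stim = stim_gain %||% rep(4, J),
                 action = action_gain %||% (3 + 5 * trials$QC),
                 outcome = outcome_gain %||% rep(3, J))
  parts <- synth_intensity(trials, kernels, gains, bin_width, supports,
                           "spikes")
  intensity <- pmax(base_rate * bin_width + parts$signal, 0)
  counts <- with_seed(seed, rpois(length(intensity), intensity))
  session <- parts$session
  session$trace <- as.numeric(scale(counts))
  list(session = session,
       truth = list(kernels = kernels, gains = gains, base_rate = base_rate,
                    counts = counts, seed = seed))
}

#' Synthetic photometry session tied to model latents
#'
#' A 50 ms-binned trace equal to the kernel model's prediction plus white
#' Gaussian noise, z-scored.  Defaults emulate a dopamine-like signal:
#' stimulus transients scaling with the predicted value QC and outcome
#' transients scaling with the prediction error delta.
#'
#' @inheritParams sim_spike_session
#' @param stim_gain,action_gain,outcome_gain Per-trial gains; defaults
#'   `1 + 2 * QC`, `0.5` and `1 + 1.5 * delta`.
#' @param noise_sd Gaussian noise SD in trace units.
#' @return A list with the z-scored `session` and a `truth` list.
#' @export
sim_photometry_session <- function(trials, kernels = NULL, stim_gain = NULL,
                                   action_gain = NULL, outcome_gain = NULL,
                                   noise_sd = 0.5, bin_width = 0.05,
                                   seed = NULL) {
  supports <- default_supports("photometry")
  kernels <- kernels %||% default_kernels("photometry", bin_width)
  J <- nrow(trials)
  gains <- cbind(stim = stim_gain %||% (1 + 2 * trials$QC),
                 action = action_gain %||% rep(0.5, J),
                 outcome = outcome_gain %||% (1 + 1.5 * trials$delta))
  parts <- synth_intensity(trials, kernels, gains, bin_width, supports,
                           "photometry")
  raw <- parts$signal +
    with_seed(seed, rnorm(length(parts$signal), 0, noise_sd))
  session <- parts$session
  session$trace <- if (sd(raw) > 0) as.numeric(scale(raw)) else raw
  list(session = session,
       truth = list(kernels = kernels, gains = gains, noise_sd = noise_sd,
                    raw = raw, seed = seed))
}
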