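# a minimal session: events on a regular grid, configurable trace
toy_session <- function(n_trials = 20, bin_width = 0.02, spacing = 4,
                        trace = NULL, modality = "spikes") {
  t0 <- spacing * (seq_len(n_trials) - 1) + 1
  ev <- tibble::tibble(trial = seq_len(n_trials), t_stim = t0,
                       t_action = t0 + 0.3, t_outcome = t0 + 0.5)
  n_bins <- ceiling((max(ev$t_outcome) + 1.5) / bin_width)
  neural_session(trace %||% numeric(n_bins), bin_width, ev, modality)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("delta F / F regresses the control channel onto the signal", {
  ctl <- 100 - seq(0, 5, length.out = 500)     # slow bleaching drift
  expect_true(all(abs(photometry_dff(ctl, ctl, z_score = FALSE)) < 1e-12))

  # affine control transforms are absorbed by the baseline fit
  transient <- c(rep(0, 200), dnorm(seq(-3, 3, length.out = 100)), rep(0, 200))
  sig <- 2 * ctl + 5 + transient
  dff <- photometry_dff(sig, ctl, z_score = FALSE)
  base <- fitted(lm(sig ~ ctl))
  expect_equal(dff, (sig - base) / base, tolerance = 1e-12)
  expect_gt(cor(dff, transient), 0.99)

  expect_error(photometry_dff(sig, rep(1, 500)), "constant")
  expect_error(photometry_dff(sig, ctl[1:10]), "length")
})

test_that("the design reproduces kernel convolution exactly", {
  s <- toy_session(n_trials = 3, bin_width = 0.1, spacing = 5)
  des <- build_design(s, supports = list(stim = c(0, 0.2)), events = "stim")
  kern <- list(stim = c(2, 2, 2))
  gains <- matrix(c(1, 2, 1), 3, 1, dimnames = list(NULL, "stim"))
  pred <- predict_trace(des, kern, gains)
  b <- des$event_bins$stim[2]
  expect_equal(pred[b:(b + 2)], c(4, 4, 4))
  expect_equal(sum(pred != 0), 9)

  # overlapping events add linearly
  s2 <- toy_session(n_trials = 2, bin_width = 0.1, spacing = 0.1)
  des2 <- build_design(s2, supports = list(stim = c(0, 0.2)), events = "stim")
  pred2 <- predict_trace(des2, kern, matrix(1, 2, 1))
  expect_equal(max(pred2), 4)

  # half-bin event times snap toward the earlier bin
  expect_equal(beliefrl:::snap_bin(0.05, 0.1), 1L)
  expect_equal(beliefrl:::snap_bin(0.06, 0.1), 2L)
})

test_that("each regression step is exact on noiseless data", {
  s <- toy_session(n_trials = 30)
  des <- build_design(s)
  kern <- default_kernels("spikes", 0.02)
  gains <- cbind(stim = runif(30, 1, 3), action = runif(30, 1, 3),
                 outcome = runif(30, 1, 3))
  trace <- predict_trace(des, kern, gains)

  k_hat <- fit_kernels(des, trace, gains)
  expect_equal(unclass(k_hat)[names(kern)], kern, tolerance = 1e-9,
               ignore_attr = TRUE)
  g_hat <- fit_gains(des, trace, kern)
  expect_equal(unname(g_hat[, colnames(gains)]), unname(gains),
               tolerance = 1e-9)
  # homogeneity: doubling the trace doubles the gains
  g2 <- fit_gains(des, 2 * trace, kern)
  expect_equal(unname(g2), unname(2 * g_hat), tolerance = 1e-9)

  # all-zero trace gives all-zero kernels
  k0 <- fit_kernels(des, numeric(des$n_bins), gains)
  expect_true(all(abs(unlist(k0[1:3])) < 1e-12))
})

test_that("a zero kernel leaves its gains at the initialisation value", {
  s <- toy_session(n_trials = 12)
  des <- build_design(s, supports = list(stim = c(0, 0.2)), events = "stim")
  g <- fit_gains(des, numeric(des$n_bins), list(stim = c(0, 0, 0, 0, 0, 0, 0,
                                                         0, 0, 0, 0)))
  expect_true(all(g[, "stim"] == 1))
  expect_equal(nrow(attr(g, "undetermined")), 12)
})

test_that("explained variance behaves at its reference points", {
  y <- rnorm(100)
  expect_equal(explained_variance(y, y), 1)
  expect_equal(explained_variance(y, rep(mean(y), 100)), 0)
  expect_lt(explained_variance(y, -y), 0)
})

test_that("the alternating fit recovers the kernel model on a synthetic session", {
  d <- sim_behavior_dataset(agent_params(), n_sessions = 1,
                            trials_per_session = 80, seed = 70)
  # constant gains, no noise: the first kernel pass is already exact
  ph <- suppressWarnings(sim_photometry_session(
    d, stim_gain = rep(2, 80), action_gain = rep(1, 80),
    outcome_gain = rep(3, 80), noise_sd = 0, seed = 71))
  sess <- ph$session
  sess$trace <- ph$truth$raw
  fit <- suppressWarnings(fit_event_kernels(sess, k_folds = 5))
  expect_gt(utils::tail(fit$train_ev, 1), 1 - 1e-9)
  expect_gt(fit$cv_ev, 0.99)
  # training EV never decreases across the alternation
  expect_true(all(diff(fit$train_ev) > -1e-9))
  # unit-norm kernels match the generating shapes up to sign-free scale
  for (e in c("stim", "action", "outcome")) {
    k <- fit$kernels$value[fit$kernels$event == e]
    expect_gt(abs(cor(k, ph$truth$kernels[[e]])), 0.999)
  }

  # single-event data: the fitted kernel equals the event-triggered average
  ph1 <- suppressWarnings(sim_photometry_session(
    d, stim_gain = rep(1, 80), action_gain = rep(0, 80),
    outcome_gain = rep(0, 80), noise_sd = 0, seed = 72))
  s1 <- ph1$session
  s1$trace <- ph1$truth$raw
  des1 <- build_design(s1, events = "stim")
  eta <- sapply(seq.int(0, 40), function(k)
    mean(s1$trace[des1$event_bins$stim + k]))
  f1 <- fit_event_kernels(s1, events = "stim", k_folds = 0,
                          intercept = FALSE)
  k1 <- f1$kernels$value * mean(f1$gains$stim)
  expect_equal(k1, eta, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("pure noise has near-zero cross-validated explained variance", {
  s <- toy_session(n_trials = 60, bin_width = 0.05, spacing = 5,
                   modality = "photometry")
  s$trace <- withr::with_seed(73, rnorm(length(s$trace)))
  fit <- suppressWarnings(fit_event_kernels(
    s, supports = list(stim = c(0, 1), action = c(-0.5, 0.2),
                       outcome = c(0, 1))))
  expect_lt(abs(fit$cv_ev), 0.1)
})

test_that("event reductions isolate the responsible event", {
  d <- sim_behavior_dataset(agent_params(), n_sessions = 1,
                            trials_per_session = 120, seed = 74)
  # an action-only neuron
  sp <- sim_spike_session(d, stim_gain = rep(0, 120),
                          action_gain = 6 + 5 * d$QC,
                          outcome_gain = rep(0, 120), seed = 75)
  tab <- suppressWarnings(event_reduction_comparison(sp$session))
  ev <- setNames(tab$cv_ev, tab$model)
  expect_gt(ev["only_action"], ev["full"] - 0.05)
  # stimulus regressors pick up part of the action response through their
  # temporal proximity, but far less than the action regressors themselves
  expect_lt(ev["only_stim"], 0.5 * ev["only_action"])
  expect_lt(ev["full"] - ev["drop_stim"], 0.05)
  expect_gt(ev["full"] - ev["drop_action"], 0.2)
})

test_that("gain-latent regressions quantify a constructed linear tie", {
  withr::with_seed(76, {
    latent <- runif(400, 0.5, 2)
    gains <- 2 * latent + rnorm(400, 0, 0.2)
  })
  cc <- correlate_gains_with_latents(gains, latent)
  g <- glance(cc)
  expect_lt(abs(g$slope - 2), 0.15)
  expect_gt(g$r_squared, 0.8)
  expect_equal(nrow(tidy(cc)), 10)

  null <- correlate_gains_with_latents(withr::with_seed(77, sample(gains)),
                                       latent)
  expect_lt(glance(null)$r_squared, 0.05)
  expect_error(correlate_gains_with_latents(gains, latent, n_bins = 1),
               "n_bins")
})
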