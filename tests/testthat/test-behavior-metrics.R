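test_that("psychometric proportions equal direct counting", {
  tr <- make_flat_trials(500, seed = 50)
  tr <- history_free_choices(tr, seed = 51)
  ps <- psychometric(tr)
  for (i in seq_len(nrow(ps))) {
    sel <- tr$signed_contrast == ps$signed_contrast[i]
    expect_equal(ps$n[i], sum(sel))
    expect_equal(ps$p_right[i], mean(tr$choice[sel] == "R"))
  }
  expect_equal(nrow(psychometric(tr[0, ])), 0)
})

test_that("the lapse-sigmoid psychometric fit recovers known parameters", {
  x <- rep(seq(-0.5, 0.5, length.out = 9), each = 1)
  n <- rep(5000, length(x))
  truth <- c(bias = 0.1, slope = 8, lapL = 0.02, lapR = 0.02)
  p <- truth["lapL"] + (1 - truth["lapL"] - truth["lapR"]) *
    pnorm(truth["slope"] * (x - truth["bias"]))
  k <- withr::with_seed(52, rbinom(length(x), n, p))
  dat <- tibble::tibble(signed_contrast = x, n = n, n_right = k)
  fit <- fit_psychometric(dat)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_lt(abs(est["bias"] - 0.1) / 0.1, 0.1)
  expect_lt(abs(est["slope"] - 8) / 8, 0.1)

  # mirrored data: bias flips sign, slope unchanged
  mir <- tibble::tibble(signed_contrast = -x, n = n, n_right = n - k)
  fm <- fit_psychometric(mir)
  em <- setNames(tidy(fm)$estimate, tidy(fm)$term)
  expect_equal(unname(em["bias"]), -unname(est["bias"]), tolerance = 1e-4)
  expect_equal(unname(em["slope"]), unname(est["slope"]), tolerance = 1e-4)

  # degenerate one-sided data is flagged
  deg <- tibble::tibble(signed_contrast = x, n = n, n_right = n)
  expect_true(glance(fit_psychometric(deg))$non_identifiable)
  # step data drives the slope into its bound
  stp <- tibble::tibble(signed_contrast = x, n = n,
                        n_right = ifelse(x > 0, n, 0))
  expect_true(glance(fit_psychometric(stp, slope_max = 15))$slope_at_bound)
  expect_error(fit_psychometric(dat[1:2, ]), "3 contrast")
})

test_that("history-free choices show no confidence-history shift", {
  tr <- make_flat_trials(60000, seed = 53)
  tr <- history_free_choices(tr, seed = 54)
  sh <- confidence_history_shift(tr)
  expect_true(all(abs(sh$shift) < 3 * sh$se))
})

test_that("the forward/backward correction cancels a slowly drifting side bias", {
  tr <- make_flat_trials(60000, seed = 55)
  drift <- function(i) 1.5 * sin(2 * pi * i / 800)
  tr <- history_free_choices(tr, bias_fun = drift, seed = 56)
  sh <- confidence_history_shift(tr)
  # the raw conditional shift is inflated by the drift ...
  expect_true(any(sh$shift_prev > 3 * sh$se))
  # ... but the corrected statistic is not
  expect_true(all(abs(sh$shift) < 3 * sh$se))
})

test_that("learning curves average the causal running mean around switches", {
  sched <- sim_block_schedule(1200, block_len_range = c(200, 200),
                              reward_x = 1, seed = 57)
  tr <- sim_trials(sched, seed = 58)
  tr <- adjudicate(tr, rep("R", nrow(tr)))
  lc <- learning_curve(tr, window = 10, before = 10, after = 30)
  expect_true(all(lc$p_right == 1))

  # window = 1 returns the raw rightward indicator
  lc1 <- learning_curve(tr, window = 1, before = 5, after = 5)
  expect_true(all(lc1$p_right %in% c(0, 1)))

  # the belief-RL agent transitions from the old to the new block preference
  ag <- run_agent(sim_trials(sim_block_schedule(
    6000, block_len_range = c(200, 200), reward_x = 3, seed = 59), seed = 60),
    agent_params(sigma2 = 0.04), seed = 61)
  lca <- learning_curve(ag, window = 10, before = 15, after = 80)
  toward_new <- lca %>%
    dplyr::mutate(p = ifelse(new_large_side == "R", p_right, 1 - p_right)) %>%
    dplyr::group_by(rel_trial) %>%
    dplyr::summarise(p = mean(p))
  early <- mean(toward_new$p[toward_new$rel_trial %in% -10:-1])
  late <- mean(toward_new$p[toward_new$rel_trial %in% 40:80])
  expect_gt(late, early + 0.15)
})

test_that("next-trial shifts split by outcome response follow the response size", {
  d <- sim_behavior_dataset(agent_params(sigma2 = 0.04), n_sessions = 8,
                            trials_per_session = 3000,
                            reward_asymmetry = FALSE, seed = 62)
  sp <- split_by_outcome_response(d, d$delta, percentile = 65)
  hi <- sp$shift[sp$group == "high"]
  lo <- sp$shift[sp$group == "low"]
  expect_gt(hi, lo)

  shuf <- withr::with_seed(63, sample(d$delta))
  sp0 <- split_by_outcome_response(d, shuf, percentile = 50)
  expect_lt(abs(sp0$shift[sp0$group == "high"] - sp0$shift[sp0$group == "low"]),
            abs(hi - lo) / 2)
})

test_that("reaction times are z-scored within sessions", {
  rt <- c(1, 2, 3, 10, 20, 30)
  s <- rep(1:2, each = 3)
  z <- zscore_rt(rt, s)
  expect_equal(mean(z), 0)
  expect_equal(z[1:3], z[4:6])             # affine invariance across sessions
  expect_equal(zscore_rt(rt * 3 + 5, s), z)  # affine invariance within
  expect_error(zscore_rt(c(1, 1, 1), rep(1, 3)), "constant")
  expect_error(zscore_rt(c(1, NA, NA), rep(1, 3)), "fewer than 2")
})
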