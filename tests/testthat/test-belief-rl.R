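test_that("percepts are Gaussian around the true contrast", {
  expect_equal(sample_percept(0.25, 0), 0.25)
  expect_error(sample_percept(0.25, -1), "nonnegative")

  withr::with_seed(1, {
    s <- sample_percept(rep(0, 1e5), 0.04)
    expect_lt(abs(mean(s)), 3 * sqrt(0.04 / 1e5))
    # variance of a sample variance: 2 sigma^4 / (n - 1)
    expect_lt(abs(var(s) - 0.04), 3 * sqrt(2 * 0.04^2 / (1e5 - 1)))
  })
})

test_that("the rightward belief equals the Gaussian posterior mass over (0, Inf)", {
  expect_equal(belief_right(0, 0.2), 0.5)
  expect_equal(belief_right(sqrt(0.09), 0.09), pnorm(1))
  expect_equal(belief_right(0.3, Inf), 0.5)
  expect_equal(belief_right(c(-1, 0, 2), 0), c(0, 0.5, 1))

  # brute-force numeric integration of the posterior N(s_hat, sigma2)
  for (s2 in c(0.04, 0.2, 0.8)) {
    for (sh in seq(-0.6, 0.6, by = 0.15)) {
      oracle <- stats::integrate(function(s) dnorm(s, sh, sqrt(s2)), 0, Inf,
                                 rel.tol = 1e-10)$value
      expect_lt(abs(belief_right(sh, s2) - oracle), 1e-6)
    }
  }
})

test_that("the agent picks the larger expected value and records its confidence", {
  withr::with_seed(1, {
    a <- choose_action(0.5, 0.5, 1, 2.2)
    expect_equal(a$choice, "R")
    expect_equal(a$QC, 1.1)
    expect_equal(a$pC, 0.5)

    b <- choose_action(0.9, 0.1, 1, 2.2)
    expect_equal(b$choice, "L")
    expect_equal(b$QC, 0.9)
    expect_equal(b$QL, 0.9)
    expect_equal(b$QR, 0.22)

    ties <- choose_action(rep(0.5, 1e4), rep(0.5, 1e4), 1, 1)
    expect_lt(abs(mean(ties$choice == "R") - 0.5), 3 * sqrt(0.25 / 1e4))
  })
})

test_that("prediction errors subtract predicted value with manipulation offsets", {
  expect_equal(prediction_error(1, 0.5), 0.5)
  expect_equal(prediction_error(0, 0.9), -0.9)
  # a reduced QC on an mPFC-suppression trial over-credits the reward
  expect_equal(prediction_error(1, 0.5, q_offset = -0.3), 0.8)
  expect_equal(prediction_error(1, 0.5, d_offset = 0.2), 0.7)
})

test_that("only the chosen value is updated", {
  expect_equal(update_values(1, 2, "L", 0.5, 0.5), c(VL = 1.25, VR = 2))
  expect_equal(update_values(1, 2, "L", 0, 5), c(VL = 1, VR = 2))
  expect_equal(update_values(1, 2, "L", 0.2, -1), c(VL = 0.8, VR = 2))
  expect_error(update_values(1, 2, "L", 1.2, 0), "alpha")
})

test_that("the simulation core agrees with a pure-R reference, draw for draw", {
  tr <- make_flat_trials(200, seed = 20)
  p <- agent_params(alpha = 0.3, sigma2 = 0.15, x = 2)
  ref <- withr::with_seed(42, reference_agent(tr, p))
  got <- run_agent(tr, p, seed = 42)
  expect_equal(got$choice, ref$choice)
  expect_equal(got$s_hat, ref$s_hat, tolerance = 1e-12)
  expect_equal(got$QC, ref$QC, tolerance = 1e-12)
  expect_equal(got$delta, ref$delta, tolerance = 1e-12)
  expect_equal(got$VL, ref$VL, tolerance = 1e-12)

  # sigma2 = 0 consumes uniforms only at zero contrast; exact agreement too
  p0 <- agent_params(alpha = 0.2, sigma2 = 0, x = 1)
  ref0 <- withr::with_seed(7, reference_agent(tr, p0))
  got0 <- run_agent(tr, p0, seed = 7)
  expect_equal(got0$choice, ref0$choice)
})

test_that("a noiseless frozen agent is perfect on nonzero contrast and at chance at zero", {
  tr <- make_flat_trials(4000, seed = 21)
  out <- run_agent(tr, agent_params(alpha = 0, sigma2 = 0, x = 0), seed = 1)
  nz <- out[out$signed_contrast != 0, ]
  z <- out[out$signed_contrast == 0, ]
  expect_true(all(nz$correct))
  expect_lt(abs(mean(z$choice == "R") - 0.5), 3 * sqrt(0.25 / nrow(z)))
})

test_that("with an uninformative percept, converged choices follow the large-reward side", {
  sched <- sim_block_schedule(3000, block_len_range = c(300, 300),
                              reward_x = 3, seed = 22)
  tr <- sim_trials(sched, seed = 23)
  out <- run_agent(tr, agent_params(alpha = 0.25, sigma2 = Inf, x = 3),
                   seed = 24)
  expect_true(all(out$pR == 0.5))
  late <- dplyr::filter(out, trial - sched$block_start[block_id] >= 100)
  large <- ifelse(late$reward_if_correct_R > late$reward_if_correct_L, "R", "L")
  # zero-contrast outcome lotteries keep the values fluctuating, so a small
  # fraction of value-driven reversals persists even after convergence
  expect_gt(mean(late$choice == large), 0.8)
})

test_that("reduced variants pin the named component", {
  base <- agent_params(alpha = 0.25, sigma2 = 0.2, x = 3)
  expect_equal(reduced_variant(base, "sigma2_zero")$sigma2, 0)
  expect_true(is.infinite(reduced_variant(base, "sigma2_inf")$sigma2))
  expect_equal(reduced_variant(base, "no_x")$x, 0)
  expect_equal(reduced_variant(base, "no_alpha")$alpha, 0)
  expect_error(reduced_variant(base, "no_such"), "variant")
})

test_that("simulated psychometric curves are monotone and shift with reward blocks", {
  d <- sim_behavior_dataset(agent_params(), n_sessions = 4,
                            trials_per_session = 3000, seed = 25)
  ps <- psychometric(d)
  expect_true(all(diff(ps$p_right[order(ps$signed_contrast)]) > -0.02))

  d$large <- ifelse(d$reward_if_correct_R > d$reward_if_correct_L, "R", "L")
  byb <- psychometric(d, large) %>%
    tidyr::pivot_wider(id_cols = "signed_contrast", names_from = "large",
                       values_from = "p_right")
  shift <- byb$R - byb$L
  expect_true(all(shift > 0))
  expect_equal(byb$signed_contrast[which.max(shift)], 0)
})
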