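test_that("Monte-Carlo choice probabilities are deterministic given the seed", {
  tr <- make_flat_trials(300, seed = 40)
  det <- simulate_choice_probs(tr, agent_params(alpha = 0, sigma2 = 0, x = 0),
                               n_iter = 5, seed = 1)
  nz <- tr$signed_contrast != 0
  p_correct <- ifelse(tr$side == "R", det$p_right, det$p_left)
  expect_true(all(p_correct[nz] == 1))
  expect_equal(det$p_left + det$p_right, rep(1, 300))

  p <- agent_params(alpha = 0.25, sigma2 = 0.2, x = 3)
  a <- simulate_choice_probs(tr, p, n_iter = 50, seed = 9)
  b <- simulate_choice_probs(tr, p, n_iter = 50, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_choice_probs(tr, p, n_iter = 0), "n_iter")
})

test_that("the NLL is the floored mean negative log choice probability", {
  expect_equal(choice_nll(c("L", "R"), c(0, 1)), 0)
  expect_equal(choice_nll(rep("R", 4), rep(0.5, 4)), log(2))
  expect_equal(choice_nll("R", 0, floor = 1e-3), -log(1e-3))
  expect_error(choice_nll(c("L", "R"), 0.5), "length")
})

test_that("trial order is irrelevant for a history-free agent but not a learner", {
  tr <- make_flat_trials(400, seed = 41)
  perm <- withr::with_seed(5, sample.int(400))
  p0 <- agent_params(alpha = 0, sigma2 = 0.1, x = 0)
  pr <- simulate_choice_probs(tr, p0, n_iter = 400, seed = 2)
  pr_perm <- simulate_choice_probs(tr[perm, ], p0, n_iter = 400, seed = 3)
  # un-permute: per-trial probabilities match up to Monte-Carlo noise
  expect_lt(max(abs(pr$p_right[perm] - pr_perm$p_right)),
            4 * sqrt(0.25 / 400) * 2)

  p1 <- agent_params(alpha = 0.45, sigma2 = 0.1, x = 3)
  tr_asym <- sim_trials(sim_block_schedule(400, block_len_range = c(100, 100),
                                           reward_x = 3, seed = 6), seed = 7)
  q <- simulate_choice_probs(tr_asym, p1, n_iter = 400, seed = 2)
  q_perm <- simulate_choice_probs(tr_asym[perm, ], p1, n_iter = 400, seed = 3)
  expect_gt(max(abs(q$p_right[perm] - q_perm$p_right)), 0.2)
})

test_that("the Monte-Carlo error of the NLL shrinks as one over root n_iter", {
  tr <- make_flat_trials(200, seed = 48)
  tr <- adjudicate(tr, run_agent(tr, agent_params(), seed = 1)$choice)
  p <- agent_params(alpha = 0.25, sigma2 = 0.2, x = 3)
  nlls <- function(n_iter) vapply(1:20, function(s) {
    probs <- simulate_choice_probs(tr, p, n_iter = n_iter, seed = 1000 + s)
    choice_nll(tr$choice, probs$p_right, floor = 1 / (n_iter + 1))
  }, numeric(1))
  ratio <- sd(nlls(50)) / sd(nlls(450))     # expected sqrt(9) = 3
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 5)
})

test_that("a one-point grid returns that point and grids stay on the printed lattice", {
  tr <- make_flat_trials(100, seed = 42)
  tr <- adjudicate(tr, run_agent(tr, agent_params(), seed = 1)$choice)
  fit <- fit_grid(tr, grid = list(alpha = 0.25, sigma2 = 0.2, x = 3),
                  n_iter = 20, seed = 1)
  expect_equal(glance(fit)$alpha, 0.25)
  expect_equal(nrow(tidy(fit)), 1)

  g <- default_grid(full = TRUE)
  expect_equal(length(g$alpha), 20)
  expect_equal(length(g$sigma2), 20)
  expect_equal(length(g$x), 76)
  expect_equal(g$alpha[2] - g$alpha[1], 0.05)
  expect_equal(range(g$x), c(-5, 10))
})

test_that("a frozen-learning generator is recovered at the grid's alpha floor", {
  d <- sim_behavior_dataset(agent_params(alpha = 0, sigma2 = 0.2, x = 3),
                            n_sessions = 2, trials_per_session = 600,
                            seed = 43)
  fit <- fit_grid(d, grid = list(alpha = c(0, 0.2, 0.4), sigma2 = 0.2, x = 3),
                  n_iter = 100, seed = 2)
  expect_equal(fit$best_params$alpha, 0)
})

test_that("cross-validation requires enough sessions and handles identical variants", {
  d <- sim_behavior_dataset(agent_params(), n_sessions = 2,
                            trials_per_session = 200, seed = 44)
  expect_error(crossval_variants(d, k = 3), "fewer sessions")

  d3 <- sim_behavior_dataset(agent_params(), n_sessions = 3,
                             trials_per_session = 200, seed = 45)
  run <- function() crossval_variants(
    d3, variants = "full", k = 3,
    grid = list(alpha = 0.25, sigma2 = 0.2, x = 3), n_iter = 50, seed = 3)
  expect_identical(glance(run()), glance(run()))
})

test_that("manipulation constants are recovered by the offset search", {
  d <- sim_behavior_dataset(agent_params(sigma2 = 0.04, d_offset = 0.6),
                            n_sessions = 6, trials_per_session = 600,
                            reward_asymmetry = FALSE,
                            laser_plan = "outcome_blocks", seed = 46)
  fit <- fit_offset(d, agent_params(sigma2 = 0.04), kind = "d_offset",
                    offsets = seq(-0.8, 0.8, by = 0.2), n_iter = 150,
                    seed = 4)
  expect_gt(fit$best_offset, 0)
  expect_lte(abs(fit$best_offset - 0.6), 0.2)

  zero <- fit_offset(d, agent_params(sigma2 = 0.04), kind = "d_offset",
                     offsets = 0, n_iter = 20, seed = 1)
  expect_equal(zero$best_offset, 0)
  expect_error(fit_offset(make_flat_trials(50), agent_params()), "laser")
})
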