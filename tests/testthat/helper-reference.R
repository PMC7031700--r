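# Pure-R reference implementation of the sequential belief-RL agent.  It
# consumes the RNG stream in exactly the same order as the package's
# simulation core (one normal draw per trial when 0 < sigma2 < Inf, one
# uniform draw only on exact expected-value ties), so under a common seed the
# two implementations must agree draw for draw.
reference_agent <- function(trials, params) {
  VL <- params$v_init
  VR <- params$v_init
  n <- nrow(trials)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s2 <- params$sigma2
    sh <- if (is.finite(s2) && s2 > 0)
      rnorm(1, trials$signed_contrast[i], sqrt(s2))
    else trials$signed_contrast[i]
    pR <- if (is.infinite(s2)) 0.5
    else if (s2 == 0) 0.5 * (sign(sh) + 1)
    else pnorm(sh / sqrt(s2))
    pL <- 1 - pR
    QL <- pL * VL
    QR <- pR * VR
    choice <- if (QR > QL) "R" else if (QL > QR) "L" else
      if (runif(1) < 0.5) "R" else "L"
    pC <- if (choice == "R") pR else pL
    QC <- if (choice == "R") QR else QL
    correct <- choice == trials$side[i]
    r_choice <- if (choice == "R") trials$reward_if_correct_R[i] else
      trials$reward_if_correct_L[i]
    r_other <- if (choice == "R") trials$reward_if_correct_L[i] else
      trials$reward_if_correct_R[i]
    r_subj <- if (!correct) 0 else if (r_choice > r_other) 1 + params$x else 1
    delta <- r_subj - QC
    out[[i]] <- data.frame(choice = choice, pL = pL, pR = pR, QL = QL,
                           QR = QR, pC = pC, QC = QC, delta = delta,
                           VL = VL, VR = VR, s_hat = sh)
    if (choice == "R") VR <- VR + params$alpha * delta else
      VL <- VL + params$alpha * delta
  }
  do.call(rbind, out)
}

# Small equal-reward trial table used across tests.
make_flat_trials <- function(n, contrast_set = c(0, 0.125, 0.25, 0.5),
                             seed = 1) {
  sched <- sim_block_schedule(n, reward_asymmetry = FALSE, seed = seed)
  sim_trials(sched, contrast_set = contrast_set, seed = seed + 1)
}

# History-free synthetic chooser: choices drawn from a fixed logistic
# psychometric function, optionally with an additive slowly varying bias on
# the logit scale; rewards adjudicated by the task rules.
history_free_choices <- function(trials, slope = 8, bias_fun = NULL,
                                 seed = 1) {
  withr::with_seed(seed, {
    n <- nrow(trials)
    b <- if (is.null(bias_fun)) rep(0, n) else bias_fun(seq_len(n))
    p <- stats::plogis(slope * trials$signed_contrast + b)
    adjudicate(trials, ifelse(runif(n) < p, "R", "L"))
  })
}
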