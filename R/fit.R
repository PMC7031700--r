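#' Monte-Carlo choice probabilities of the belief-RL agent
#'
#' Free-runs the agent `n_iter` times over the fixed stimulus sequence with
#' independent percept noise and returns, per trial, the fraction of
#' iterations on which each side was chosen.  Identical seeds give
#' identical probability arrays.
#'
#' @param trials Trial table carrying stimuli and reward contingencies.
#' @param params An [agent_params()] object.
#' @param n_iter Number of simulation iterations (the reference analysis
#'   uses 1000; smaller values trade precision for speed).
#' @param seed Optional integer seed.
#' @return A tibble with per-trial `p_left` and `p_right` (summing to 1),
#'   with the iteration count in attribute `n_iter`.
#' @export
simulate_choice_probs <- function(trials, params, n_iter = 1000, seed = NULL) {
  if (n_iter < 1) abort("`n_iter` must be at least 1.")
  n <- nrow(trials)
  sess_raw <- col_or(trials, "session", rep(1L, n))
  session <- as.integer(factor(sess_raw, levels = unique(sess_raw)))
  epoch <- col_or(trials, "laser_epoch", rep("none", n))
  laser_stim <- epoch == "stimulus" & col_or(trials, "laser_on", rep(TRUE, n))
  laser_side <- col_or(trials, "laser_side", rep(NA_character_, n))
  out_side <- ifelse(is.na(laser_side), -1L, side_to_int(laser_side))
  out_trial <- epoch == "outcome" & is.na(laser_side) &
    col_or(trials, "laser_on", rep(FALSE, n))

  p_r <- with_seed(seed, cpp_choice_probs(
    trials$signed_contrast, side_to_int(trials$side),
    trials$reward_if_correct_L, trials$reward_if_correct_R, session,
    laser_stim, as.integer(out_side), out_trial,
    params$alpha, params$sigma2, params$x, params$q_offset, params$d_offset,
    params$v_init, FALSE, 0.1, as.integer(n_iter)))
  out <- tibble::tibble(p_left = 1 - p_r, p_right = p_r)
  attr(out, "n_iter") <- n_iter
  out
}

#' Mean negative log-likelihood of recorded choices
#'
#' The NLL is the across-trial average of `-log(P(choice))`, with
#' probabilities floored to keep the sum finite when a Monte-Carlo frequency
#' is exactly zero.  The natural floor for a frequency estimated from
#' `n_iter` iterations is `1 / (n_iter + 1)`.
#'
#' @param choice Character vector of recorded `"L"`/`"R"` choices.
#' @param p_right Per-trial probability of a rightward choice (as from
#'   [simulate_choice_probs()]).
#' @param floor Probability floor applied inside the log.
#' @return Mean NLL (a scalar).
#' @export
choice_nll <- function(choice, p_right, floor = 0) {
  if (length(choice) != length(p_right))
    abort("`choice` and `p_right` must have the same length.")
  p <- ifelse(choice == "R", p_right, 1 - p_right)
  mean(-log(pmax(p, floor)))
}

#' Default parameter grids for the exhaustive search
#'
#' `full = TRUE` returns the reference grids
#' `alpha = 0:0.05:0.95`, `sigma2 = 0.04:0.04:0.8`, `x = -5:0.2:10`
#' (inclusive endpoints; 20 x 20 x 76 points).  The default coarse grid is a
#' 5 x 5 x 6 subset for desk-scale fitting whose interior contains the
#' package's default generating parameters.
#'
#' @param full Return the full reference grid?
#' @return Named list of numeric vectors `alpha`, `sigma2`, `x`.
#' @export
default_grid <- function(full = FALSE) {
  if (full) {
    list(alpha = seq(0, 0.95, by = 0.05),
         sigma2 = seq(0.04, 0.8, by = 0.04),
         x = seq(-5, 10, by = 0.2))
  } else {
    list(alpha = c(0.05, 0.15, 0.25, 0.35, 0.45),
         sigma2 = c(0.04, 0.12, 0.20, 0.28, 0.36),
         x = c(1, 2, 3, 4, 5, 6))
  }
}

variant_grid <- function(grid, variant) {
  switch(variant,
         full = grid,
         sigma2_zero = { grid$sigma2 <- 0; grid },
         sigma2_inf = { grid$sigma2 <- Inf; grid },
         no_x = { grid$x <- 0; grid },
         no_alpha = { grid$alpha <- 0; grid },
         abort(sprintf("unknown model variant '%s'", variant)))
}

#' Exhaustive-grid simulation-based model fit
#'
#' Evaluates the Monte-Carlo NLL of the recorded choices at every point of
#' the parameter grid and returns the minimising parameters.  By default the
#' same seed is reused at every grid point (common random numbers), which
#' removes between-point simulation variance from the comparison.
#'
#' @param trials Trial table with recorded choices.
#' @param grid Named list of candidate values for `alpha`, `sigma2`, `x`
#'   (see [default_grid()]); scalars pin a parameter.
#' @param variant Model variant (see [reduced_variant()]); pins the
#'   corresponding grid dimension.
#' @param n_iter Simulation iterations per grid point.
#' @param seed Integer seed.
#' @param common_rng Reuse the seed across grid points (default `TRUE`).
#' @param q_offset,d_offset Manipulation constants held fixed during the
#'   search.
#' @return An object of class `rl_fit`: the evaluated grid with NLLs
#'   (`tidy()`), the best parameters (`$best_params`) and fit metadata
#'   (`glance()`).
#' @export
fit_grid <- function(trials, grid = default_grid(), variant = "full",
                     n_iter = 200, seed = 1, common_rng = TRUE,
                     q_offset = 0, d_offset = 0) {
  assert_columns(trials, "choice")
  grid <- variant_grid(grid, variant)
  if (any(lengths(grid) == 0)) abort("grid dimensions must be non-empty.")
  points <- tidyr::expand_grid(alpha = grid$alpha, sigma2 = grid$sigma2,
                               x = grid$x)
  floor_p <- 1 / (n_iter + 1)
  nll <- purrr::pmap_dbl(points, function(alpha, sigma2, x) {
    p <- agent_params(alpha = alpha, sigma2 = sigma2, x = x,
                      q_offset = q_offset, d_offset = d_offset)
    probs <- simulate_choice_probs(trials, p, n_iter = n_iter,
                                   seed = if (common_rng) seed else NULL)
    choice_nll(trials$choice, probs$p_right, floor = floor_p)
  })
  points$nll <- nll
  best <- points[which.min(points$nll), ]
  structure(list(
    grid = points,
    best_params = agent_params(alpha = best$alpha, sigma2 = best$sigma2,
                               x = best$x, q_offset = q_offset,
                               d_offset = d_offset),
    variant = variant, n_iter = n_iter, floor = floor_p, seed = seed,
    n_trials = nrow(trials)), class = "rl_fit")
}

#' @method print rl_fit
#' @export
print.rl_fit <- function(x, ...) {
  b <- x$best_params
  cat("<rl_fit>", x$variant, "model,", nrow(x$grid), "grid points,",
      x$n_trials, "trials\n  best: alpha =", b$alpha, " sigma2 =", b$sigma2,
      " x =", b$x, " (NLL =", round(min(x$grid$nll), 4), ")\n")
  invisible(x)
}

#' @export
tidy.rl_fit <- function(x, ...) x$grid

#' @export
glance.rl_fit <- function(x, ...) {
  b <- x$best_params
  meta <- list(variant = x$variant, nll = min(x$grid$nll),
               n_grid = nrow(x$grid), n_iter = x$n_iter,
               n_trials = x$n_trials)
  tibble::tibble(variant = meta$variant, alpha = b$alpha, sigma2 = b$sigma2,
                 x = b$x, nll = meta$nll, n_grid = meta$n_grid,
                 n_iter = meta$n_iter, n_trials = meta$n_trials)
}

#' Cross-validated comparison of model variants
#'
#' Sessions are split into `k` folds; for each fold and variant the model is
#' fitted by [fit_grid()] on the training sessions and the fitted parameters
#' are evaluated on the held-out sessions.  The reference analysis uses
#' 3-fold cross-validation over sessions.
#'
#' @param trials Trial table with a `session` column and recorded choices.
#' @param variants Character vector of variant names.
#' @param k Number of folds (must not exceed the number of sessions).
#' @param grid Parameter grid passed to [fit_grid()].
#' @param n_iter Simulation iterations per grid point.
#' @param seed Integer seed.
#' @return An object of class `cv_compare`; `tidy()` gives per-fold test
#'   NLLs, `glance()` the across-fold mean per variant.
#' @export
crossval_variants <- function(trials,
                              variants = c("full", "sigma2_zero", "sigma2_inf",
                                           "no_x", "no_alpha"),
                              k = 3, grid = default_grid(), n_iter = 100,
                              seed = 1) {
  assert_columns(trials, c("session", "choice"))
  sessions <- unique(trials$session)
  if (length(sessions) < k)
    abort("fewer sessions than folds.")
  fold_of <- rep_len(seq_len(k), length(sessions))
  rows <- purrr::map(seq_len(k), function(f) {
    test_sessions <- sessions[fold_of == f]
    train <- trials[!trials$session %in% test_sessions, ]
    test <- trials[trials$session %in% test_sessions, ]
    purrr::map(variants, function(v) {
      fit <- fit_grid(train, grid = grid, variant = v, n_iter = n_iter,
                      seed = seed)
      probs <- simulate_choice_probs(test, fit$best_params, n_iter = n_iter,
                                     seed = seed)
      tibble::tibble(variant = v, fold = f,
                     train_nll = min(fit$grid$nll),
                     test_nll = choice_nll(test$choice, probs$p_right,
                                           floor = fit$floor),
                     alpha = fit$best_params$alpha,
                     sigma2 = fit$best_params$sigma2,
                     x = fit$best_params$x)
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  structure(list(folds = rows,
                 summary = rows %>%
                   dplyr::group_by(.data$variant) %>%
                   dplyr::summarise(mean_test_nll = mean(.data$test_nll),
                                    mean_train_nll = mean(.data$train_nll),
                                    .groups = "drop")),
            class = "cv_compare")
}

#' @method print cv_compare
#' @export
print.cv_compare <- function(x, ...) {
  cat("<cv_compare> mean held-out NLL per variant:\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.cv_compare <- function(x, ...) x$folds

#' @export
glance.cv_compare <- function(x, ...) x$summary

#' Fit an optogenetic manipulation constant
#'
#' Holding the behavioral parameters fixed, searches an offset grid for the
#' constant -- added to the predicted value QC (`q_offset`, stimulus-time
#' suppression) or to the prediction error (`d_offset`, outcome-time
#' dopamine manipulation) -- that minimises the Monte-Carlo NLL of the
#' recorded choices.
#'
#' @param trials Trial table containing laser-flagged trials.
#' @param base_params Fitted [agent_params()] held fixed.
#' @param kind `"q_offset"` or `"d_offset"`.
#' @param offsets Candidate offset grid.
#' @param n_iter Simulation iterations per candidate.
#' @param seed Integer seed (common random numbers across candidates).
#' @return An object of class `offset_fit` with the NLL curve and best
#'   offset.
#' @export
fit_offset <- function(trials, base_params, kind = c("q_offset", "d_offset"),
                       offsets = seq(-1, 1, by = 0.1), n_iter = 200,
                       seed = 1) {
  kind <- match.arg(kind)
  epoch <- col_or(trials, "laser_epoch", rep("none", nrow(trials)))
  if (!any(epoch != "none"))
    abort("no laser-flagged trials in the dataset.")
  floor_p <- 1 / (n_iter + 1)
  nll <- purrr::map_dbl(offsets, function(o) {
    p <- base_params
    p[[kind]] <- o
    probs <- simulate_choice_probs(trials, p, n_iter = n_iter, seed = seed)
    choice_nll(trials$choice, probs$p_right, floor = floor_p)
  })
  structure(list(curve = tibble::tibble(offset = offsets, nll = nll),
                 best_offset = offsets[which.min(nll)], kind = kind,
                 n_iter = n_iter), class = "offset_fit")
}

#' @method print offset_fit
#' @export
print.offset_fit <- function(x, ...) {
  cat("<offset_fit>", x$kind, "best =", x$best_offset, "\n")
  invisible(x)
}

#' @export
tidy.offset_fit <- function(x, ...) x$curve

#' @export
glance.offset_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, best_offset = x$best_offset,
                 min_nll = min(x$curve$nll), n_iter = x$n_iter)
}
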