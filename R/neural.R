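#' Container for a binned neural session
#'
#' Couples a binned trace (z-scored spike counts or \eqn{\Delta F/F}) with
#' per-trial event times on the same clock.
#'
#' @param trace Numeric vector of per-bin signal values.
#' @param bin_width Bin width in seconds (0.020 for spikes, 0.050 for
#'   photometry by convention).
#' @param events Tibble with columns `trial`, `t_stim`, `t_action`,
#'   `t_outcome` (seconds from trace start; `NA` for missing events).
#' @param modality `"spikes"` or `"photometry"`.
#' @return An object of class `neural_session`.
#' @export
neural_session <- function(trace, bin_width, events,
                           modality = c("spikes", "photometry")) {
  modality <- match.arg(modality)
  assert_columns(events, c("trial", "t_stim", "t_action", "t_outcome"),
                 "event table")
  structure(list(trace = as.numeric(trace), bin_width = bin_width,
                 events = events, modality = modality),
            class = "neural_session")
}

#' @method print neural_session
#' @export
print.neural_session <- function(x, ...) {
  cat("<neural_session>", x$modality, ":", length(x$trace), "bins of",
      x$bin_width, "s,", nrow(x$events), "trials\n")
  invisible(x)
}

#' Default kernel supports per modality
#'
#' Spikes: stimulus `[0, 0.6]`, action `[-0.4, 0.2]`, outcome `[0, 0.6]` s.
#' Photometry (slow calcium transients): `[0, 2]`, `[-1, 0.2]`, `[0, 3]` s.
#'
#' @param modality `"spikes"` or `"photometry"`.
#' @return Named list of `c(lo, hi)` supports.
#' @export
default_supports <- function(modality = c("spikes", "photometry")) {
  modality <- match.arg(modality)
  if (modality == "spikes") {
    list(stim = c(0, 0.6), action = c(-0.4, 0.2), outcome = c(0, 0.6))
  } else {
    list(stim = c(0, 2), action = c(-1, 0.2), outcome = c(0, 3))
  }
}

# Snap an event time to its nearest bin (1-based); exact half-bin ties round
# toward the earlier bin.
snap_bin <- function(t, bin_width) {
  as.integer(ceiling(t / bin_width - 0.5)) + 1L
}

#' Build the event-indicator design for the kernel regression
#'
#' Each event contributes one unit impulse at its nearest bin; convolving a
#' kernel with these indicators reproduces the model's predicted trace
#' exactly.  Events whose kernel window would leave the trace are excluded
#' (with a warning naming the count).  Bins are assigned to the trial with
#' the nearest anchor event, which defines the contiguous cross-validation
#' segments.
#'
#' @param session A [neural_session()].
#' @param supports Named list of kernel supports in seconds
#'   (default: [default_supports()] for the session's modality).
#' @param events Which events to include.
#' @return An object of class `kernel_design`.
#' @export
build_design <- function(session, supports = NULL,
                         events = c("stim", "action", "outcome")) {
  stopifnot(inherits(session, "neural_session"))
  supports <- supports %||% default_supports(session$modality)
  supports <- supports[events]
  if (any(purrr::map_lgl(supports, function(s) s[2] <= s[1])))
    abort("kernel supports must have positive length.")
  bw <- session$bin_width
  n_bins <- length(session$trace)
  ev_tab <- session$events
  J <- nrow(ev_tab)

  offsets <- purrr::map(supports, function(s)
    seq.int(round(s[1] / bw), round(s[2] / bw)))
  event_bins <- purrr::map(events, function(e) {
    t <- ev_tab[[paste0("t_", e)]]
    b <- snap_bin(t, bw)
    off <- offsets[[e]]
    bad <- !is.na(b) & (b + min(off) < 1 | b + max(off) > n_bins)
    if (any(bad)) {
      warn(sprintf("%d %s event(s) fall outside the trace and are excluded",
                   sum(bad), e))
      b[bad] <- NA_integer_
    }
    b
  })
  names(event_bins) <- events

  # trial ownership of bins: nearest anchor (first available event per trial)
  anchors <- purrr::reduce(event_bins, dplyr::coalesce)
  ord <- order(anchors)
  bounds <- floor((anchors[ord][-J] + anchors[ord][-1]) / 2)
  seg <- rep.int(ord, diff(c(0L, pmin(pmax(bounds, 0L), n_bins), n_bins)))

  structure(list(n_bins = n_bins, bin_width = bw, events = events,
                 offsets = offsets, event_bins = event_bins,
                 n_trials = J, trial = ev_tab$trial, trial_seg = seg),
            class = "kernel_design")
}

# Sparse design for the kernel-fitting step (gains fixed): columns are
# kernel bins of all included events.
kernel_step_X <- function(design, gains) {
  i <- integer(0); j <- integer(0); x <- numeric(0)
  col0 <- 0L
  for (e in design$events) {
    off <- design$offsets[[e]]
    K <- length(off)
    b <- design$event_bins[[e]]
    ok <- which(!is.na(b))
    if (length(ok)) {
      i <- c(i, rep(b[ok], each = K) + rep.int(off, length(ok)))
      j <- c(j, rep.int(col0 + seq_len(K), length(ok)))
      x <- c(x, rep(gains[ok, e], each = K))
    }
    col0 <- col0 + K
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(design$n_bins, col0))
}

# Sparse design for the gain-fitting step (kernels fixed): one column per
# (trial, event) with the shifted kernel as its profile.
gain_step_X <- function(design, kernels) {
  i <- integer(0); j <- integer(0); x <- numeric(0)
  J <- design$n_trials
  for (ei in seq_along(design$events)) {
    e <- design$events[ei]
    off <- design$offsets[[e]]
    K <- length(off)
    b <- design$event_bins[[e]]
    ok <- which(!is.na(b))
    if (length(ok)) {
      i <- c(i, rep(b[ok], each = K) + rep.int(off, length(ok)))
      j <- c(j, rep((ei - 1L) * J + ok, each = K))
      x <- c(x, rep.int(kernels[[e]], length(ok)))
    }
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(design$n_bins, length(design$events) * J))
}

solve_ls <- function(X, y, ridge = 0) {
  XtX <- Matrix::crossprod(X)
  Xty <- as.numeric(Matrix::crossprod(X, y))
  if (ridge > 0) XtX <- XtX + ridge * Matrix::Diagonal(ncol(X))
  beta <- tryCatch(as.numeric(Matrix::solve(XtX, Xty)),
                   error = function(err) NULL)
  if (is.null(beta)) {
    warn("rank-deficient design; returning minimum-norm least-squares solution")
    A <- as.matrix(XtX)
    sv <- svd(A)
    pos <- sv$d > max(sv$d[1], 0) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Xty) / sv$d[pos])
    beta <- as.numeric(beta)
  }
  beta
}

#' Fit kernel shapes with per-trial gains held fixed
#'
#' Simultaneous least squares for all kernel bins of all included events.
#'
#' @param design A [build_design()] object.
#' @param trace Numeric trace.
#' @param gains Matrix of per-trial gains (trials x events, column order as
#'   `design$events`).
#' @param rows Optional logical vector restricting the fit to a bin subset.
#' @param ridge Optional ridge penalty for rank-deficient designs.
#' @param intercept Also fit a free baseline term (returned in the
#'   `"intercept"` attribute); useful on z-scored traces whose event
#'   regressors have nonzero mean.
#' @return Named list of kernel vectors, one per event.
#' @export
fit_kernels <- function(design, trace, gains, rows = NULL, ridge = 0,
                        intercept = FALSE) {
  X <- kernel_step_X(design, gains)
  if (intercept)
    X <- cbind(X, Matrix::sparseMatrix(i = seq_len(design$n_bins),
                                       j = rep(1L, design$n_bins), x = 1,
                                       dims = c(design$n_bins, 1L)))
  y <- trace
  if (!is.null(rows)) { X <- X[rows, , drop = FALSE]; y <- y[rows] }
  beta <- solve_ls(X, y, ridge)
  b0 <- 0
  if (intercept) { b0 <- beta[length(beta)]; beta <- beta[-length(beta)] }
  ks <- split(beta, rep(seq_along(design$events),
                        lengths(design$offsets[design$events])))
  ks <- setNames(ks, design$events)
  attr(ks, "intercept") <- b0
  ks
}

#' Fit per-trial gains with kernel shapes held fixed
#'
#' Least-squares scaling of each event's kernel contribution, one
#' coefficient per trial and event.  Coefficients whose kernel contribution
#' is identically zero on the fitted bins are undefined; they are set to
#' `init` and flagged in the `"undetermined"` attribute.
#'
#' @inheritParams fit_kernels
#' @param kernels Named list of kernel vectors.
#' @param init Value used for undetermined coefficients (the alternating
#'   fit initialises all gains at 1).
#' @return A trials x events gain matrix.
#' @export
fit_gains <- function(design, trace, kernels, rows = NULL, ridge = 0,
                      init = 1) {
  X <- gain_step_X(design, kernels)
  y <- trace
  if (!is.null(rows)) { X <- X[rows, , drop = FALSE]; y <- y[rows] }
  norms <- Matrix::colSums(X^2)
  live <- norms > 0
  beta <- rep(NA_real_, ncol(X))
  if (any(live)) beta[live] <- solve_ls(X[, live, drop = FALSE], y, ridge)
  J <- design$n_trials
  gains <- matrix(beta, nrow = J, ncol = length(design$events),
                  dimnames = list(NULL, design$events))
  undetermined <- which(is.na(gains), arr.ind = TRUE)
  gains[is.na(gains)] <- init
  attr(gains, "undetermined") <- undetermined
  gains
}

#' Predicted trace from kernels and gains
#'
#' @inheritParams fit_gains
#' @param gains Trials x events gain matrix.
#' @return Numeric vector of length `design$n_bins`.
#' @export
predict_trace <- function(design, kernels, gains) {
  pred <- numeric(design$n_bins)
  for (ei in seq_along(design$events)) {
    e <- design$events[ei]
    off <- design$offsets[[e]]
    k <- kernels[[e]]
    b <- design$event_bins[[e]]
    for (jj in which(!is.na(b))) {
      idx <- b[jj] + off
      pred[idx] <- pred[idx] + gains[jj, ei] * k
    }
  }
  pred
}

#' Explained variance of a prediction
#'
#' `1 - SS_res / SS_tot`; negative values indicate a prediction worse than
#' the observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Scalar EV in `(-Inf, 1]`.
#' @export
explained_variance <- function(observed, predicted) {
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

# normalise each kernel to unit Euclidean norm, moving the scale into the
# gains (the model is identified only up to a per-event scale)
normalise_kernels <- function(kernels, gains) {
  for (ei in seq_along(kernels)) {
    nrm <- sqrt(sum(kernels[[ei]]^2))
    if (nrm > 0) {
      kernels[[ei]] <- kernels[[ei]] / nrm
      gains[, ei] <- gains[, ei] * nrm
    }
  }
  list(kernels = kernels, gains = gains)
}

als_fit <- function(design, trace, rows = NULL, n_iter = 5, ridge = 0,
                    intercept = TRUE) {
  J <- design$n_trials
  E <- length(design$events)
  gains <- matrix(1, J, E, dimnames = list(NULL, design$events))
  kernels <- NULL
  b0 <- 0
  train_ev <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    kernels <- fit_kernels(design, trace, gains, rows = rows, ridge = ridge,
                           intercept = intercept)
    b0 <- attr(kernels, "intercept")
    nk <- normalise_kernels(kernels, gains)
    kernels <- nk$kernels
    gains <- fit_gains(design, trace - b0, kernels, rows = rows,
                       ridge = ridge)
    pred <- predict_trace(design, kernels, gains) + b0
    if (is.null(rows)) train_ev[it] <- explained_variance(trace, pred)
    else train_ev[it] <- explained_variance(trace[rows], pred[rows])
  }
  list(kernels = kernels, gains = gains, intercept = b0, train_ev = train_ev)
}

#' Alternating least-squares fit of the trial-gain kernel model
#'
#' The neural trace is modelled as the sum over events of a kernel convolved
#' with that event's indicator train, scaled on each trial by a coefficient.
#' The fit alternates (default 5 iterations) between solving for the kernel
#' shapes with gains fixed and for the gains with kernels fixed, both by
#' linear regression, starting from all gains at 1.  After each kernel step
#' every kernel is renormalised to unit Euclidean norm with the scale moved
#' into its gains, resolving the per-event scale ambiguity.
#'
#' Cross-validation uses contiguous blocks of trials (limiting leakage
#' through overlapping kernel windows): kernels are fitted on 80% of trials
#' and tested on the held-out 20% (5-fold by default), where held-out gains
#' are re-estimated given the trained kernels and the explained variance is
#' computed on held-out bins.
#'
#' @param session A [neural_session()].
#' @param supports Kernel supports (default by modality).
#' @param events Events to include.
#' @param n_iter Alternation iterations.
#' @param k_folds Cross-validation folds (0 skips cross-validation).
#' @param ridge Optional ridge penalty.
#' @param intercept Fit a free baseline term alongside the kernels (default
#'   `TRUE`; z-scored traces have zero mean overall while the event
#'   regressors do not).
#' @return An object of class `kernel_fit` with elements `kernels` (tidy
#'   tibble), `gains` (tibble), `intercept`, `train_ev` (per-iteration
#'   training EV), `cv_ev`, `fold_ev`.
#' @export
fit_event_kernels <- function(session, supports = NULL,
                              events = c("stim", "action", "outcome"),
                              n_iter = 5, k_folds = 5, ridge = 0,
                              intercept = TRUE) {
  design <- build_design(session, supports = supports, events = events)
  if (design$n_trials < 10) abort("need at least 10 trials.")
  trace <- session$trace
  full <- als_fit(design, trace, n_iter = n_iter, ridge = ridge,
                  intercept = intercept)

  fold_ev <- numeric(0)
  if (k_folds > 0) {
    J <- design$n_trials
    fold_of <- ceiling(seq_len(J) / (J / k_folds))
    fold_ev <- purrr::map_dbl(seq_len(k_folds), function(f) {
      test_trials <- which(fold_of == f)
      test_rows <- design$trial_seg %in% test_trials
      train <- als_fit(design, trace, rows = !test_rows, n_iter = n_iter,
                       ridge = ridge, intercept = intercept)
      g_test <- fit_gains(design, trace - train$intercept, train$kernels,
                          rows = test_rows, ridge = ridge)
      pred <- predict_trace(design, train$kernels, g_test) + train$intercept
      explained_variance(trace[test_rows], pred[test_rows])
    })
  }

  kern_tbl <- purrr::map2(design$events, design$offsets[design$events],
                          function(e, off) {
    tibble::tibble(event = e, time = off * design$bin_width,
                   value = full$kernels[[e]])
  }) %>% dplyr::bind_rows()
  gains_tbl <- tibble::as_tibble(full$gains) %>%
    dplyr::mutate(trial = design$trial, .before = 1)

  structure(list(kernels = kern_tbl, gains = gains_tbl,
                 intercept = full$intercept,
                 train_ev = full$train_ev,
                 cv_ev = if (length(fold_ev)) mean(fold_ev) else NA_real_,
                 fold_ev = fold_ev, events = design$events,
                 bin_width = design$bin_width, n_trials = design$n_trials,
                 modality = session$modality), class = "kernel_fit")
}

#' @method print kernel_fit
#' @export
print.kernel_fit <- function(x, ...) {
  cat("<kernel_fit>", paste(x$events, collapse = "+"), "on", x$n_trials,
      "trials;", "train EV =", round(utils::tail(x$train_ev, 1), 3),
      " cv EV =", round(x$cv_ev, 3), "\n")
  invisible(x)
}

#' @export
tidy.kernel_fit <- function(x, ...) x$kernels

#' @export
glance.kernel_fit <- function(x, ...) {
  tibble::tibble(events = paste(x$events, collapse = "+"),
                 train_ev = utils::tail(x$train_ev, 1), cv_ev = x$cv_ev,
                 n_trials = x$n_trials)
}

#' Explained variance of event-reduced kernel models
#'
#' Refits the kernel model with only one event type at a time and with each
#' event type left out, using identical contiguous folds, and tabulates the
#' cross-validated explained variance of every reduction next to the full
#' model.
#'
#' @inheritParams fit_event_kernels
#' @return A tibble with `model`, `events`, `cv_ev`.
#' @export
event_reduction_comparison <- function(session, supports = NULL,
                                       events = c("stim", "action", "outcome"),
                                       n_iter = 5, k_folds = 5, ridge = 0) {
  specs <- c(list(full = events),
             setNames(as.list(events), paste0("only_", events)),
             setNames(purrr::map(events, function(e) setdiff(events, e)),
                      paste0("drop_", events)))
  purrr::imap(specs, function(ev, nm) {
    fit <- fit_event_kernels(session, supports = supports, events = ev,
                             n_iter = n_iter, k_folds = k_folds, ridge = ridge)
    tibble::tibble(model = nm, events = paste(ev, collapse = "+"),
                   cv_ev = fit$cv_ev)
  }) %>% dplyr::bind_rows()
}

#' Relate per-trial gains to a model latent
#'
#' Bins the latent into quantile bins, reports the mean gain per bin, and
#' regresses gain on latent.
#'
#' @param gains Numeric vector of per-trial gains.
#' @param latent Aligned numeric vector (e.g. QC or delta from
#'   [run_agent()]).
#' @param n_bins Number of quantile bins (at least 2).
#' @return An object of class `latent_cor`: `tidy()` gives the binned
#'   means, `glance()` the regression slope, R^2 and p-value.
#' @export
correlate_gains_with_latents <- function(gains, latent, n_bins = 10) {
  if (length(gains) != length(latent))
    abort("`gains` and `latent` must align.")
  if (n_bins < 2) abort("`n_bins` must be at least 2.")
  ok <- is.finite(gains) & is.finite(latent)
  g <- gains[ok]; l <- latent[ok]
  breaks <- unique(quantile(l, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(l, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  bins <- tibble::tibble(bin = bin, latent = l, gain = g) %>%
    dplyr::group_by(.data$bin) %>%
    dplyr::summarise(latent_mean = mean(.data$latent),
                     gain_mean = mean(.data$gain),
                     se = sd(.data$gain) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  fit <- lm(g ~ l)
  sm <- summary(fit)
  structure(list(bins = bins,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(g)), class = "latent_cor")
}

#' @method print latent_cor
#' @export
print.latent_cor <- function(x, ...) {
  cat("<latent_cor> slope =", signif(x$slope, 3), " R^2 =",
      signif(x$r_squared, 3), " p =", format.pval(x$p_value), " n =", x$n,
      "\n")
  invisible(x)
}

#' @export
tidy.latent_cor <- function(x, ...) x$bins

#' @export
glance.latent_cor <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, p_value = x$p_value, n = x$n)
}

#' Ratiometric \eqn{\Delta F/F} from signal and control channels
#'
#' The control (isosbestic 405 nm) channel is regressed onto the
#' calcium-dependent signal channel by least squares; the fractional change
#' is `(signal - fitted control) / fitted control`, z-scored by default.
#'
#' @param signal Calcium-dependent channel.
#' @param control Isosbestic control channel of the same length.
#' @param z_score Return the z-scored trace (default `TRUE`).
#' @return Numeric \eqn{\Delta F/F} trace.
#' @export
photometry_dff <- function(signal, control, z_score = TRUE) {
  if (length(signal) != length(control))
    abort("`signal` and `control` must have the same length.")
  if (sd(control) == 0)
    abort("constant control trace: baseline regression is degenerate.")
  baseline <- fitted(lm(signal ~ control))
  dff <- (signal - baseline) / baseline
  if (z_score) as.numeric(scale(dff)) else dff
}
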