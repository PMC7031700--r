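---
title: "Confidence-weighted reinforcement learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-weighted reinforcement learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented in `beliefrl`, the choices
made where the procedures admit more than one reasonable reading, and what
the synthetic-data checks do and do not establish.

## The task

A head-fixed two-alternative contrast-discrimination task: on each trial a
grating of signed contrast $c \in [-1, 1]$ (negative = left) appears and the
subject reports its side.  Correct reports earn water; in blocks of 50--350
trials (lengths drawn uniformly) one response side earns a larger drop, and
the large-reward side alternates between consecutive blocks.  The small
drop is normalised to one model unit and the large drop is worth $1 + x$,
with $x$ the subjective value of the extra water.  Errors earn nothing.
Zero-contrast trials carry no side information; their rewarded side is
pre-assigned uniformly at random when the trial table is generated, so
adjudication is a pure function of the record.

`sim_block_schedule()` and `sim_trials()` generate this structure.  The
default contrast set is $\{0, 0.125, 0.25, 0.5\}$ (seven signed levels);
the exact per-animal levels in such experiments vary, so the set is a
configurable argument everywhere.  Reaction times in the generator are
log-normal (median 0.35 s, log-SD 0.45), giving the event-time jitter that
the neural regression relies on to separate stimulus- from action-locked
responses.

## The belief-state RL model

On each trial the agent receives a noisy internal percept
$\hat{s} \sim \mathcal{N}(c, \sigma^2)$.  With a flat prior the posterior
over the true contrast is $\mathcal{N}(\hat{s}, \sigma^2)$, so the belief
that the stimulus is on the right is

$$p_R = \Phi\!\left(\hat{s} / \sigma\right), \qquad p_L = 1 - p_R.$$

Beliefs multiply stored action values into expected values
$Q_L = p_L V_L$, $Q_R = p_R V_R$; the agent picks the larger one
deterministically (argmax).  The chosen side's belief is the decision
confidence $p_C$ and its expected value the predicted value $Q_C$.  After
the outcome $r$ the confidence-scaled prediction error
$\delta = r - Q_C$ updates the chosen value only:
$V_C \leftarrow V_C + \alpha\,\delta$.  The pre-stimulus expectation at
trial start is $V_{\text{tone}} = (V_L + V_R)/2$.  There is no temporal
discounting.  A softmax decision rule is available behind a flag, but
argmax is the default and the tested configuration.

Numerical conventions, chosen where the procedure is silent:

* **Tie-breaking.**  Exact ties $Q_L = Q_R$ are resolved by a fair coin
  from the session RNG.  This matters mainly for the $\sigma^2 = 0$ variant
  at zero contrast and preserves left/right symmetry.
* **$\sigma^2 = 0$ at zero contrast.**  The sign of a zero percept is
  undefined; $p_R$ is set to $0.5$.
* **Initial values.**  $V_L = V_R = 1$ (the normalised small reward) at
  session start; values carry over within a session and reset between
  sessions.  Starting at the small-reward value bounds the magnitude of
  early prediction errors sensibly.
* **Subjective payoff during fitting.**  The trial table records which side
  carries the large drop; the simulated agent values that drop at
  $1 + x$ with its *own* $x$, so a fitting model can disagree with the
  generating one about the worth of the extra water.

Optogenetic manipulations enter as additive constants: `q_offset` is added
to $Q_C$ inside the $\delta$ computation on stimulus-time laser trials
(never in the choice itself, because $Q_C$ exists only after the choice),
and `d_offset` is added to $\delta$ on laser-paired outcomes (rewarded
choices to the paired side under block pairing, or any rewarded flagged
trial).  A note on what these do in simulation: a side-paired `d_offset`
is an asymmetric boost that moves the steady-state difference between the
two stored values, so choices shift toward (positive) or away from
(negative) the paired side.  A symmetric `q_offset` leaves ongoing choices
untouched and inflates *both* value fixed points by the same amount
($V^* = (\mathbb{E}[r \mid \text{chosen}] - q)/\mathbb{E}[p_C \mid
\text{chosen}]$), so in long simulations it does not enlarge the
between-block psychometric shift; it mainly increases update variance.
The test suite records this behaviour explicitly.

Error trials at high contrast are informative about the confidence
computation: with equal values, errors happen only when the percept falls
on the wrong side of zero, which at contrast $c$ requires a
$c/\sigma$-sigma excursion.  The chosen-side belief on those trials is
$\Phi(z)$ with $z$ approximately exponential with rate $c/\sigma$, so its
mean is $1/2 + O(\sigma/c)$ -- close to chance, far below the near-one
confidence of correct high-contrast trials, though the finite-noise mean
(about 0.62 at $c = 0.5$, $\sigma^2 = 0.04$) sits measurably above one
half.  The acceptance script reports this quantity by direct simulation.

### Reduced variants

`reduced_variant()` pins one component: $\sigma^2 = 0$ (no sensory noise),
$\sigma^2 = \infty$ (uninformative percept, $p_R \equiv 0.5$, so choices
follow values alone), $x = 0$ (indifference to drop size), $\alpha = 0$
(frozen values).  The $\sigma^2 = \infty$ variant draws no percepts, so it
is deterministic apart from tie-breaks.

## The HMM ideal observer

The alternative model knows the task's block structure and infers the
current block state $S \in \{L, R\}$ from outcomes with a two-state hidden
Markov model: symmetric per-trial switch probability (estimated as
switches/trials from the schedule), and action-conditional emissions over
outcome sizes in which the observer confuses the two drop sizes with
probability $\beta \in [0, 0.5]$ (at $\beta = 0$ the matrix is exact and a
single rewarded trial reveals the block).  The per-trial recursion is:
predict (mix the posterior through the transition matrix), choose by
$Q_a = p_a \sum_s P(S = s)\, r(a, s)$ with random tie-breaks, then correct
the posterior with the emission likelihood of the observed outcome and
renormalise.

Two modelling decisions:

* **No-reward outcomes are uninformative.**  Their probability depends on
  the sensory error, not on the block, so they enter the filter with equal
  likelihood in both states (only transition mixing acts).  The observer
  learns from any rewarded trial, large or small.
* **Action-conditional emissions.**  The emission alphabet is the outcome
  size conditioned on the taken action, implemented as per-action emission
  matrices, matching the conditional form of the confusion probability.
  $\beta$ is capped at 0.5, beyond which the matrix would invert the
  meaning of the blocks.

The posterior resets to $(0.5, 0.5)$ at session start.  Degenerate
observations (zero likelihood under both states, possible only at
$\beta = 0$ with a collapsed posterior and no transition mixing) raise an
error rather than silently renormalising.

`fit_beta()` estimates $\beta$ by exhaustive search using the same
simulation-based likelihood as the RL fit.

## Simulation-based fitting

Because the agent is deterministic given its percepts, the likelihood of a
choice sequence has no closed form; it is estimated by free-running the
agent repeatedly over the fixed stimulus sequence (`n_iter` iterations,
independent percept noise) and taking per-trial choice frequencies
$\hat{P}$.  The fit quality is the mean of $-\log \hat{P}(\text{choice})$
across trials.  Conventions:

* **Probability floor.**  $\hat{P}$ is floored at $1/(n_\text{iter} + 1)$,
  the natural add-one bound for a Monte-Carlo frequency, so the NLL stays
  finite when an observed choice never occurs in simulation.
* **Common random numbers.**  By default every grid point reuses the same
  seed, removing between-point simulation variance from the comparison;
  switchable via `common_rng = FALSE`.
* **Grids.**  The reference grids are
  $\alpha = 0\!:\!0.05\!:\!0.95$, $\sigma^2 = 0.04\!:\!0.04\!:\!0.8$,
  $x = -5\!:\!0.2\!:\!10$ with inclusive endpoints (`default_grid(full =
  TRUE)`, 30,400 points).  The default coarse grid
  ($5 \times 5 \times 6$) is the desk-scale working grid; its interior
  contains the default generating parameters
  ($\alpha = 0.25$, $\sigma^2 = 0.20$, $x = 3$), so exact grid recovery is
  well defined.

`crossval_variants()` splits sessions into $k$ folds (3 by default), fits
every variant on the training sessions and evaluates the fitted parameters
on held-out sessions.  `fit_offset()` searches a one-dimensional grid for a
manipulation constant with the behavioral parameters held fixed.

## Behavioral statistics

**Confidence-history shift.**  Within blocks, rightward-choice curves are
computed conditional on the *preceding* trial being rewarded with a
difficult or easy stimulus on the left or right; the L/R difference,
averaged over current contrast levels, is the shift (in percentage
points).  The same quantity conditioned on the *following* trial is
subtracted: slow side-bias drifts are shared by both neighbours of a trial
and cancel, while a causal influence of the past trial survives.  The
difficulty split is configurable; the default takes "difficult" as zero
plus the lowest nonzero tier and "easy" as the highest tier.  Pairs that
straddle a block switch are dropped.  A delta-method binomial SE
accompanies each shift.  The belief-RL signature (a positive shift after
rewarded difficult trials, none after easy ones) requires the easy
stimulus to be nearly unambiguous; the packaged checks therefore simulate
this analysis at $\sigma^2 = 0.04$, where confidence at the top contrast
is $\approx 0.99$ -- the regime of a well-trained animal.

**Learning curves** are causal moving averages (default window 10 trials)
of the rightward indicator aligned to block switches; a causal window
avoids leaking post-switch information backward.

**Psychometric fits** use a maximum-likelihood lapse sigmoid
$P(R) = \lambda_L + (1 - \lambda_L - \lambda_R) F(\beta (c - \mu))$ with a
cumulative-Gaussian $F$ by default (logistic optional), lapses bounded in
$[0, 0.5]$, and explicit flags for non-identifiable (one-sided) data and
slopes at the optimiser bound.

**Outcome-response splits** divide rewarded trials at a percentile
(default 65) of a per-trial neural response and compare the next-trial
shift toward the rewarded side between the high and low groups,
stratifying by previous stimulus tier and block reward side.

## Trial-gain event-kernel regression

A binned neural trace is modelled as
$R_j(t) = S_j K_s * X^s_j + A_j K_a * X^a_j + O_j K_o * X^o_j$:
per-event kernels convolved with unit impulses at the event times, scaled
per trial by coefficients.  Fitting alternates (5 iterations) between two
exact linear-regression steps -- kernels given gains, then gains given
kernels -- starting from all gains at 1.  Default supports: spikes
(20 ms bins) stimulus $[0, 0.6]$, action $[-0.4, 0.2]$, outcome
$[0, 0.6]$ s; photometry (50 ms bins) $[0, 2]$, $[-1, 0.2]$, $[0, 3]$ s.

Numerical choices:

* **Scale ambiguity.**  The model is invariant under kernel
  $\times c$ / gains $\div c$; after each kernel step every kernel is
  renormalised to unit Euclidean norm with the scale moved into its gains.
  Kernel--gain *products* are the identified quantities.
* **Baseline term.**  Traces are z-scored per session (mean zero overall),
  but the event regressors have nonzero mean, so a free intercept is
  fitted alongside the kernels (default on).  Without it a noiseless
  z-scored session could not reach explained variance one.
* **Event snapping.**  Event times snap to the nearest bin; exact half-bin
  ties round toward the earlier bin.  Events whose kernel window leaves
  the trace are excluded with a warning.
* **Cross-validation.**  Folds are contiguous blocks of trials (bins are
  assigned to the trial with the nearest event), limiting leakage through
  overlapping kernel windows; kernels are fitted on 80% of trials, gains on
  the held-out trials are re-estimated given those kernels, and explained
  variance is computed on held-out bins.  Training EV is non-decreasing
  across iterations because each step is an exact least-squares solve.
* **Degeneracy.**  Rank-deficient designs fall back to the minimum-norm
  solution with a warning; a small ridge is available behind a flag.
  Gains whose kernel contribution is identically zero on the fitted bins
  are set to the initialisation value and flagged.

Both steps operate on the continuous concatenated trace, so responses that
bleed across neighbouring trials are handled by the linear model itself
rather than by windowing.

`photometry_dff()` implements the ratiometric preprocessing: the
isosbestic control channel is regressed onto the signal channel by least
squares and the trace is $(signal - fit)/fit$, z-scored.

## Synthetic data and what the checks mean

`sim_behavior_dataset()` produces multi-session datasets from known agent
parameters; `sim_spike_session()` draws inhomogeneous Poisson counts
(20 ms bins) around a base rate of 20 Hz with event responses scaled by
per-trial gain rules (default: an action response $3 + 5\,Q_C$, in
z-score-scale units per unit-norm kernel, emulating strong value coupling
of frontal action responses); `sim_photometry_session()` adds white
Gaussian noise to slow gamma-shaped transients (roughly 1 s decay, a
GCaMP-like stand-in) whose stimulus gains follow $Q_C$ and outcome gains
follow $\delta$.  Poisson intensities are floored at zero after summation
-- a documented deviation from pure linearity.  Every artifact is exactly
regenerable from its seed.

Problem sizes used by the packaged checks: behavioral parameter recovery
uses 10 sessions of 500 trials with `n_iter = 200` on the coarse grid;
model comparison uses 9 sessions with 3-fold cross-validation at
`n_iter = 100`; history analyses use equal-reward simulations of 80,000
trials; kernel-regression recovery uses single sessions of 150--400 trials
and a 50-neuron Monte-Carlo at the default modulation.  These sizes give
the reported statistics comfortable standard errors while keeping a full
run of the suite within a coffee break.

What passing these checks does **not** show: the generators emulate the
*structure* of real data, not its nuisance processes.  There is no
satiety or engagement drift, no lapse process, no motion or bleaching
artifact in the photometry channel (the control-channel regression is
exercised on constructed traces), no spike-sorting contamination, and the
percept-noise model is exactly the one the fitted agent assumes, so
recovery results bound estimation error under a well-specified model only.
Real sessions can and do violate each of these assumptions.

## Known limitations

* The simulation-based likelihood is biased for very small `n_iter`
  because of the probability floor; comparisons should hold `n_iter` fixed
  across variants (the cross-validation function does).
* The observer's switch probability is taken from the schedule, not
  learned online; semi-Markov block durations (the truncated-uniform
  lengths) are approximated by a geometric hazard.
* With heavily overlapping events and little event-time jitter, kernel
  attribution between stimulus and action regressors is partly
  ill-conditioned; the event-reduction table makes this visible rather
  than hiding it.
* Values reset at session boundaries; if an experiment's subjects carry
  value estimates across days, the fitted $\alpha$ will partially absorb
  that carry-over.
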