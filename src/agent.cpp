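#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Belief that the stimulus is on the right given a percept and the sensory
// noise variance.  sigma2 == 0 collapses to the sign of the percept (0.5 at
// zero); infinite sigma2 is fully uninformative.
static inline double belief_R(double s_hat, double sigma2) {
  if (!R_finite(sigma2)) return 0.5;
  if (sigma2 == 0.0) return s_hat > 0 ? 1.0 : (s_hat < 0 ? 0.0 : 0.5);
  return R::pnorm(s_hat / std::sqrt(sigma2), 0.0, 1.0, 1, 0);
}

// One percept draw.  No RNG is consumed when sigma2 is 0 or infinite, which
// the pure-R reference implementation in the test suite relies on.
static inline double draw_percept(double contrast, double sigma2) {
  if (!R_finite(sigma2) || sigma2 == 0.0) return contrast;
  return contrast + std::sqrt(sigma2) * norm_rand();
}

// Argmax over expected values; exact ties resolved by a fair coin from the
// session RNG.  Returns 1 for R, 0 for L.
static inline int pick_action(double qL, double qR, bool softmax, double temp) {
  if (softmax) {
    double pR = 1.0 / (1.0 + std::exp((qL - qR) / temp));
    return unif_rand() < pR ? 1 : 0;
  }
  if (qR > qL) return 1;
  if (qL > qR) return 0;
  return unif_rand() < 0.5 ? 1 : 0;
}

// Subjective value of the delivered reward: the small drop is normalised to
// 1, the large drop is worth 1 + x.  Which side is "large" is read off the
// trial's reward contingencies so that fitting can use its own x.
static inline double subjective_reward(bool correct, double r_choice,
                                       double r_other, double x) {
  if (!correct) return 0.0;
  return (r_choice > r_other) ? 1.0 + x : 1.0;
}

// [[Rcpp::export]]
List cpp_run_agent(NumericVector contrast, IntegerVector side,
                   NumericVector rL, NumericVector rR, IntegerVector session,
                   LogicalVector laser_stim, IntegerVector laser_out_side,
                   LogicalVector laser_out_trial, double alpha, double sigma2,
                   double x, double q_offset, double d_offset, double v_init,
                   bool softmax, double temp) {
  const int n = contrast.size();
  NumericVector s_hat(n), p_l(n), p_r(n), q_l(n), q_r(n), p_c(n), q_c(n),
      v_tone(n), delta(n), v_l(n), v_r(n), reward(n);
  IntegerVector choice(n);
  LogicalVector correct(n), laser_fired(n);

  double VL = v_init, VR = v_init;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && session[i] != session[i - 1]) { VL = v_init; VR = v_init; }
    v_l[i] = VL; v_r[i] = VR;
    v_tone[i] = 0.5 * (VL + VR);

    s_hat[i] = draw_percept(contrast[i], sigma2);
    double pR = belief_R(s_hat[i], sigma2), pL = 1.0 - pR;
    p_l[i] = pL; p_r[i] = pR;

    double qL = pL * VL, qR = pR * VR;
    q_l[i] = qL; q_r[i] = qR;
    int ch = pick_action(qL, qR, softmax, temp);
    choice[i] = ch;
    p_c[i] = ch == 1 ? pR : pL;
    q_c[i] = ch == 1 ? qR : qL;

    bool corr = (ch == 1) == (side[i] == 1);
    correct[i] = corr;
    double r_choice = ch == 1 ? rR[i] : rL[i];
    double r_other = ch == 1 ? rL[i] : rR[i];
    reward[i] = corr ? r_choice : 0.0;
    double r_subj = subjective_reward(corr, r_choice, r_other, x);

    // laser at the outcome pairs with rewarded choices to the flagged side
    // (block plans) or with any rewarded choice on flagged trials
    bool paired = corr && ((laser_out_side[i] >= 0 && laser_out_side[i] == ch) ||
                           laser_out_trial[i]);
    laser_fired[i] = paired || laser_stim[i];

    double qc_eff = q_c[i] + (laser_stim[i] ? q_offset : 0.0);
    double d = r_subj - qc_eff + (paired ? d_offset : 0.0);
    delta[i] = d;
    if (ch == 1) VR += alpha * d; else VL += alpha * d;
  }
  return List::create(
      _["s_hat"] = s_hat, _["p_l"] = p_l, _["p_r"] = p_r, _["q_l"] = q_l,
      _["q_r"] = q_r, _["choice"] = choice, _["p_c"] = p_c, _["q_c"] = q_c,
      _["v_tone"] = v_tone, _["delta"] = delta, _["v_l"] = v_l,
      _["v_r"] = v_r, _["correct"] = correct, _["reward"] = reward,
      _["laser_fired"] = laser_fired);
}

// Monte-Carlo choice probabilities: the agent free-runs n_iter times over the
// fixed stimulus sequence with independent noise; returns the fraction of
// iterations choosing R on each trial.
// [[Rcpp::export]]
NumericVector cpp_choice_probs(NumericVector contrast, IntegerVector side,
                               NumericVector rL, NumericVector rR,
                               IntegerVector session, LogicalVector laser_stim,
                               IntegerVector laser_out_side,
                               LogicalVector laser_out_trial, double alpha,
                               double sigma2, double x, double q_offset,
                               double d_offset, double v_init, bool softmax,
                               double temp, int n_iter) {
  const int n = contrast.size();
  std::vector<int> count_R(n, 0);
  for (int it = 0; it < n_iter; ++it) {
    double VL = v_init, VR = v_init;
    for (int i = 0; i < n; ++i) {
      if (i > 0 && session[i] != session[i - 1]) { VL = v_init; VR = v_init; }
      double sh = draw_percept(contrast[i], sigma2);
      double pR = belief_R(sh, sigma2), pL = 1.0 - pR;
      double qL = pL * VL, qR = pR * VR;
      int ch = pick_action(qL, qR, softmax, temp);
      if (ch == 1) count_R[i]++;

      bool corr = (ch == 1) == (side[i] == 1);
      double r_choice = ch == 1 ? rR[i] : rL[i];
      double r_other = ch == 1 ? rL[i] : rR[i];
      double r_subj = subjective_reward(corr, r_choice, r_other, x);
      bool paired = corr && ((laser_out_side[i] >= 0 && laser_out_side[i] == ch) ||
                             laser_out_trial[i]);
      double qc = (ch == 1 ? qR : qL) + (laser_stim[i] ? q_offset : 0.0);
      double d = r_subj - qc + (paired ? d_offset : 0.0);
      if (ch == 1) VR += alpha * d; else VL += alpha * d;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (double)count_R[i] / n_iter;
  return out;
}

// ---- HMM ideal observer ----------------------------------------------------

// Action-conditional emission likelihood of the observed outcome size under
// each block state.  symbol: 0 = no reward, 1 = small, 2 = large.  No-reward
// outcomes are state-uninformative (their probability depends on the sensory
// error, not on the block).
static inline void emission_lik(int symbol, int action, double beta,
                                double &lik_L, double &lik_R) {
  if (symbol == 0) { lik_L = 1.0; lik_R = 1.0; return; }
  // In the L block the left action carries the large drop.
  bool a_large_in_L = (action == 0), a_large_in_R = (action == 1);
  if (symbol == 2) {
    lik_L = a_large_in_L ? 1.0 - beta : beta;
    lik_R = a_large_in_R ? 1.0 - beta : beta;
  } else {
    lik_L = a_large_in_L ? beta : 1.0 - beta;
    lik_R = a_large_in_R ? beta : 1.0 - beta;
  }
}

struct ObsState { double postL; };

// One observer step shared by the latent-recording and probability runs.
static inline int observer_trial(double contrast, int side, double rLt,
                                 double rRt, double sigma2, double p_switch,
                                 double beta, double r_small, double r_large,
                                 double &postL, double *rec, bool &corr_out,
                                 double &reward_out) {
  // transition mixing: the block may have switched since the last trial
  postL = postL * (1.0 - p_switch) + (1.0 - postL) * p_switch;
  double postR = 1.0 - postL;

  double sh = draw_percept(contrast, sigma2);
  double pR = belief_R(sh, sigma2), pL = 1.0 - pR;
  // r(a, s): large-on-left block pays r_large for L, r_small for R
  double qL = pL * (postL * r_large + postR * r_small);
  double qR = pR * (postL * r_small + postR * r_large);
  int ch = pick_action(qL, qR, false, 0.0);

  bool corr = (ch == 1) == (side == 1);
  double r_choice = ch == 1 ? rRt : rLt;
  double r_other = ch == 1 ? rLt : rRt;
  double rew = corr ? r_choice : 0.0;
  int symbol = 0;
  if (rew > 0) {
    if (std::abs(r_large - r_small) < 1e-12) symbol = 0;  // sizes equal: uninformative
    else symbol = (r_choice > r_other) ? 2 : 1;
  }
  double lik_L, lik_R;
  emission_lik(symbol, ch, beta, lik_L, lik_R);
  double numL = postL * lik_L, numR = postR * lik_R, tot = numL + numR;
  if (tot <= 0.0)
    stop("degenerate observation: outcome has zero likelihood under both block states");
  postL = numL / tot;

  if (rec) {
    rec[0] = sh; rec[1] = pL; rec[2] = pR; rec[3] = qL; rec[4] = qR;
    rec[5] = ch == 1 ? pR : pL;
  }
  corr_out = corr; reward_out = rew;
  return ch;
}

// [[Rcpp::export]]
List cpp_run_observer(NumericVector contrast, IntegerVector side,
                      NumericVector rL, NumericVector rR, IntegerVector session,
                      double sigma2, double p_switch, double beta,
                      double r_small, double r_large) {
  const int n = contrast.size();
  NumericVector s_hat(n), p_l(n), p_r(n), q_l(n), q_r(n), p_c(n), post_l(n),
      post_r(n), reward(n);
  IntegerVector choice(n);
  LogicalVector correct(n);

  double postL = 0.5;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && session[i] != session[i - 1]) postL = 0.5;
    // record the posterior used at decision time (after transition mixing)
    double mixed = postL * (1.0 - p_switch) + (1.0 - postL) * p_switch;
    double rec[7]; bool corr; double rew;
    int ch = observer_trial(contrast[i], side[i], rL[i], rR[i], sigma2,
                            p_switch, beta, r_small, r_large, postL, rec,
                            corr, rew);
    s_hat[i] = rec[0]; p_l[i] = rec[1]; p_r[i] = rec[2];
    q_l[i] = rec[3]; q_r[i] = rec[4]; p_c[i] = rec[5];
    post_l[i] = mixed; post_r[i] = 1.0 - mixed;
    choice[i] = ch; correct[i] = corr; reward[i] = rew;
  }
  return List::create(
      _["s_hat"] = s_hat, _["p_l"] = p_l, _["p_r"] = p_r, _["q_l"] = q_l,
      _["q_r"] = q_r, _["choice"] = choice, _["p_c"] = p_c,
      _["post_l"] = post_l, _["post_r"] = post_r, _["correct"] = correct,
      _["reward"] = reward);
}

// [[Rcpp::export]]
NumericVector cpp_observer_probs(NumericVector contrast, IntegerVector side,
                                 NumericVector rL, NumericVector rR,
                                 IntegerVector session, double sigma2,
                                 double p_switch, double beta, double r_small,
                                 double r_large, int n_iter) {
  const int n = contrast.size();
  std::vector<int> count_R(n, 0);
  for (int it = 0; it < n_iter; ++it) {
    double postL = 0.5;
    for (int i = 0; i < n; ++i) {
      if (i > 0 && session[i] != session[i - 1]) postL = 0.5;
      bool corr; double rew;
      int ch = observer_trial(contrast[i], side[i], rL[i], rR[i], sigma2,
                              p_switch, beta, r_small, r_large, postL, nullptr,
                              corr, rew);
      if (ch == 1) count_R[i]++;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (double)count_R[i] / n_iter;
  return out;
}
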