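#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hybrid model-free / model-based agent for the two-stage, one-decision task.
//
// One state recursion serves both simulation and likelihood replay, so the
// likelihood is by construction the exact probability model of the simulator.
//
// Indexing conventions (all 0-based internally):
//   set     0 = the set whose true transition structure is predictable,
//           1 = the truly random set.  The agent never sees these labels;
//           its beliefs come exclusively from the transition counters.
//   action  0/1 (stage-1 stimuli of the presented set)
//   picture 0/1 (stage-2 stimuli of the presented set)
//
// Parameters per set: alpha, lambda, beta, omega, rho. In the shared-parameter
// case both sets receive the same vector.

struct HybridState {
  double q1[2][2];   // set x action,  Q_MF|S1
  double q2[2][2];   // set x picture, Q_MF|S2
  double cnt[2][2][2]; // set x action x picture transition counters
  int    last[2];    // last chosen action per set, -1 = none

  void reset() {
    for (int s = 0; s < 2; ++s) {
      last[s] = -1;
      for (int i = 0; i < 2; ++i) {
        q1[s][i] = 0.0;
        q2[s][i] = 0.0;
        for (int j = 0; j < 2; ++j) cnt[s][i][j] = 0.0;
      }
    }
  }
};

// Counter-based internal model: per set,
//   d = (n[a0->p0] + n[a1->p1]) - (n[a0->p1] + n[a1->p0]);
// the set with larger |d| is tagged predictable and gets 0.75/0.25 beliefs
// oriented by sign(d); the other (and both on ties, and on sign(d)==0) get
// 0.5/0.5.  Returns the inferred predictable set (-1 on tie).
static int transition_beliefs(const HybridState& st, double P[2][2][2]) {
  double d[2];
  for (int s = 0; s < 2; ++s)
    d[s] = (st.cnt[s][0][0] + st.cnt[s][1][1]) -
           (st.cnt[s][0][1] + st.cnt[s][1][0]);
  for (int s = 0; s < 2; ++s)
    for (int a = 0; a < 2; ++a)
      for (int p = 0; p < 2; ++p) P[s][a][p] = 0.5;
  int pred = -1;
  if (std::abs(d[0]) > std::abs(d[1])) pred = 0;
  else if (std::abs(d[1]) > std::abs(d[0])) pred = 1;
  if (pred >= 0 && d[pred] != 0.0) {
    double hi = 0.75, lo = 0.25;
    if (d[pred] > 0) { // more a0->p0 and a1->p1 transitions
      P[pred][0][0] = hi; P[pred][0][1] = lo;
      P[pred][1][1] = hi; P[pred][1][0] = lo;
    } else {
      P[pred][0][0] = lo; P[pred][0][1] = hi;
      P[pred][1][1] = lo; P[pred][1][0] = hi;
    }
  }
  return pred;
}

// Overflow-safe softmax over two actions: z[a] = beta*qnet[a] + rho*rep(a).
static void softmax2(const double qnet[2], int last, double beta, double rho,
                     double pr[2]) {
  double z[2];
  for (int a = 0; a < 2; ++a)
    z[a] = beta * qnet[a] + rho * (last == a ? 1.0 : 0.0);
  double m = std::max(z[0], z[1]);
  double e0 = std::exp(z[0] - m), e1 = std::exp(z[1] - m);
  pr[0] = e0 / (e0 + e1);
  pr[1] = e1 / (e0 + e1);
}

// Core driver.
//
// mode = 0: replay observed (action, picture, reward) sequences; emits the
//           per-trial probability of the observed stage-1 action.
// mode = 1: simulate; samples action from the softmax, picture from the true
//           transition structure and reward from the reward structure, using
//           R's RNG stream.
//
// block, set: per-trial indices (0-based); state resets when block changes.
// common_map[b]: picture commonly following action 0 of the predictable set
//                in block b (action 1 commonly leads to the other picture).
// hr_pic[b][s] (passed flattened): high-reward picture of set s in block b.
// [[Rcpp::export]]
List cpp_hybrid_run(IntegerVector block, IntegerVector set,
                    IntegerVector action, IntegerVector picture,
                    NumericVector reward,
                    NumericVector par_set0, NumericVector par_set1,
                    int mode,
                    IntegerVector common_map,
                    IntegerVector hr_pic0, IntegerVector hr_pic1,
                    double p_common, double p_reward_high) {
  int n = block.size();
  HybridState st;
  st.reset();

  IntegerVector out_action(n), out_picture(n), out_transition(n);
  NumericVector out_reward(n), p_choice(n), logp(n), rpe(n);
  NumericVector qnetA(n), qnetB(n);
  IntegerVector inferred_pred(n);

  int cur_block = -1;
  double P[2][2][2];

  for (int t = 0; t < n; ++t) {
    int b = block[t];
    if (b != cur_block) { st.reset(); cur_block = b; }
    int s = set[t];
    const double* par = (s == 0) ? &par_set0[0] : &par_set1[0];
    double alpha = par[0], lam = par[1], beta = par[2], omega = par[3],
           rho = par[4];

    inferred_pred[t] = transition_beliefs(st, P);

    double qnet[2];
    for (int a = 0; a < 2; ++a) {
      double qmb = P[s][a][0] * st.q2[s][0] + P[s][a][1] * st.q2[s][1];
      qnet[a] = omega * qmb + (1.0 - omega) * st.q1[s][a];
    }
    qnetA[t] = qnet[0];
    qnetB[t] = qnet[1];

    double pr[2];
    softmax2(qnet, st.last[s], beta, rho, pr);

    int a_t, p_t;
    double r_t;
    if (mode == 1) {
      a_t = (R::unif_rand() < pr[0]) ? 0 : 1;
      if (s == 0) { // predictable structure
        int common_pic = (a_t == 0) ? common_map[b] : 1 - common_map[b];
        bool common = R::unif_rand() < p_common;
        p_t = common ? common_pic : 1 - common_pic;
        out_transition[t] = common ? 0 : 1; // 0 common, 1 rare
      } else {
        p_t = (R::unif_rand() < 0.5) ? 0 : 1;
        out_transition[t] = NA_INTEGER; // undefined
      }
      int hr = (s == 0) ? hr_pic0[b] : hr_pic1[b];
      bool win;
      if (p_t == hr) win = R::unif_rand() < p_reward_high;
      else           win = R::unif_rand() >= p_reward_high;
      r_t = win ? 1.0 : -1.0;
    } else {
      a_t = action[t];
      p_t = picture[t];
      r_t = reward[t];
      out_transition[t] = NA_INTEGER;
    }
    out_action[t] = a_t;
    out_picture[t] = p_t;
    out_reward[t] = r_t;

    double eps = 1e-12; // underflow guard for the log-likelihood
    p_choice[t] = pr[a_t];
    logp[t] = std::log(std::max(pr[a_t], eps));

    // Model-free updates.  Both deltas reference the pre-update Q_MF|S2.
    double q2_old = st.q2[s][p_t];
    rpe[t] = r_t - q2_old;
    st.q1[s][a_t] += alpha * (q2_old - st.q1[s][a_t]) + alpha * lam * rpe[t];
    st.q2[s][p_t] += alpha * rpe[t];

    // Forgetting: every q entry of both sets except the chosen action and
    // presented picture decays by (1 - alpha).
    for (int ss = 0; ss < 2; ++ss)
      for (int i = 0; i < 2; ++i) {
        if (!(ss == s && i == a_t)) st.q1[ss][i] *= (1.0 - alpha);
        if (!(ss == s && i == p_t)) st.q2[ss][i] *= (1.0 - alpha);
      }

    st.cnt[s][a_t][p_t] += 1.0;
    st.last[s] = a_t;
  }

  return List::create(
      _["action"] = out_action, _["picture"] = out_picture,
      _["transition"] = out_transition, _["reward"] = out_reward,
      _["p_choice"] = p_choice, _["logp"] = logp, _["rpe"] = rpe,
      _["qnet_A"] = qnetA, _["qnet_B"] = qnetB,
      _["inferred_pred_set"] = inferred_pred);
}

// Zero-phase IIR filtering of each matrix column: one forward and one
// backward pass with zero initial conditions (epochs are baseline-corrected
// and taper to small values at the edges, so startup transients are benign).
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_cols(NumericMatrix x, NumericVector b,
                                NumericVector a) {
  int n = x.nrow(), m = x.ncol();
  int nb = b.size(), na = a.size();
  NumericMatrix out(n, m);
  std::vector<double> tmp(n);
  for (int j = 0; j < m; ++j) {
    // forward
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int k = 0; k < nb; ++k)
        if (i - k >= 0) acc += b[k] * x(i - k, j);
      for (int k = 1; k < na; ++k)
        if (i - k >= 0) acc -= a[k] * tmp[i - k];
      tmp[i] = acc / a[0];
    }
    // backward
    std::vector<double> rev(n);
    for (int i = n - 1; i >= 0; --i) {
      double acc = 0.0;
      for (int k = 0; k < nb; ++k)
        if (i + k < n) acc += b[k] * tmp[i + k];
      for (int k = 1; k < na; ++k)
        if (i + k < n) acc -= a[k] * rev[i + k];
      rev[i] = acc / a[0];
    }
    for (int i = 0; i < n; ++i) out(i, j) = rev[i];
  }
  return out;
}

// Pink (1/f) background noise, samples x trials, via a cascade of
// first-order filters driven by Gaussian white noise (Kellet's refined
// coefficients, giving power ~ 1/f across the usable band). Output is
// calibrated to unit RMS and scaled by `amp`; uses R's RNG stream.
// [[Rcpp::export]]
NumericMatrix cpp_pink_noise(int n, int trials, double amp) {
  NumericMatrix out(n, trials);
  if (amp == 0.0 || trials == 0) return out;
  const double rms = 3.0451; // stationary RMS of the unit-gain cascade
  for (int j = 0; j < trials; ++j) {
    double b0 = 0, b1 = 0, b2 = 0, b3 = 0, b4 = 0, b5 = 0, b6 = 0;
    for (int i = -200; i < n; ++i) { // 200-sample warm-up to stationarity
      double w = R::norm_rand();
      b0 = 0.99886 * b0 + w * 0.0555179;
      b1 = 0.99332 * b1 + w * 0.0750759;
      b2 = 0.96900 * b2 + w * 0.1538520;
      b3 = 0.86650 * b3 + w * 0.3104856;
      b4 = 0.55000 * b4 + w * 0.5329522;
      b5 = -0.7616 * b5 - w * 0.0168980;
      double x = b0 + b1 + b2 + b3 + b4 + b5 + b6 + w * 0.5362;
      b6 = w * 0.115926;
      if (i >= 0) out(i, j) = x * amp / rms;
    }
  }
  return out;
}

// Peak-to-peak FRN over matrix columns (samples x trials). Mirrors the
// scalar R implementation frn_peak_to_peak(): most negative local minimum
// in the search window (fallback: window minimum), flank maxima in 100 ms
// windows widened outward in 10 ms steps up to 300 ms when the maximum sits
// on the outer edge.
// [[Rcpp::export]]
List cpp_frn_cols(NumericMatrix x, NumericVector times,
                  double search_lo, double search_hi) {
  int n = x.nrow(), m = x.ncol();
  NumericVector p2p(m), t_frn(m);
  LogicalVector fallback(m);

  std::vector<int> win;
  for (int i = 0; i < n; ++i)
    if (times[i] >= search_lo && times[i] <= search_hi) win.push_back(i);

  for (int j = 0; j < m; ++j) {
    // FRN peak: earliest most-negative local minimum
    int i_frn = -1;
    double best = R_PosInf;
    for (size_t k = 0; k < win.size(); ++k) {
      int i = win[k];
      if (i > 0 && i < n - 1 && x(i, j) <= x(i - 1, j) &&
          x(i, j) <= x(i + 1, j) &&
          (x(i, j) < x(i - 1, j) || x(i, j) < x(i + 1, j)) &&
          x(i, j) < best) {
        best = x(i, j);
        i_frn = i;
      }
    }
    bool fb = (i_frn < 0);
    if (fb) {
      for (size_t k = 0; k < win.size(); ++k)
        if (x(win[k], j) < best) { best = x(win[k], j); i_frn = win[k]; }
    }
    double tf = times[i_frn];

    double flank[2];
    for (int d = 0; d < 2; ++d) { // 0 = preceding, 1 = succeeding
      double width = 0.1;
      int i_max = -1;
      while (true) {
        double lo = d == 0 ? tf - width : tf;
        double hi = d == 0 ? tf : tf + width;
        i_max = -1;
        double bmax = R_NegInf;
        int first = -1, last = -1;
        for (int i = 0; i < n; ++i) {
          if (times[i] >= lo && times[i] <= hi) {
            if (first < 0) first = i;
            last = i;
            if (x(i, j) > bmax) { bmax = x(i, j); i_max = i; }
          }
        }
        int outer = d == 0 ? first : last;
        if (i_max != outer || width >= 0.3) break;
        width += 0.01;
      }
      flank[d] = x(i_max, j);
    }
    p2p[j] = x(i_frn, j) - 0.5 * (flank[0] + flank[1]);
    t_frn[j] = tf;
    fallback[j] = fb;
  }
  return List::create(_["p2p"] = p2p, _["t_frn"] = t_frn,
                      _["fallback"] = fallback);
}
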