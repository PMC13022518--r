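#include <Rcpp.h>
using namespace Rcpp;

// Two-option softmax written as a logistic; argument clipped at +/-700 so
// exp() never overflows, probabilities floored at 1e-12 inside logs.
static inline double logistic_choice(double q_diff, double beta) {
  double z = beta * q_diff;
  if (z > 700.0) z = 700.0;
  if (z < -700.0) z = -700.0;
  return 1.0 / (1.0 + std::exp(-z));
}

// Replay a chronologically ordered condition stream under fixed parameters
// and return the negative log-likelihood plus per-trial signed prediction
// errors and choice probabilities.
//
// pair:        0-based pair index per trial (indexes q0_good / q0_bad)
// chosen_good: 1 if the "good" option was chosen, 0 otherwise
// outcome:     r in {-1, 0, +1}
// group:       0-based parameter-group index per trial (context variants);
//              alpha_pos/alpha_neg/beta have one entry per group
// rho:         outcome-sensitivity scalar (1 = base model)
// [[Rcpp::export]]
List cpp_replay(IntegerVector pair, IntegerVector chosen_good,
                NumericVector outcome, IntegerVector group,
                NumericVector q0_good, NumericVector q0_bad,
                NumericVector alpha_pos, NumericVector alpha_neg,
                NumericVector beta, double rho) {
  int n = pair.size();
  int npair = q0_good.size();
  std::vector<double> qg(q0_good.begin(), q0_good.end());
  std::vector<double> qb(q0_bad.begin(), q0_bad.end());
  NumericVector pe(n), p_chosen(n), q_chosen_pre(n);
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    int p = pair[t];
    if (p < 0 || p >= npair) stop("pair index out of range");
    int g = group[t];
    double qgv = qg[p], qbv = qb[p];
    double pc;
    if (chosen_good[t] == 1) {
      pc = logistic_choice(qgv - qbv, beta[g]);
    } else {
      pc = logistic_choice(qbv - qgv, beta[g]);
    }
    p_chosen[t] = pc;
    if (pc < 1e-12) pc = 1e-12;
    nll -= std::log(pc);
    double qc = (chosen_good[t] == 1) ? qgv : qbv;
    q_chosen_pre[t] = qc;
    double delta = rho * outcome[t] - qc;
    pe[t] = delta;
    double a = (delta > 0) ? alpha_pos[g] : ((delta < 0) ? alpha_neg[g] : 0.0);
    double qn = qc + a * delta;
    if (chosen_good[t] == 1) qg[p] = qn; else qb[p] = qn;
  }
  return List::create(_["nll"] = nll, _["pe"] = pe,
                      _["p_chosen"] = p_chosen, _["q_chosen"] = q_chosen_pre);
}

// Simulate one agent over a full schedule. Uses R's RNG (respects set.seed).
//
// valence:  1 for reward pairs, 0 for punishment pairs (per trial)
// p_good:   probability that the "good" option's salient outcome occurs
//           (win for reward pairs; for punishment pairs the good option's
//           loss probability is 1 - p_good)
// miss_rate: probability a trial times out (no choice, no update)
// [[Rcpp::export]]
List cpp_simulate(IntegerVector pair, IntegerVector valence,
                  NumericVector p_good,
                  NumericVector q0_good, NumericVector q0_bad,
                  double alpha_pos, double alpha_neg, double beta,
                  double rho, double miss_rate) {
  int n = pair.size();
  std::vector<double> qg(q0_good.begin(), q0_good.end());
  std::vector<double> qb(q0_bad.begin(), q0_bad.end());
  IntegerVector chosen_good(n), valid(n);
  NumericVector outcome(n);
  RNGScope scope;
  for (int t = 0; t < n; ++t) {
    int p = pair[t];
    if (miss_rate > 0.0 && unif_rand() < miss_rate) {
      valid[t] = 0;
      chosen_good[t] = NA_INTEGER;
      outcome[t] = NA_REAL;
      continue;
    }
    valid[t] = 1;
    double pg = logistic_choice(qg[p] - qb[p], beta);
    int cg = (unif_rand() < pg) ? 1 : 0;
    chosen_good[t] = cg;
    double u = unif_rand();
    double r;
    if (valence[t] == 1) {              // reward pair: win or nothing
      double pw = cg ? p_good[t] : (1.0 - p_good[t]);
      r = (u < pw) ? 1.0 : 0.0;
    } else {                            // punishment pair: loss or nothing
      double pl = cg ? (1.0 - p_good[t]) : p_good[t];
      r = (u < pl) ? -1.0 : 0.0;
    }
    outcome[t] = r;
    double qc = cg ? qg[p] : qb[p];
    double delta = rho * r - qc;
    double a = (delta > 0) ? alpha_pos : ((delta < 0) ? alpha_neg : 0.0);
    double qn = qc + a * delta;
    if (cg) qg[p] = qn; else qb[p] = qn;
  }
  return List::create(_["chosen_good"] = chosen_good,
                      _["outcome"] = outcome, _["valid"] = valid);
}

// Likelihood-only variant of cpp_replay: no per-trial outputs, used inside
// optimization loops.
// [[Rcpp::export]]
double cpp_nll(IntegerVector pair, IntegerVector chosen_good,
               NumericVector outcome, IntegerVector group,
               NumericVector q0_good, NumericVector q0_bad,
               NumericVector alpha_pos, NumericVector alpha_neg,
               NumericVector beta, double rho) {
  int n = pair.size();
  std::vector<double> qg(q0_good.begin(), q0_good.end());
  std::vector<double> qb(q0_bad.begin(), q0_bad.end());
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    int p = pair[t];
    int g = group[t];
    double qgv = qg[p], qbv = qb[p];
    double pc = (chosen_good[t] == 1)
      ? logistic_choice(qgv - qbv, beta[g])
      : logistic_choice(qbv - qgv, beta[g]);
    if (pc < 1e-12) pc = 1e-12;
    nll -= std::log(pc);
    double qc = (chosen_good[t] == 1) ? qgv : qbv;
    double delta = rho * outcome[t] - qc;
    double a = (delta > 0) ? alpha_pos[g] : ((delta < 0) ? alpha_neg[g] : 0.0);
    double qn = qc + a * delta;
    if (chosen_good[t] == 1) qg[p] = qn; else qb[p] = qn;
  }
  return nll;
}
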