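#include <Rcpp.h>
using namespace Rcpp;

// Forward pass of the hybrid Rescorla-Wagner / Pearce-Hall learner over one
// animal's trial stream, returning the negative log-likelihood of the
// observed actions under phase-specific softmax choice.
//
// state, action: 1-based indices (2 states x 2 actions), NA = no state for
//   this model family (trial neither updates values nor enters the
//   likelihood).
// include: whether the trial contributes a likelihood term; excluded trials
//   with a defined state still drive value updates.
// rule: 0 = full hybrid (kappa, eta free), 1 = hybrid with kappa fixed at 1,
//   2 = pure Rescorla-Wagner (constant associability alpha0).
// [[Rcpp::export]]
double rl_nll_cpp(IntegerVector state, IntegerVector action,
                  NumericVector reward, IntegerVector phase,
                  LogicalVector include,
                  double kappa, double eta, NumericVector beta,
                  double v0, double alpha0, int rule) {
  int n = state.size();
  double V[2][2] = {{v0, v0}, {v0, v0}};
  double alpha = alpha0;
  double k = (rule == 1) ? 1.0 : kappa;
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (state[t] == NA_INTEGER || action[t] == NA_INTEGER) continue;
    int s = state[t] - 1, a = action[t] - 1;
    if (include[t]) {
      double b = beta[phase[t] - 1];
      double dv = V[s][1 - a] - V[s][a];
      // -log p(a|s) with p from the two-action softmax, overflow-safe
      nll += (b * dv > 30) ? b * dv : std::log1p(std::exp(b * dv));
    }
    double delta = reward[t] - V[s][a];
    V[s][a] += k * alpha * delta;
    if (rule != 2) alpha = (1.0 - eta) * alpha + eta * std::fabs(delta);
  }
  return nll;
}
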