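#include <Rcpp.h>
using namespace Rcpp;

// Shared helpers for simulating replacement processes to absorption.
// Labels are arbitrary integers; a run absorbs when all sites carry the
// same label. R's RNG is used throughout so set.seed() governs results.

static inline bool monomorphic(const std::vector<int> &lab) {
  for (size_t i = 1; i < lab.size(); ++i)
    if (lab[i] != lab[0]) return false;
  return true;
}

static inline int sample_categorical(const std::vector<double> &cum) {
  double u = unif_rand() * cum.back();
  // binary search for first cum[k] > u
  size_t lo = 0, hi = cum.size() - 1;
  while (lo < hi) {
    size_t mid = (lo + hi) / 2;
    if (cum[mid] > u) hi = mid; else lo = mid + 1;
  }
  return static_cast<int>(lo);
}

// Run an explicit-event replacement rule to absorption, n_runs times.
// Events are flattened: event k replaces sites replaced[offsets[k]..
// offsets[k+1]-1] (0-based site indices) with offspring of the matching
// parents. Returns the winning label and step count per run.
// [[Rcpp::export]]
List sim_explicit_cpp(NumericVector probs, IntegerVector offsets,
                      IntegerVector replaced, IntegerVector parents,
                      IntegerVector initial, int n_runs, double max_steps) {
  const int n_events = probs.size();
  const int n_sites = initial.size();
  std::vector<double> cum(n_events);
  double acc = 0.0;
  for (int k = 0; k < n_events; ++k) { acc += probs[k]; cum[k] = acc; }

  IntegerVector winners(n_runs);
  NumericVector steps(n_runs);
  std::vector<int> lab(n_sites), parent_lab;

  for (int run = 0; run < n_runs; ++run) {
    for (int i = 0; i < n_sites; ++i) lab[i] = initial[i];
    double t = 0.0;
    while (!monomorphic(lab)) {
      if (t >= max_steps)
        stop("max_steps exceeded before absorption (invalid rule or "
             "Assumption-1 violation?)");
      int k = sample_categorical(cum);
      int from = offsets[k], to = offsets[k + 1];
      parent_lab.resize(to - from);
      for (int m = from; m < to; ++m)
        parent_lab[m - from] = lab[parents[m]];
      for (int m = from; m < to; ++m)
        lab[replaced[m]] = parent_lab[m - from];
      t += 1.0;
    }
    winners[run] = lab[0];
    steps[run] = t;
  }
  return List::create(_["winner"] = winners, _["steps"] = steps);
}

// Wright-Fisher: every site is replaced each step; site j's parent is
// drawn from column j of parent_probs (columns sum to 1).
// [[Rcpp::export]]
List sim_wright_fisher_cpp(NumericMatrix parent_probs, IntegerVector initial,
                           int n_runs, double max_steps) {
  const int n_sites = initial.size();
  std::vector<std::vector<double>> cum(n_sites,
                                       std::vector<double>(n_sites));
  for (int j = 0; j < n_sites; ++j) {
    double acc = 0.0;
    for (int i = 0; i < n_sites; ++i) {
      acc += parent_probs(i, j);
      cum[j][i] = acc;
    }
  }

  IntegerVector winners(n_runs);
  NumericVector steps(n_runs);
  std::vector<int> lab(n_sites), nxt(n_sites);

  for (int run = 0; run < n_runs; ++run) {
    for (int i = 0; i < n_sites; ++i) lab[i] = initial[i];
    double t = 0.0;
    while (!monomorphic(lab)) {
      if (t >= max_steps)
        stop("max_steps exceeded before absorption (invalid rule or "
             "Assumption-1 violation?)");
      for (int j = 0; j < n_sites; ++j)
        nxt[j] = lab[sample_categorical(cum[j])];
      std::swap(lab, nxt);
      t += 1.0;
    }
    winners[run] = lab[0];
    steps[run] = t;
  }
  return List::create(_["winner"] = winners, _["steps"] = steps);
}
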