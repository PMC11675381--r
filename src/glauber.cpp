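#include <Rcpp.h>
using namespace Rcpp;

// Asynchronous Glauber chain on a graph with binary node states.
//
// One step = one node-update attempt: a node is drawn uniformly from the
// update pool (all nodes, minus a pinned node if present) and flipped with
// probability 1 / (1 + exp(-beta * dE)), where dE = -2 * J * sigma_i * h_i
// is the energy released by the flip (h_i = sum of neighbour spins).
//
// Uses R's RNG so a set.seed() in the caller makes traces bit-reproducible.
//
// neighbours are passed flattened (0-based ids) with CSR-style offsets.
// pinned < 0 disables pinning.  When track_states is true the 0-based
// little-endian state index is tallied per attempt (caller guarantees
// n <= 30 so the index fits an int-valued double).
// [[Rcpp::export(name = ".glauber_run")]]
List glauber_run(int n,
                 IntegerVector nbr,
                 IntegerVector offset,
                 double beta,
                 double coupling,
                 IntegerVector init,
                 double steps,
                 int pinned,
                 bool record_attempts,
                 bool track_states) {
  std::vector<int> sigma(n);
  int ones = 0;
  for (int i = 0; i < n; ++i) {
    sigma[i] = init[i] ? 1 : -1;
    ones += init[i];
  }
  std::vector<int> pool;
  pool.reserve(n);
  for (int i = 0; i < n; ++i)
    if (i != pinned) pool.push_back(i);
  const int n_free = pool.size();
  if (n_free == 0) stop("update pool is empty");

  const long long n_steps = (long long)steps;
  const long long n_sweeps = n_steps / n;
  NumericVector sweep_trace(n_sweeps);
  NumericVector attempt_trace(record_attempts ? n_steps : 0);
  long long n_states = 0;
  double state_idx = 0.0;
  if (track_states) {
    n_states = 1LL << n;
    for (int i = 0; i < n; ++i)
      if (init[i]) state_idx += (double)(1LL << i);
  }
  NumericVector visits(track_states ? n_states : 0);

  RNGScope scope;
  long long sweep = 0;
  for (long long t = 0; t < n_steps; ++t) {
    int i = pool[(int)(unif_rand() * n_free) % n_free];
    int h = 0;
    for (int k = offset[i]; k < offset[i + 1]; ++k) h += sigma[nbr[k]];
    double dE = -2.0 * coupling * sigma[i] * h;
    double p = 1.0 / (1.0 + std::exp(-beta * dE));
    if (unif_rand() < p) {
      ones -= (sigma[i] > 0);
      sigma[i] = -sigma[i];
      ones += (sigma[i] > 0);
      if (track_states) {
        double bit = (double)(1LL << i);
        state_idx += (sigma[i] > 0) ? bit : -bit;
      }
    }
    if (track_states) visits[(long long)state_idx] += 1.0;
    if (record_attempts) attempt_trace[t] = (double)ones / n;
    if ((t + 1) % n == 0) sweep_trace[sweep++] = (double)ones / n;
  }

  IntegerVector final_state(n);
  for (int i = 0; i < n; ++i) final_state[i] = sigma[i] > 0 ? 1 : 0;
  List out = List::create(
    _["sweep_trace"] = sweep_trace,
    _["final_config"] = final_state);
  if (record_attempts) out["attempt_trace"] = attempt_trace;
  if (track_states) out["visits"] = visits / (double)n_steps;
  return out;
}
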