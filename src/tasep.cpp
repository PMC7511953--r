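#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time Markov (Gillespie direct) simulation of ribosome traffic on
// a codon lattice with extended particles (footprint L) and a two-phase dwell
// per codon: elongation-factor recruitment (rate k_wait, sequence independent)
// followed by translocation (rate k_trans[pos], charge dependent).
//
// Ribosome position = 5'-most codon covered; a ribosome at p occupies
// [p, p+L-1]. Initiation (rate alpha) requires codons 1..L vacant and places a
// ribosome at p = 1. A ribosome at p advances to p+1 when the ahead neighbour
// is not at p+L; at p = n_codons the translocation event is termination.
// Uses R's RNG: wrap calls in set.seed() for reproducibility.

// [[Rcpp::export]]
List tasep_run(int n_codons, int L, double alpha, double k_wait,
               NumericVector k_trans, double t_burnin, double t_measure,
               double sample_dt, bool check_exclusion) {
  if (k_trans.size() != n_codons) stop("k_trans must have length n_codons");
  const double t_end = t_burnin + t_measure;

  std::vector<int> pos;      // ascending codon positions
  std::vector<int> stage;    // 0 = waiting for factor, 1 = ready to translocate

  double t = 0.0;
  double next_sample = t_burnin;
  long n_completed = 0, n_initiated = 0;
  int lattice_at_burnin = 0;
  bool burnin_recorded = false;

  // snapshot bookkeeping: at every sample time record the lattice load and
  // the ribosome positions, so that mean(load_samples) == sum(density) exactly
  NumericVector pos_counts(n_codons);
  std::vector<int> load_samples;
  std::vector<double> completion_times;

  std::vector<double> rates;
  std::vector<int> ev_type;  // 0 = initiation, k>0 = ribosome index k-1
  const int max_iter_guard = 200000000;
  int iter = 0;

  while (t < t_end) {
    if (++iter > max_iter_guard) stop("tasep_run: event budget exceeded");
    const int N = (int)pos.size();

    // enabled events and rates
    rates.clear(); ev_type.clear();
    bool init_ok = (N == 0) || (pos.front() > L);
    if (init_ok && alpha > 0) { rates.push_back(alpha); ev_type.push_back(0); }
    for (int i = 0; i < N; ++i) {
      if (stage[i] == 0) {
        if (k_wait > 0) { rates.push_back(k_wait); ev_type.push_back(i + 1); }
      } else {
        bool blocked = (i + 1 < N) && (pos[i + 1] == pos[i] + L);
        if (!blocked) { rates.push_back(k_trans[pos[i] - 1]); ev_type.push_back(i + 1); }
      }
    }
    double total = 0.0;
    for (double r : rates) total += r;
    if (total <= 0.0) {
      if (N == 0 && alpha <= 0) {
        // no dynamics at all: record empty-lattice snapshots to the end
        while (next_sample <= t_end) {
          load_samples.push_back(0);
          next_sample += sample_dt;
        }
        t = t_end;
        break;
      }
      stop("tasep_run: zero total event rate with ribosomes on the lattice");
    }

    double dt = R::exp_rand() / total;
    double t_next = t + dt;

    // snapshots inside the measurement window
    while (next_sample < t_next && next_sample <= t_end) {
      load_samples.push_back(N);
      for (int i = 0; i < N; ++i) pos_counts[pos[i] - 1] += 1.0;
      next_sample += sample_dt;
    }
    if (!burnin_recorded && t_next >= t_burnin) {
      lattice_at_burnin = N;
      burnin_recorded = true;
    }
    if (t_next >= t_end) { t = t_end; break; }
    t = t_next;

    // pick event
    double u = unif_rand() * total, acc = 0.0;
    size_t k = 0;
    for (; k < rates.size(); ++k) { acc += rates[k]; if (u <= acc) break; }
    if (k == rates.size()) k = rates.size() - 1;

    if (ev_type[k] == 0) {
      pos.insert(pos.begin(), 1);
      stage.insert(stage.begin(), 0);
      if (t >= t_burnin) ++n_initiated;
    } else {
      int i = ev_type[k] - 1;
      if (stage[i] == 0) {
        stage[i] = 1;
      } else if (pos[i] == n_codons) {
        pos.erase(pos.begin() + i);
        stage.erase(stage.begin() + i);
        if (t >= t_burnin) { ++n_completed; completion_times.push_back(t - t_burnin); }
      } else {
        pos[i] += 1;
        stage[i] = 0;
      }
    }

    if (check_exclusion) {
      for (size_t i = 1; i < pos.size(); ++i) {
        if (pos[i] - pos[i - 1] < L)
          stop("exclusion violated: footprints overlap");
      }
    }
  }

  NumericVector density = clone(pos_counts);
  const double n_samp = std::max((double)load_samples.size(), 1.0);
  for (int c = 0; c < n_codons; ++c) density[c] /= n_samp;

  return List::create(
    _["n_completed"] = (double)n_completed,
    _["n_initiated"] = (double)n_initiated,
    _["lattice_at_burnin"] = lattice_at_burnin,
    _["lattice_at_end"] = (int)pos.size(),
    _["density"] = density,
    _["load_samples"] = wrap(load_samples),
    _["completion_times"] = wrap(completion_times)
  );
}
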