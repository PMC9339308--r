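#include <Rcpp.h>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Continuous-time (random-sequential / Gillespie) simulation of the
// inhomogeneous l-TASEP with extended particles.
//
// Convention: a ribosome is identified by the position i of its A-site codon
// (the 5'-most codon of its footprint); its body covers codons [i, i + ell).
// Dynamics:
//   * entry at rate alpha iff codons 0..ell-1 are all vacant; the new
//     ribosome sits at position 0;
//   * a ribosome at i < n-1 hops to i+1 at rate rates[i] iff codon i+ell is
//     vacant (always true when i+ell >= n);
//   * a ribosome at n-1 exits at rate beta.
// Occupancy is the fraction of sampled time each codon carries an A-site;
// current is the number of exits per unit sampled time.
//
// Bookkeeping is event-driven: each ribosome remembers when it arrived at
// its current codon so occupancy accrues in O(1) per event, and the total
// propensity is maintained incrementally (recomputed periodically to stop
// floating-point drift). The hard-exclusion invariant is asserted on every
// hop.
// [[Rcpp::export]]
List tasep_gillespie(int n, double alpha, double beta, NumericVector rates,
                     int ell, double burn_in, double sample_time,
                     bool record_hops = false) {
  if (n < 1) stop("n must be >= 1");
  if (ell < 1 || ell > n) stop("ell must be in [1, n]");
  if (rates.size() != n) stop("rates must have length n");
  for (int i = 0; i < n; ++i)
    if (!(rates[i] > 0)) stop("all elongation rates must be strictly positive");
  if (alpha < 0 || !(beta > 0)) stop("alpha must be >= 0 and beta > 0");
  if (!(burn_in > 0) || !(sample_time > 0))
    stop("burn_in and sample_time must be > 0");

  std::deque<int> pos;        // front = most downstream ribosome
  std::deque<double> prop;    // effective rate of each ribosome
  std::deque<double> arrive;  // time of arrival at current position
  NumericVector occ(n);
  NumericVector hops(record_hops ? n : 0);

  const double t_end = burn_in + sample_time;
  double t = 0.0, total = 0.0;
  long exits = 0;
  long long n_events = 0, sampled_events = 0;

  // effective propensity of ribosome k given its neighbour ahead
  auto eff = [&](size_t k) -> double {
    int p = pos[k];
    if (p == n - 1) return beta;
    if (k > 0 && pos[k - 1] - p <= ell) return 0.0;  // site p+ell occupied
    return rates[p];
  };
  auto entry_open = [&]() -> bool {
    return pos.empty() || pos.back() >= ell;
  };

  while (t < t_end) {
    double entry_rate = entry_open() ? alpha : 0.0;
    double R = entry_rate + total;
    if (R <= 0) { t = t_end; break; }  // frozen configuration

    double u = unif_rand();
    if (u <= 0) u = 1e-300;
    double t_next = t - std::log(u) / R;
    if (t_next >= t_end) { t = t_end; break; }
    t = t_next;
    if (t >= burn_in) ++sampled_events;

    double pick = unif_rand() * R;
    if (pick < entry_rate) {
      // initiation: new ribosome at position 0
      pos.push_back(0);
      arrive.push_back(t);
      prop.push_back(0.0);
      double e = eff(pos.size() - 1);
      prop.back() = e;
      total += e;
    } else {
      pick -= entry_rate;
      size_t k = 0;
      double acc = 0.0;
      for (; k < prop.size(); ++k) {
        acc += prop[k];
        if (pick < acc) break;
      }
      if (k == prop.size()) {  // numerical edge: take last movable ribosome
        while (k > 0 && prop[k - 1] <= 0) --k;
        if (k == 0) continue;
        --k;
      }
      int p = pos[k];
      // accrue occupancy for the codon being vacated
      double a = arrive[k] > burn_in ? arrive[k] : burn_in;
      if (t > a) occ[p] += t - a;
      if (p == n - 1) {
        // termination
        if (t >= burn_in) ++exits;
        total -= prop.front();
        pos.pop_front(); prop.pop_front(); arrive.pop_front();
        if (!pos.empty()) {
          double old = prop.front(), nw = eff(0);
          prop.front() = nw; total += nw - old;
        }
      } else {
        if (k > 0 && pos[k - 1] - p <= ell)
          stop("exclusion violated: blocked ribosome selected");
        pos[k] = p + 1;
        arrive[k] = t;
        if (record_hops && t >= burn_in) hops[p] += 1.0;
        double old = prop[k], nw = eff(k);
        prop[k] = nw; total += nw - old;
        if (k + 1 < pos.size()) {  // ribosome behind may unblock
          double o2 = prop[k + 1], n2 = eff(k + 1);
          prop[k + 1] = n2; total += n2 - o2;
        }
      }
    }
    if ((++n_events & 0xFFFFLL) == 0) {  // kill accumulated rounding drift
      total = 0.0;
      for (size_t j = 0; j < prop.size(); ++j) total += prop[j];
    }
  }

  // flush occupancy for ribosomes still on the lattice
  for (size_t k = 0; k < pos.size(); ++k) {
    double a = arrive[k] > burn_in ? arrive[k] : burn_in;
    if (t_end > a) occ[pos[k]] += t_end - a;
  }
  for (int i = 0; i < n; ++i) occ[i] /= sample_time;
  if (record_hops) for (int i = 0; i < n; ++i) hops[i] /= sample_time;

  return List::create(
    _["occupancy"] = occ,
    _["current"] = exits / sample_time,
    _["exits"] = (double)exits,
    _["sampled_events"] = (double)sampled_events,
    _["hop_current"] = hops);
}
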