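#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Counter-based per-clone random substreams (SplitMix64). Each clone gets an
// independent stream derived from (master seed, task index), so cohort results
// do not depend on evaluation order.
namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1): 53-bit mantissa, offset to exclude 0
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

uint64_t task_seed(uint64_t master, uint64_t idx) {
  SplitMix64 s(master ^ (0xD1342543DE82EF95ULL * (idx + 1)));
  s.next();
  return s.next();
}

// One exact event-driven (Gillespie) trajectory of the single-progenitor
// model. State: p progenitors, d post-mitotic basal, s first-suprabasal.
void simulate_one(double lambda, double pPP, double pPD, double gamma_,
                  double mu, double t_end_weeks, int &p, int &d, int &s,
                  SplitMix64 &rng) {
  double t = 0.0;
  for (;;) {
    double rp = p * lambda, rd = d * gamma_, rs = s * mu;
    double total = rp + rd + rs;
    if (total <= 0.0) break;
    t += -std::log(rng.unif()) / total;
    if (t > t_end_weeks) break;
    double u = rng.unif() * total;
    if (u < rp) {
      double v = rng.unif();
      if (v < pPP) {
        ++p;                      // PP: two progenitor daughters
      } else if (v < pPP + pPD) {
        ++d;                      // PD: one of each type
      } else {
        --p; d += 2;              // DD: two differentiating daughters
      }
    } else if (u < rp + rd) {
      --d; ++s;                   // stratification into first suprabasal layer
    } else {
      --s;                        // shedding from first suprabasal layer
    }
  }
}

} // namespace

// Simulate independent clone realizations. Row i uses the substream for
// (seed, index0 + i) and runs from state0 for t_end_weeks[i].
// [[Rcpp::export]]
IntegerMatrix simulate_clones_cpp(double lambda, double pPP, double pPD,
                                  double gamma_, double mu,
                                  IntegerVector state0,
                                  NumericVector t_end_weeks,
                                  double seed, double index0) {
  const int n = t_end_weeks.size();
  IntegerMatrix out(n, 3);
  const uint64_t master = static_cast<uint64_t>(seed);
  const uint64_t i0 = static_cast<uint64_t>(index0);
  for (int i = 0; i < n; ++i) {
    int p = state0[0], d = state0[1], s = state0[2];
    SplitMix64 rng(task_seed(master, i0 + static_cast<uint64_t>(i)));
    simulate_one(lambda, pPP, pPD, gamma_, mu, t_end_weeks[i], p, d, s, rng);
    out(i, 0) = p;
    out(i, 1) = d;
    out(i, 2) = s;
  }
  return out;
}
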