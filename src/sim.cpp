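#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Read generation core: each read copies its template (optionally behind a
// short random 5' pad emulating the fusion construct's 3-6-mer N stretch),
// truncated at the cycle count, with independent per-base substitution
// errors and Phred qualities drawn from a positional profile (flat mean
// until `decay_start`, then linear decay, Gaussian noise). All randomness
// comes from R's RNG so set.seed() governs reproducibility.

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline char random_base() {
  return BASES[(int)(unif_rand() * 4) & 3];
}

static inline char mutate_base(char b) {
  char c;
  do { c = random_base(); } while (c == b);
  return c;
}

//' @noRd
// [[Rcpp::export]]
List cpp_sim_reads(StringVector templates, IntegerVector tpl_idx,
                   int read_len, double error_rate, double q_mean,
                   double q_sd, int decay_start, double decay_rate,
                   int pad_min, int pad_max) {
  int n = tpl_idx.size();
  StringVector bases(n), quals(n);
  std::vector<char> seq(read_len + 1), qual(read_len + 1);

  for (int r = 0; r < n; ++r) {
    const char *t = CHAR(STRING_ELT(templates, tpl_idx[r] - 1));
    int tlen = (int)std::strlen(t);
    int pad = pad_min;
    if (pad_max > pad_min)
      pad = pad_min + (int)(unif_rand() * (pad_max - pad_min + 1));
    if (pad > pad_max) pad = pad_max;
    int len = std::min(read_len, pad + tlen);
    for (int i = 0; i < len; ++i) {
      char b = i < pad ? random_base() : t[i - pad];
      if (error_rate > 0 && unif_rand() < error_rate) b = mutate_base(b);
      seq[i] = b;
      double q = q_mean;
      if (i >= decay_start) q -= decay_rate * (i - decay_start);
      q += norm_rand() * q_sd;
      int qi = (int)(q + 0.5);
      if (qi < 2) qi = 2;
      if (qi > 41) qi = 41;
      qual[i] = (char)(33 + qi);
    }
    seq[len] = '\0';
    qual[len] = '\0';
    bases[r] = std::string(seq.data(), len);
    quals[r] = std::string(qual.data(), len);
    if (r % 4096 == 0) checkUserInterrupt();
  }
  return List::create(_["bases"] = bases, _["quals"] = quals);
}
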