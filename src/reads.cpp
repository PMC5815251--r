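#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Locate an IUPAC primer at the 5' end of each read, allowing a variable
// 0..max_pad random pad before it (the fusion construct carries 3-6
// degenerate bases ahead of the specific primer). Returns the number of
// leading characters to remove (pad + primer), or -1 when the primer is
// not found within `max_mismatch` at any admissible offset. The smallest
// offset with the fewest mismatches wins.

static int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4;
    case 'T': return 8;
    case 'R': return 1 | 4; case 'Y': return 2 | 8; case 'S': return 2 | 4;
    case 'W': return 1 | 8; case 'K': return 4 | 8; case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default: return 0;
  }
}

static int base_bit(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4;
    case 'T': return 8;
    default: return 0;  // N / other read bases match nothing
  }
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_primer_offset(StringVector bases, std::string primer,
                                int max_pad, int max_mismatch) {
  int plen = (int)primer.size();
  std::vector<int> pm(plen);
  for (int i = 0; i < plen; ++i) pm[i] = iupac_mask(primer[i]);
  int n = bases.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(bases, r));
    int len = (int)std::strlen(s);
    int best_off = -1, best_mm = max_mismatch + 1;
    for (int off = 0; off <= max_pad && off + plen <= len; ++off) {
      int mm = 0;
      for (int i = 0; i < plen; ++i) {
        if (!(base_bit(s[off + i]) & pm[i]) && ++mm > max_mismatch) break;
      }
      if (mm <= max_mismatch && mm < best_mm) {
        best_mm = mm;
        best_off = off;
        if (mm == 0) break;
      }
    }
    out[r] = best_off < 0 ? -1 : best_off + plen;
  }
  return out;
}
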