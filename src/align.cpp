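#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment shared by OTU clustering and
// taxonomic assignment. Scoring: match +1, mismatch -1, linear gap -2 —
// terminal gaps are scored like internal ones, which keeps the optimum
// from collapsing onto spurious micro-overlaps between unrelated
// sequences. Identity is then computed over the alignment columns with
// the terminal gap runs excluded: matching columns / remaining columns,
// internal gaps counting as non-matching columns. So a 3'-trimmed read
// that is an exact prefix of its centroid still scores identity 1.
//
// The DP is banded around the length-offset corridor: homologous
// amplicon alignments drift from it by at most the number of internal
// indels, bounded by (1 - identity) * overlap for any identity above the
// decision threshold, so a band sized for that threshold is exact for
// every identity at or above it.

static const int NEG_INF = -1000000000;
static const int GAP_COST = 2;

struct AlnResult {
  double identity;
  int matches;
  int columns;
};

static AlnResult global_identity(const char *a, int la, const char *b,
                                 int lb, int W) {
  AlnResult res{0.0, 0, 0};
  if (la == 0 || lb == 0) return res;
  if (W < 1) W = 1;
  const int kmin = std::min(0, lb - la) - W;
  const int kmax = std::max(0, lb - la) + W;
  const int bw = kmax - kmin + 1;

  // pointer codes: 0 = origin, 1 = diag, 2 = up (gap in b),
  // 3 = left (gap in a)
  std::vector<unsigned char> ptr((size_t)(la + 1) * bw, 0);
  std::vector<int> prev(bw, NEG_INF), cur(bw, NEG_INF);

  for (int j = std::max(0, kmin); j <= std::min(lb, kmax); ++j) {
    prev[j - kmin] = -GAP_COST * j;
    ptr[j - kmin] = j == 0 ? 0 : 3;
  }
  for (int i = 1; i <= la; ++i) {
    std::fill(cur.begin(), cur.end(), NEG_INF);
    int jlo = std::max(0, i + kmin), jhi = std::min(lb, i + kmax);
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - i - kmin;
      int sc = NEG_INF;
      unsigned char p = 0;
      if (j == 0) {
        sc = -GAP_COST * i;
        p = 2;
      } else {
        // on score ties gap steps are preferred over the diagonal so
        // that co-optimal gaps coalesce into terminal runs (which the
        // identity denominator excludes) instead of scattering inward
        if (k + 1 < bw && prev[k + 1] > NEG_INF) {  // up
          int d = prev[k + 1] - GAP_COST;
          if (d > sc) { sc = d; p = 2; }
        }
        if (k - 1 >= 0 && cur[k - 1] > NEG_INF) {   // left
          int d = cur[k - 1] - GAP_COST;
          if (d > sc) { sc = d; p = 3; }
        }
        if (prev[k] > NEG_INF) {  // diagonal keeps the same offset index
          int d = prev[k] + (a[i - 1] == b[j - 1] ? 1 : -1);
          if (d > sc) { sc = d; p = 1; }
        }
        if (sc == NEG_INF) continue;
      }
      cur[k] = sc;
      ptr[(size_t)i * bw + k] = p;
    }
    std::swap(prev, cur);
  }
  if (prev[lb - la - kmin] <= NEG_INF) return res;

  // traceback from (la, lb), recording one step per column
  std::vector<unsigned char> steps;
  steps.reserve(la + lb);
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    unsigned char p = ptr[(size_t)i * bw + (j - i - kmin)];
    if (p == 0) break;
    steps.push_back(p);
    if (p == 1) { --i; --j; }
    else if (p == 2) { --i; }
    else { --j; }
  }
  // steps run 3'->5'; drop the terminal gap runs at both ends
  int lo = 0, hi = (int)steps.size() - 1;
  while (lo <= hi && steps[lo] != 1) ++lo;
  while (hi >= lo && steps[hi] != 1) --hi;
  int matches = 0, columns = 0;
  int ai = la, bj = lb;  // replay to know the residues under each column
  for (int t = 0; t <= hi; ++t) {
    unsigned char p = steps[t];
    if (t >= lo) {
      ++columns;
      if (p == 1 && a[ai - 1] == b[bj - 1]) ++matches;
    }
    if (p == 1) { --ai; --bj; }
    else if (p == 2) { --ai; }
    else { --bj; }
  }
  res.matches = matches;
  res.columns = columns;
  res.identity = columns > 0 ? (double)matches / columns : 0.0;
  return res;
}

static int auto_band(int la, int lb) {
  int mn = std::min(la, lb);
  return std::max(32, (int)(0.2 * mn) + 8);
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_pair_identity(std::string a, std::string b,
                                int band = -1) {
  if (band <= 0) band = auto_band(a.size(), b.size());
  AlnResult r = global_identity(a.c_str(), a.size(), b.c_str(), b.size(),
                                 band);
  return NumericVector::create(_["identity"] = r.identity,
                               _["matches"] = (double)r.matches,
                               _["columns"] = (double)r.columns);
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_identity_to_refs(std::string query, StringVector refs,
                                   int band = -1) {
  int n = refs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(refs[i]);
    int b = band > 0 ? band : auto_band(query.size(), r.size());
    out[i] = global_identity(query.c_str(), query.size(), r.c_str(),
                              r.size(), b).identity;
    if (i % 64 == 0) checkUserInterrupt();
  }
  return out;
}

// 8-mer presence bitmap used as an identity upper-bound screen: d
// non-matching columns destroy at most 8d of the overlap's 8-mers, so two
// sequences at >= 97% identity over an overlap of length L share at least
// ~0.76 (L - 7) 8-mers. The 0.6 threshold below is conservative.
static const int KMER_K = 8;
static const size_t KMER_SPACE = 1 << (2 * KMER_K);  // 4^8

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static void kmer_codes(const std::string &s, std::vector<int> &out) {
  out.clear();
  int n = (int)s.size();
  if (n < KMER_K) return;
  int code = 0, valid = 0;
  const int mask = (int)KMER_SPACE - 1;
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    if (++valid >= KMER_K) out.push_back(code);
  }
}

// Abundance-ordered greedy centroid clustering. `seqs` must already be
// sorted (abundance desc, sequence asc); each sequence joins the
// best-scoring existing centroid with identity >= cutoff (ties keep the
// earliest-created centroid) or founds a new one. Returns 1-based centroid
// indices in creation order.
//
// Candidate centroids are retrieved through an inverted 8-mer index and
// gated by a shared-k-mer identity bound before any alignment: an
// alignment at identity >= c has d <= (1-c)(L0+d) non-matching columns,
// each destroying at most 8 of the overlap's distinct 8-mers, so
// candidates sharing fewer than ~0.7 (L0-7) distinct 8-mers (0.75 minus
// slack for within-sequence k-mer collisions) cannot reach a 0.97 cutoff
// and are skipped exactly. Sequences too short to carry 8-mers fall back
// to scanning every centroid.
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(StringVector seqs, double cutoff) {
  int n = seqs.size();
  IntegerVector assign(n);
  std::vector<std::string> cents;
  std::vector<std::vector<int>> kindex(KMER_SPACE);  // kmer -> centroids
  std::vector<int> codes;
  std::vector<int> kseen(KMER_SPACE, -1);   // epoch stamp: query dedup
  std::vector<int> cstamp, ccount;          // epoch-stamped shared counts
  std::vector<int> touched;

  double gate = cutoff >= 0.9 ? 0.7 : 0.0;  // below 0.9 the bound is weak

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int la = (int)s.size();
    kmer_codes(s, codes);
    double best_id = -1.0;
    int best_c = -1;

    if (!codes.empty() && !cents.empty()) {
      touched.clear();
      for (size_t q = 0; q < codes.size(); ++q) {
        int cd = codes[q];
        if (kseen[cd] == i) continue;  // count distinct query k-mers once
        kseen[cd] = i;
        const std::vector<int> &lst = kindex[cd];
        for (size_t t = 0; t < lst.size(); ++t) {
          int c = lst[t];
          if (cstamp[c] != i) {
            cstamp[c] = i;
            ccount[c] = 0;
            touched.push_back(c);
          }
          ++ccount[c];
        }
      }
      std::sort(touched.begin(), touched.end());  // earliest-centroid ties
      for (size_t t = 0; t < touched.size(); ++t) {
        int c = touched[t];
        const std::string &ct = cents[c];
        int lc = (int)ct.size();
        int L0 = std::min(la, lc);
        if (L0 < KMER_K) continue;
        if (ccount[c] < gate * (L0 - KMER_K + 1)) continue;
        // shared-k-mer upper bound on achievable identity: at least
        // d_min = (distinct overlap k-mers - shared - slack)/8 edits are
        // needed, and identity <= 1 - d_min/(L0 + d_min). Skipping when
        // the bound cannot beat the incumbent is exact: on a tie the
        // earlier centroid (already held) wins anyway.
        double d_min = (double)(L0 - KMER_K + 1 - ccount[c] - 4) / 8.0;
        if (d_min > 0) {
          double ub = 1.0 - d_min / (L0 + d_min);
          if (ub < cutoff || ub <= best_id) continue;
        }
        int band = std::max(16, (int)((1.0 - cutoff) * L0) + 8);
        AlnResult r = global_identity(s.c_str(), la, ct.c_str(), lc,
                                       band);
        if (r.identity >= cutoff && r.identity > best_id + 1e-12) {
          best_id = r.identity;
          best_c = c;
        }
      }
    } else if (!cents.empty()) {
      // short-sequence fallback: no k-mers to index on
      for (size_t c = 0; c < cents.size(); ++c) {
        const std::string &ct = cents[c];
        int L0 = std::min(la, (int)ct.size());
        int band = std::max(16, (int)((1.0 - cutoff) * L0) + 8);
        AlnResult r = global_identity(s.c_str(), la, ct.c_str(),
                                       (int)ct.size(), band);
        if (r.identity >= cutoff && r.identity > best_id + 1e-12) {
          best_id = r.identity;
          best_c = (int)c;
        }
      }
    }

    if (best_c >= 0) {
      assign[i] = best_c + 1;
    } else {
      int cid = (int)cents.size();
      cents.push_back(s);
      cstamp.push_back(-1);
      ccount.push_back(0);
      // index the new centroid's distinct k-mers
      for (size_t q = 0; q < codes.size(); ++q) {
        int cd = codes[q];
        std::vector<int> &lst = kindex[cd];
        if (lst.empty() || lst.back() != cid) lst.push_back(cid);
      }
      assign[i] = cid + 1;
    }
    if (i % 256 == 0) checkUserInterrupt();
  }
  return assign;
}

// 3'-peeling quality trim: drop the terminal base while any of the last
// `window` qualities is below `minq`; stop when the terminal window is
// clean or fewer than `window` bases remain. Returns retained lengths.
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_trim_lengths(StringVector quals, int window, int minq) {
  int n = quals.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(quals, i));
    int len = (int)std::strlen(q);
    while (len >= window) {
      bool clean = true;
      for (int p = len - window; p < len; ++p) {
        if (q[p] - 33 < minq) { clean = false; break; }
      }
      if (clean) break;
      --len;
    }
    out[i] = len;
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_count_lowq(StringVector quals, int thresh) {
  int n = quals.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(quals, i));
    int cnt = 0;
    for (; *q; ++q) if (*q - 33 < thresh) ++cnt;
    out[i] = cnt;
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_min_qual(StringVector quals) {
  int n = quals.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(quals, i));
    int mn = 99;
    for (; *q; ++q) if (*q - 33 < mn) mn = *q - 33;
    out[i] = mn;
  }
  return out;
}
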