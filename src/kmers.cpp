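#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// 2-bit base code; -1 for anything outside A/C/G/T (ambiguity codes, N, ...)
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// Canonical k-mer codes (lexicographic min of k-mer and reverse complement,
// A<C<G<T so string order == numeric order of the 2-bit encoding) for every
// window of `seq`; NA where the window contains a non-ACGT character.
// k is capped at 26 so codes stay exactly representable as doubles.
static std::vector<double> kmer_code_vec(const char* s, int n, int k) {
  std::vector<double> out;
  if (k < 1 || k > n) return out;
  out.assign(n - k + 1, NA_REAL);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;  // number of consecutive valid bases ending at i
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      out[i - k + 1] = (double)canon;
    }
  }
  return out;
}

static void check_k(int k) {
  if (k < 1) stop("k must be >= 1");
  if (k > 26) stop("k must be <= 26 (codes are stored as exact doubles)");
}

// [[Rcpp::export]]
NumericVector cpp_kmer_codes(std::string seq, int k) {
  check_k(k);
  std::vector<double> v = kmer_code_vec(seq.c_str(), (int)seq.size(), k);
  return NumericVector(v.begin(), v.end());
}

// Sorted unique canonical k-mer codes over a set of sequences.
// [[Rcpp::export]]
NumericVector cpp_unique_kmer_codes(CharacterVector seqs, int k) {
  check_k(k);
  std::vector<double> all;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int n = (int)LENGTH(STRING_ELT(seqs, i));
    std::vector<double> v = kmer_code_vec(s, n, k);
    for (double x : v) if (!ISNA(x)) all.push_back(x);
  }
  std::sort(all.begin(), all.end());
  all.erase(std::unique(all.begin(), all.end()), all.end());
  return NumericVector(all.begin(), all.end());
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(NumericVector codes, int k) {
  check_k(k);
  CharacterVector out(codes.size());
  const char* bases = "ACGT";
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t code = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = bases[code & 3ULL];
      code >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

static inline bool in_sorted(const double* tab, int n, double x) {
  return std::binary_search(tab, tab + n, x);
}

// 0-based offsets of all marker windows (width `width`) of `seq` that
// (a) contain only A/C/G/T and (b) share no canonical k-window with
// `shared_sorted` (sorted numeric codes).  Pass a zero-length shared set to
// enumerate clean windows only.
// [[Rcpp::export]]
IntegerVector cpp_stretch_survivors(std::string seq, int k,
                                    NumericVector shared_sorted, int width) {
  check_k(k);
  int n = (int)seq.size();
  if (width < k) stop("marker width must be >= k");
  std::vector<int> keep;
  if (n < width) return IntegerVector(0);
  std::vector<double> codes = kmer_code_vec(seq.c_str(), n, k);
  const double* tab = shared_sorted.begin();
  int ntab = (int)shared_sorted.size();
  int ncode = (int)codes.size();
  // bad[j]: k-window j is ambiguous or present in the shared set
  std::vector<int> badpre(ncode + 1, 0);
  for (int j = 0; j < ncode; ++j) {
    bool bad = ISNA(codes[j]) || (ntab > 0 && in_sorted(tab, ntab, codes[j]));
    badpre[j + 1] = badpre[j] + (bad ? 1 : 0);
  }
  int wk = width - k + 1;  // k-windows per marker window
  for (int i = 0; i + width <= n; ++i) {
    // a marker window is clean iff all its k-windows are valid, and it
    // survives iff none of them is shared; both collapse to badpre
    if (badpre[i + wk] - badpre[i] == 0) keep.push_back(i);
  }
  return IntegerVector(keep.begin(), keep.end());
}

// [[Rcpp::export]]
bool cpp_any_shared(std::string seq, int k, NumericVector shared_sorted) {
  check_k(k);
  std::vector<double> codes = kmer_code_vec(seq.c_str(), (int)seq.size(), k);
  const double* tab = shared_sorted.begin();
  int ntab = (int)shared_sorted.size();
  for (double x : codes)
    if (!ISNA(x) && ntab > 0 && in_sorted(tab, ntab, x)) return true;
  return false;
}
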