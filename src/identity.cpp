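// Seed-and-extend search for the closest non-target window of a candidate
// marker, with a candidate-anchored (global) identity denominator.
//
// Seeding uses short exact words (default length 6) on both strands.  For
// the routine 50-mer / 85% setting, an ungapped window with >= 43 matching
// positions has at most 7 mismatches, hence at most 8 match runs; if its
// longest run were <= 7 the total would be <= 7 + 7*5 = 42 < 43.  So every
// such window contains, on its diagonal, either a match run of >= 8
// (which yields >= 3 seed hits at consecutive positions) or two runs of
// >= 6 (two seed hits separated by a mismatch, i.e. a positional gap of
// 7..44 within one window).  The trigger rule below -- evaluate a diagonal
// when two seed hits occur at gap 2..(width-seed_len), or when three
// consecutive hits occur at gap 1 -- is therefore complete for ungapped
// similarity at the threshold, while ignoring the isolated gap-1 seed
// pairs that dominate random background (a quarter of all hits).
// Diagonals that trigger get an ungapped count; a banded unit-cost DP
// (minimum edit operations, free end gaps on the genomic window) refines
// counts close to the decision boundary, since >= 43 identical positions
// is exactly an alignment with <= 7 edit operations.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: break;
    }
  }
  return r;
}

// Counting-sort seed index over all forward-strand windows of `seqs`.
// [[Rcpp::export]]
List cpp_seed_index(CharacterVector seqs, int seed_len) {
  if (seed_len < 1 || seed_len > 12) stop("seed_len must be in [1, 12]");
  const int nbuck = 1 << (2 * seed_len);
  std::vector<int> counts(nbuck + 1, 0);
  const uint32_t mask = (uint32_t)(nbuck - 1);

  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char* s = CHAR(STRING_ELT(seqs, si));
    int n = (int)LENGTH(STRING_ELT(seqs, si));
    uint32_t code = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)c) & mask;
      if (++run >= seed_len) counts[code + 1]++;
    }
  }
  for (int b = 0; b < nbuck; ++b) counts[b + 1] += counts[b];
  int total = counts[nbuck];

  IntegerVector starts(counts.begin(), counts.end());
  IntegerVector gid(total), pos(total);
  std::vector<int> fill(counts.begin(), counts.end() - 1);

  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char* s = CHAR(STRING_ELT(seqs, si));
    int n = (int)LENGTH(STRING_ELT(seqs, si));
    uint32_t code = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)c) & mask;
      if (++run >= seed_len) {
        int at = fill[code]++;
        gid[at] = (int)si;
        pos[at] = i - seed_len + 1;
      }
    }
  }
  return List::create(_["starts"] = starts, _["gid"] = gid, _["pos"] = pos,
                      _["seed_len"] = seed_len);
}

// Banded alignment of the whole candidate against a genomic window with
// free end gaps on the window, unit costs (match 0, mismatch/indel 1),
// band +/- pad around the seeded diagonal.  Returns the minimum number
// of edit operations; `len - ops` lower-bounds the number of identical
// aligned positions in some alignment, so `ops <= len - ceil(0.85*len)`
// is exactly the inclusive >= 85% identity condition (for a 50-mer:
// 7 operations, 43 matches).  `s0` is the window position aligned to
// the first candidate base on the seeded diagonal.
static int nw_min_ops(const char* q, int n, const char* w, int wlen,
                      int s0, int pad) {
  const int INF = 1000000;
  const int B = 2 * pad;
  static thread_local std::vector<int> prev, cur;
  prev.assign(B + 1, INF); cur.assign(B + 1, INF);
  // offset t maps to window column jw = i + s0 - pad + t
  for (int t = 0; t <= B; ++t) {
    int jw = s0 - pad + t;
    if (jw >= 0 && jw <= wlen) prev[t] = 0;  // free leading window
  }
  for (int i = 1; i <= n; ++i) {
    int base = i + s0 - pad;
    for (int t = 0; t <= B; ++t) {
      int jw = base + t;
      cur[t] = INF;
      if (jw < 0 || jw > wlen) continue;
      int best = INF;
      if (jw >= 1 && prev[t] < INF) {        // diag: q[i-1] vs w[jw-1]
        int sc = prev[t] + (q[i - 1] == w[jw - 1] ? 0 : 1);
        if (sc < best) best = sc;
      }
      if (t + 1 <= B && prev[t + 1] < INF) { // gap in window (deletion)
        int sc = prev[t + 1] + 1;
        if (sc < best) best = sc;
      }
      if (t >= 1 && jw >= 1 && cur[t - 1] < INF) { // gap in candidate
        int sc = cur[t - 1] + 1;                   // (insertion)
        if (sc < best) best = sc;
      }
      cur[t] = best;
    }
    std::swap(prev, cur);
  }
  int best = INF;
  for (int t = 0; t <= B; ++t) if (prev[t] < best) best = prev[t];
  return best;
}

// ungapped matches of q[0..len) against s on absolute diagonal d
static inline int ungapped_matches(const char* q, int len, const char* s,
                                   int slen, int d) {
  int m0 = 0;
  int t0 = 0, t1 = len;
  if (d < 0) t0 = -d;
  if (d + len > slen) t1 = slen - d;
  for (int t = t0; t < t1; ++t)
    if (q[t] == s[d + t]) ++m0;
  return m0;
}

// ungapped count, refined by the banded minimum-edit-operation DP only
// where gaps could change the filtering decision
static inline int eval_window(const char* q, int len, const char* s,
                              int slen, int d, int trigger, int hicut,
                              int pad) {
  int m0 = ungapped_matches(q, len, s, slen, d);
  int m = m0;
  if (m0 >= trigger && m0 < hicut && m0 < len) {
    int ws = d - pad; if (ws < 0) ws = 0;
    int we = d + len + pad; if (we > slen) we = slen;
    if (we > ws) {
      int ops = nw_min_ops(q, len, s + ws, we - ws, d - ws, pad);
      if (len - ops > m) m = len - ops;
    }
  }
  return m;
}

// Maximum identity (identical aligned positions / candidate length) of
// each candidate against any indexed sequence whose group differs from
// the candidate's group.  Stops scanning a candidate once `stop_at` is
// reached.
// [[Rcpp::export]]
NumericVector cpp_max_identity(CharacterVector candidates,
                               IntegerVector cand_group,
                               CharacterVector seqs,
                               IntegerVector seq_group,
                               List index,
                               double nw_trigger,
                               int pad,
                               double stop_at) {
  IntegerVector starts = index["starts"];
  IntegerVector gidv = index["gid"];
  IntegerVector posv = index["pos"];
  int seed_len = as<int>(index["seed_len"]);
  const int* st = starts.begin();
  const int* gid = gidv.begin();
  const int* pos = posv.begin();
  const uint32_t mask = (uint32_t)((1 << (2 * seed_len)) - 1);

  const int HBITS = 17;               // open-address table, stamp-reset
  const int HSIZE = 1 << HBITS;
  std::vector<uint64_t> hkey(HSIZE, 0);
  std::vector<int> hlast(HSIZE), hstamp(HSIZE, -1);
  std::vector<unsigned char> hstreak(HSIZE), htrig(HSIZE);
  std::vector<int> trig_slots;
  trig_slots.reserve(1024);

  int nseq = (int)seqs.size();
  std::vector<const char*> sp(nseq);
  std::vector<int> sl(nseq);
  for (int i = 0; i < nseq; ++i) {
    sp[i] = CHAR(STRING_ELT(seqs, i));
    sl[i] = (int)LENGTH(STRING_ELT(seqs, i));
  }

  NumericVector out(candidates.size());
  for (R_xlen_t ci = 0; ci < candidates.size(); ++ci) {
    std::string fwd = as<std::string>(candidates[ci]);
    int len = (int)fwd.size();
    if (len < seed_len) { out[ci] = 0.0; continue; }
    std::string rc = revcomp(fwd);
    int cg = cand_group[ci];
    int stamp = (int)ci;
    int max_gap = len - seed_len;
    trig_slots.clear();

    for (int strand = 0; strand < 2; ++strand) {
      const char* q = strand == 0 ? fwd.c_str() : rc.c_str();
      uint32_t code = 0; int run = 0;
      for (int i = 0; i < len; ++i) {
        int c = base_code(q[i]);
        if (c < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint32_t)c) & mask;
        if (++run < seed_len) continue;
        int qpos = i - seed_len + 1;
        for (int b = st[code]; b < st[code + 1]; ++b) {
          int g = gid[b];
          if (seq_group[g] == cg) continue;
          int diag = pos[b] - qpos;
          uint64_t key = (((uint64_t)(g + 1)) << 33) |
                         (((uint64_t)strand) << 32) |
                         (uint64_t)(uint32_t)(diag + (1 << 30));
          uint64_t h = key;
          h ^= h >> 33; h *= 0xff51afd7ed558ccdULL; h ^= h >> 33;
          int slot = (int)(h & (uint64_t)(HSIZE - 1));
          for (;;) {
            if (hstamp[slot] != stamp) {
              hstamp[slot] = stamp; hkey[slot] = key;
              hlast[slot] = qpos; hstreak[slot] = 0; htrig[slot] = 0;
              break;
            }
            if (hkey[slot] == key) {
              int gap = qpos - hlast[slot];
              bool fire = false;
              if (gap == 1) {
                if (++hstreak[slot] >= 2) fire = true;
              } else {
                hstreak[slot] = 0;
                if (gap >= 2 && gap <= max_gap) fire = true;
              }
              hlast[slot] = qpos;
              if (fire && !htrig[slot]) {
                htrig[slot] = 1;
                trig_slots.push_back(slot);
              }
              break;
            }
            slot = (slot + 1) & (HSIZE - 1);
          }
        }
      }
    }

    double best = 0.0;
    int trigger = (int)std::ceil(nw_trigger * len);
    int hicut = stop_at >= 1.0 ? len + 1 : (int)std::ceil(stop_at * len);
    for (size_t k = 0; k < trig_slots.size() && best < stop_at; ++k) {
      int slot = trig_slots[k];
      uint64_t key = hkey[slot];
      int g = (int)(key >> 33) - 1;
      int strand = (int)((key >> 32) & 1ULL);
      int diag = (int)(key & 0xFFFFFFFFULL) - (1 << 30);
      const char* q = strand == 0 ? fwd.c_str() : rc.c_str();
      int m = eval_window(q, len, sp[g], sl[g], diag, trigger, hicut, pad);
      double id = (double)m / (double)len;
      if (id > best) best = id;
    }
    out[ci] = best;
  }
  return out;
}

// Contig-level batch identity: same trigger rule as cpp_max_identity, but
// seed hits are enumerated once per target contig instead of once per
// candidate window, in chunks of query positions; each chunk is
// stable-radix-sorted by (strand, contig, diagonal), which leaves hits
// qpos-ordered within a diagonal, and scanned with the run/pair rule.
// `offsets` are the candidate (stretch-survivor) starts on `target`;
// returns the max identity per offset, short-circuiting candidates that
// already reached `threshold`.
// [[Rcpp::export]]
NumericVector cpp_contig_max_identity(std::string target,
                                      IntegerVector offsets, int width,
                                      int cand_group,
                                      CharacterVector seqs,
                                      IntegerVector seq_group,
                                      List index,
                                      double nw_trigger, int pad,
                                      double threshold) {
  IntegerVector bstarts = index["starts"];
  IntegerVector gidv = index["gid"];
  IntegerVector posv = index["pos"];
  int seed_len = as<int>(index["seed_len"]);
  const int* st = bstarts.begin();
  const int* gid = gidv.begin();
  const int* pos = posv.begin();
  const uint32_t mask = (uint32_t)((1 << (2 * seed_len)) - 1);
  const int L = (int)target.size();
  const int n_off = (int)offsets.size();
  NumericVector out(n_off);
  if (n_off == 0 || L < width) return out;
  const int max_gap = width - seed_len;  // two seeds fit one window

  std::vector<int> cand_at(L - width + 1, -1);
  for (int i = 0; i < n_off; ++i) cand_at[offsets[i]] = i;

  int nseq = (int)seqs.size();
  if (nseq >= (1 << 18)) stop("too many contigs for the seed index");
  std::vector<const char*> sp(nseq);
  std::vector<int> sl(nseq);
  for (int i = 0; i < nseq; ++i) {
    sp[i] = CHAR(STRING_ELT(seqs, i));
    sl[i] = (int)LENGTH(STRING_ELT(seqs, i));
  }

  std::string rc = revcomp(target);
  const char* qs[2] = { target.c_str(), rc.c_str() };
  int trigger = (int)std::ceil(nw_trigger * width);
  int hicut = threshold >= 1.0 ? width + 1
                               : (int)std::ceil(threshold * width);

  struct Hit { uint64_t key; int qpos; };
  std::vector<Hit> hits, tmp;
  const int CHUNK = 8192;
  const int DOFF = 1 << 28;  // diagonal offset so keys stay non-negative
  // overlap so pair/run state never straddles a chunk boundary unseen
  const int OVER = max_gap + 2;

  for (int chunk = 0; chunk < L; chunk += CHUNK) {
    int lo_q = chunk - OVER; if (lo_q < 0) lo_q = 0;
    int hi_q = chunk + CHUNK; if (hi_q > L) hi_q = L;
    hits.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const char* q = qs[strand];
      uint32_t code = 0; int run = 0;
      int warm = lo_q - (seed_len - 1); if (warm < 0) warm = 0;
      for (int e = warm; e < hi_q + seed_len - 1 && e < L; ++e) {
        int c = base_code(q[e]);
        if (c < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint32_t)c) & mask;
        if (++run < seed_len) continue;
        int qpos = e - seed_len + 1;
        if (qpos < lo_q || qpos >= hi_q) continue;
        for (int b = st[code]; b < st[code + 1]; ++b) {
          int g = gid[b];
          if (seq_group[g] == cand_group) continue;
          uint64_t gg = ((uint64_t)g << 1) | (uint64_t)strand;
          uint64_t key = (gg << 29) |
                         (uint64_t)(uint32_t)(pos[b] - qpos + DOFF);
          hits.push_back(Hit{ key, qpos });
        }
      }
    }
    if (hits.size() < 2) continue;
    // stable LSD radix sort by key (48 bits, 3 x 16-bit passes); hits were
    // generated in qpos order, so ties stay qpos-sorted
    tmp.resize(hits.size());
    for (int pass = 0; pass < 3; ++pass) {
      int shift = 16 * pass;
      static thread_local std::vector<size_t> cnt;
      cnt.assign(65537, 0);
      for (const Hit& h : hits) cnt[((h.key >> shift) & 0xFFFF) + 1]++;
      for (int i = 0; i < 65536; ++i) cnt[i + 1] += cnt[i];
      for (const Hit& h : hits) tmp[cnt[(h.key >> shift) & 0xFFFF]++] = h;
      std::swap(hits, tmp);
    }
    size_t n = hits.size();
    for (size_t a = 0; a < n; ) {
      size_t b = a + 1;
      uint64_t key = hits[a].key;
      int maxdone = -1, streak = 0;
      int g = (int)(key >> 30);          // gg >> 1
      int strand = (int)((key >> 29) & 1ULL);
      int d = (int)(key & ((1ULL << 29) - 1)) - DOFF;
      const char* q = qs[strand];
      const char* s = sp[g];
      int slen = sl[g];
      while (b < n && hits[b].key == key) {
        int last = hits[b - 1].qpos, qp = hits[b].qpos;
        int gap = qp - last;
        bool fire = false;
        if (gap == 1) {
          if (++streak >= 2) fire = true;
        } else {
          streak = 0;
          if (gap >= 2 && gap <= max_gap) fire = true;
        }
        // only evaluations whose second hit is in the chunk proper; pairs
        // fully inside the overlap were handled by the previous chunk
        if (fire && qp >= chunk) {
          int lo = qp - max_gap; if (lo < 0) lo = 0;
          int hi = last; if (hi > L - width) hi = L - width;
          int startj = maxdone + 1; if (startj < lo) startj = lo;
          for (int j = startj; j <= hi; ++j) {
            int ci = strand == 0 ? cand_at[j] : cand_at[L - width - j];
            if (ci < 0 || out[ci] >= threshold) continue;
            int m = eval_window(q + j, width, s, slen, d + j, trigger,
                                hicut, pad);
            double id = (double)m / (double)width;
            if (id > out[ci]) out[ci] = id;
          }
          if (hi > maxdone) maxdone = hi;
        }
        ++b;
      }
      a = b;
    }
  }
  return out;
}
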