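#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Exhaustive unique-hit Hamming alignment of short reads against a small
// transcriptome, forward strand only. A read is reported iff it has exactly
// one alignment position within its minimal-mismatch stratum at <= max_mm
// mismatches. Candidate positions come from a seed index (three disjoint
// k-mer seeds per read; with <= 2 mismatches at least one seed is exact by
// pigeonhole); reads too short to carry three seeds fall back to a full
// scan, so the procedure is exact, not heuristic.

static const int K = 8;
static const uint32_t NK = 1u << (2 * K); // 4^K buckets

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N: never matches
  }
}

struct RefIndex {
  std::string cat;            // concatenated transcripts
  std::vector<int> tstart;    // start offset of each transcript in cat
  std::vector<int> tlen;
  std::vector<int> bucket_start; // CSR over NK+1
  std::vector<int> bucket_pos;   // concatenated positions (in cat) per k-mer
};

static void build_index(const CharacterVector& refs, RefIndex& ix) {
  int nt = refs.size();
  ix.tstart.resize(nt);
  ix.tlen.resize(nt);
  size_t total = 0;
  for (int i = 0; i < nt; i++) total += LENGTH(STRING_ELT(refs, i));
  ix.cat.reserve(total);
  for (int i = 0; i < nt; i++) {
    ix.tstart[i] = (int)ix.cat.size();
    const char* s = CHAR(STRING_ELT(refs, i));
    ix.tlen[i] = (int)strlen(s);
    ix.cat.append(s);
  }
  // count k-mers per bucket, then fill (CSR)
  std::vector<int> cnt(NK + 1, 0);
  int n = (int)ix.cat.size();
  std::vector<int8_t> code(n);
  for (int i = 0; i < n; i++) code[i] = (int8_t)base_code(ix.cat[i]);
  // positions valid for a k-mer: inside one transcript
  std::vector<uint32_t> kmer(n, UINT32_MAX);
  for (int t = 0; t < (int)ix.tstart.size(); t++) {
    int s = ix.tstart[t], e = s + ix.tlen[t];
    uint32_t h = 0; int run = 0;
    for (int i = s; i < e; i++) {
      int c = code[i];
      if (c > 3) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t)c) & (NK - 1);
      run++;
      if (run >= K) kmer[i - K + 1] = h;
    }
  }
  for (int i = 0; i < n; i++) if (kmer[i] != UINT32_MAX) cnt[kmer[i] + 1]++;
  for (uint32_t b = 0; b < NK; b++) cnt[b + 1] += cnt[b];
  ix.bucket_start = cnt;
  ix.bucket_pos.resize(cnt[NK]);
  std::vector<int> fill(ix.bucket_start.begin(), ix.bucket_start.end() - 1);
  for (int i = 0; i < n; i++)
    if (kmer[i] != UINT32_MAX) ix.bucket_pos[fill[kmer[i]]++] = i;
}

static inline int transcript_of(const RefIndex& ix, int pos) {
  // index of last tstart <= pos
  int lo = 0, hi = (int)ix.tstart.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (ix.tstart[mid] <= pos) lo = mid; else hi = mid - 1;
  }
  return lo;
}

static inline int hamming_leq(const char* a, const char* b, int len, int maxmm) {
  int mm = 0;
  for (int i = 0; i < len; i++) {
    char x = a[i], y = b[i];
    if (x != y || x == 'N' || x == 'n') {
      if (++mm > maxmm) return maxmm + 1;
    }
  }
  return mm;
}

struct Hit { int best_mm, n_best, tid, pos; };

static void score_candidates(const RefIndex& ix, const char* read, int rl,
                             std::vector<int>& cand, int maxmm, Hit& h) {
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  for (int start : cand) {
    if (start < 0 || start + rl > (int)ix.cat.size()) continue;
    int t = transcript_of(ix, start);
    if (start + rl > ix.tstart[t] + ix.tlen[t]) continue; // spans transcripts
    int mm = hamming_leq(ix.cat.c_str() + start, read, rl, maxmm);
    if (mm > maxmm) continue;
    if (mm < h.best_mm) {
      h.best_mm = mm; h.n_best = 1; h.tid = t; h.pos = start - ix.tstart[t];
    } else if (mm == h.best_mm) {
      h.n_best++;
    }
  }
}

// [[Rcpp::export]]
DataFrame align_hamming_cpp(CharacterVector reads, CharacterVector refs,
                            int max_mm = 2) {
  RefIndex ix;
  build_index(refs, ix);
  int nr = reads.size();
  IntegerVector tid(nr), pos(nr), mm(nr), nbest(nr);
  std::vector<int> cand;
  for (int r = 0; r < nr; r++) {
    const char* rd = CHAR(STRING_ELT(reads, r));
    int rl = LENGTH(STRING_ELT(reads, r));
    Hit h = { max_mm + 1, 0, -1, -1 };
    if (rl >= 3 * K && max_mm <= 2) {
      cand.clear();
      int offs[3] = { 0, rl / 2 - K / 2, rl - K };
      // ensure disjoint (rl >= 24 guarantees it for K = 8)
      for (int s = 0; s < 3; s++) {
        uint32_t hsh = 0; bool ok = true;
        for (int i = 0; i < K; i++) {
          int c = base_code(rd[offs[s] + i]);
          if (c > 3) { ok = false; break; }
          hsh = (hsh << 2) | (uint32_t)c;
        }
        if (!ok) continue;
        for (int j = ix.bucket_start[hsh]; j < ix.bucket_start[hsh + 1]; j++)
          cand.push_back(ix.bucket_pos[j] - offs[s]);
      }
      score_candidates(ix, rd, rl, cand, max_mm, h);
    } else {
      // short read (or relaxed mismatch cap): full scan
      cand.clear();
      for (int t = 0; t < (int)ix.tstart.size(); t++)
        for (int p = 0; p + rl <= ix.tlen[t]; p++)
          cand.push_back(ix.tstart[t] + p);
      score_candidates(ix, rd, rl, cand, max_mm, h);
    }
    if (h.n_best == 0) {
      tid[r] = NA_INTEGER; pos[r] = NA_INTEGER; mm[r] = NA_INTEGER; nbest[r] = 0;
    } else {
      tid[r] = h.tid + 1; // 1-based transcript index
      pos[r] = h.pos;     // 0-based within transcript
      mm[r] = h.best_mm;
      nbest[r] = h.n_best;
    }
  }
  return DataFrame::create(_["tid"] = tid, _["pos"] = pos,
                           _["mismatches"] = mm, _["n_best"] = nbest);
}
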