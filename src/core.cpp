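#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// DNA/RNA alphabet helpers. T and U are equivalent everywhere; anything else
// (including N) never pairs and never matches.
static inline int baseIdx(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  }
  return -1;
}

static inline double pairWeight(int x, int y, double wGC, double wAU, double wGU) {
  if (x < 0 || y < 0) return 0.0;
  if ((x == 0 && y == 3) || (x == 3 && y == 0)) return wAU;
  if ((x == 1 && y == 2) || (x == 2 && y == 1)) return wGC;
  if ((x == 2 && y == 3) || (x == 3 && y == 2)) return wGU;
  return 0.0;
}

static inline char compBase(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': case 'U': return 'A';
  }
  return 'N';
}

static std::string revcompStr(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = compBase(r[i]);
  return r;
}

// Base-pair maximisation (Nussinov) over {AU, GC, GU} with minimum hairpin
// loop of 3 unpaired bases. Pair weights are configurable so the same kernel
// serves plain pair counting (all weights 1) and the weighted GC3/AU2/GU1
// scoring used by the accessibility predictor. `blocked` lists 1-based
// positions that are forbidden from pairing (site-accessibility constraint).
// Traceback is deterministic: at every interval the leftmost base is paired
// to the smallest admissible partner among optimal choices.
// [[Rcpp::export]]
List cpp_nussinov(std::string seq, double wGC, double wAU, double wGU,
                  IntegerVector blocked) {
  const int n = (int) seq.size();
  const int minLoop = 3;
  std::vector<int> b(n);
  for (int i = 0; i < n; ++i) b[i] = baseIdx(seq[i]);
  std::vector<bool> blk(n, false);
  for (int i = 0; i < blocked.size(); ++i) {
    int p = blocked[i] - 1;
    if (p >= 0 && p < n) blk[p] = true;
  }
  if (n < minLoop + 2) {
    return List::create(_["score"] = 0.0,
                        _["pairs"] = IntegerMatrix(0, 2));
  }
  std::vector<double> S((size_t) n * n, 0.0);
  #define AT(i, j) S[(size_t)(i) * n + (j)]
  for (int len = minLoop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = AT(i + 1, j);
      if (!blk[i]) {
        for (int k = i + minLoop + 1; k <= j; ++k) {
          if (blk[k]) continue;
          double w = pairWeight(b[i], b[k], wGC, wAU, wGU);
          if (w <= 0.0) continue;
          double s = w + ((i + 1 <= k - 1) ? AT(i + 1, k - 1) : 0.0) +
                         ((k < j) ? AT(k + 1, j) : 0.0);
          if (s > best) best = s;
        }
      }
      AT(i, j) = best;
    }
  }
  // deterministic traceback
  std::vector<std::pair<int, int> > pairs;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < minLoop + 1) continue;
    double cur = AT(i, j);
    if (cur <= 0.0) continue;
    bool done = false;
    if (!blk[i]) {
      // stem-biased deterministic tie-break: among score-optimal partners
      // of i, take the outermost (largest k), so degenerate optima resolve
      // to long nested stems rather than branched local hairpins
      for (int k = j; k >= i + minLoop + 1 && !done; --k) {
        if (blk[k]) continue;
        double w = pairWeight(b[i], b[k], wGC, wAU, wGU);
        if (w <= 0.0) continue;
        double s = w + ((i + 1 <= k - 1) ? AT(i + 1, k - 1) : 0.0) +
                       ((k < j) ? AT(k + 1, j) : 0.0);
        if (s == cur) {
          pairs.push_back(std::make_pair(i + 1, k + 1));
          if (i + 1 <= k - 1) stack.push_back(std::make_pair(i + 1, k - 1));
          if (k < j) stack.push_back(std::make_pair(k + 1, j));
          done = true;
        }
      }
    }
    if (!done) stack.push_back(std::make_pair(i + 1, j));
  }
  #undef AT
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix pm((int) pairs.size(), 2);
  for (size_t i = 0; i < pairs.size(); ++i) {
    pm(i, 0) = pairs[i].first;
    pm(i, 1) = pairs[i].second;
  }
  double sc = S[(size_t) 0 * n + (n - 1)];
  return List::create(_["score"] = sc, _["pairs"] = pm);
}

// ---------------------------------------------------------------------------
// Seed-and-extend short-read mapper: ungapped, <=1 mismatch, all best loci
// reported, multi-mappers above max_hits discarded.
// Reads of length >= 2*kLong are seeded with their first and last
// kLong-mer; shorter reads fall back to kShort so that the two-seed pigeonhole
// argument still guarantees detection of every <=1-mismatch locus.

struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<int> > tab;
};

static bool encodeKmer(const char* s, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = baseIdx(s[i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t) b;
  }
  out = v;
  return true;
}

static void buildKIndex(const std::string& g, const std::vector<int>& offs,
                        const std::vector<int>& lens, int k, KmerIndex& idx) {
  idx.k = k;
  for (size_t s = 0; s < offs.size(); ++s) {
    int off = offs[s], len = lens[s];
    for (int p = 0; p + k <= len; ++p) {
      uint64_t code;
      if (encodeKmer(g.data() + off + p, k, code)) idx.tab[code].push_back(off + p);
    }
  }
}

struct Hit { int start; char strand; int mm; };

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector scaffolds,
                   int kLong, int kShort, int maxMm, int maxHits) {
  const int nScaf = scaffolds.size();
  std::vector<int> offs(nScaf), lens(nScaf);
  std::string g;
  {
    size_t tot = 0;
    for (int s = 0; s < nScaf; ++s) tot += std::string(scaffolds[s]).size();
    g.reserve(tot);
  }
  for (int s = 0; s < nScaf; ++s) {
    std::string sc = as<std::string>(scaffolds[s]);
    offs[s] = (int) g.size();
    lens[s] = (int) sc.size();
    g += sc;
  }
  const int G = (int) g.size();
  KmerIndex idxL, idxS;
  buildKIndex(g, offs, lens, kLong, idxL);
  buildKIndex(g, offs, lens, kShort, idxS);

  const int nReads = reads.size();
  std::vector<int> o_read, o_scaf, o_start, o_end, o_mm;
  std::vector<char> o_strand;
  IntegerVector status(nReads);  // 0 unmapped, 1 mapped, 2 multimapper discarded

  for (int r = 0; r < nReads; ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int L = (int) rd.size();
    if (L < kShort) { status[r] = 0; continue; }
    const KmerIndex& idx = (L >= 2 * kLong) ? idxL : idxS;
    const int k = idx.k;
    std::vector<Hit> hits;
    for (int strand = 0; strand < 2; ++strand) {
      std::string s = strand == 0 ? rd : revcompStr(rd);
      std::vector<int> cand;
      uint64_t code;
      if (encodeKmer(s.data(), k, code)) {
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
          idx.tab.find(code);
        if (it != idx.tab.end())
          for (size_t q = 0; q < it->second.size(); ++q) cand.push_back(it->second[q]);
      }
      if (encodeKmer(s.data() + (L - k), k, code)) {
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
          idx.tab.find(code);
        if (it != idx.tab.end())
          for (size_t q = 0; q < it->second.size(); ++q) {
            int p = it->second[q] - (L - k);
            if (p >= 0) cand.push_back(p);
          }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (size_t q = 0; q < cand.size(); ++q) {
        int p = cand[q];
        if (p < 0 || p + L > G) continue;
        // must lie within one scaffold
        int si = (int)(std::upper_bound(offs.begin(), offs.end(), p) - offs.begin()) - 1;
        if (p + L > offs[si] + lens[si]) continue;
        int mm = 0;
        bool ok = true;
        for (int q2 = 0; q2 < L; ++q2) {
          if (s[q2] != g[p + q2]) { if (++mm > maxMm) { ok = false; break; } }
        }
        if (ok) {
          Hit h; h.start = p; h.strand = strand == 0 ? '+' : '-'; h.mm = mm;
          hits.push_back(h);
        }
      }
    }
    if (hits.empty()) { status[r] = 0; continue; }
    int best = maxMm + 1;
    for (size_t q = 0; q < hits.size(); ++q) best = std::min(best, hits[q].mm);
    std::vector<Hit> keep;
    for (size_t q = 0; q < hits.size(); ++q)
      if (hits[q].mm == best) keep.push_back(hits[q]);
    if ((int) keep.size() > maxHits) { status[r] = 2; continue; }
    status[r] = 1;
    for (size_t q = 0; q < keep.size(); ++q) {
      int p = keep[q].start;
      int si = (int)(std::upper_bound(offs.begin(), offs.end(), p) - offs.begin()) - 1;
      o_read.push_back(r + 1);
      o_scaf.push_back(si + 1);
      o_start.push_back(p - offs[si] + 1);  // 1-based local
      o_end.push_back(p - offs[si] + L);
      o_strand.push_back(keep[q].strand);
      o_mm.push_back(keep[q].mm);
    }
  }
  const int nOut = (int) o_read.size();
  IntegerVector vread(nOut), vscaf(nOut), vstart(nOut), vend(nOut), vmm(nOut);
  CharacterVector vstrand(nOut);
  for (int i = 0; i < nOut; ++i) {
    vread[i] = o_read[i]; vscaf[i] = o_scaf[i]; vstart[i] = o_start[i];
    vend[i] = o_end[i]; vmm[i] = o_mm[i];
    vstrand[i] = std::string(1, o_strand[i]);
  }
  return List::create(_["read"] = vread, _["scaf"] = vscaf,
                      _["start"] = vstart, _["end"] = vend,
                      _["strand"] = vstrand, _["mm"] = vmm,
                      _["status"] = status);
}

// 3' adapter search: leftmost read position where a prefix of the adapter
// aligns to the read suffix with mismatch fraction <= maxErr and overlap >=
// minOverlap. Returns the number of bases to keep (read length if untrimmed).
// [[Rcpp::export]]
IntegerVector cpp_trim_adapter(CharacterVector reads, std::string adapter,
                               int minOverlap, double maxErr) {
  const int alen = (int) adapter.size();
  IntegerVector keep(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    const int L = (int) r.size();
    int cut = L;
    for (int p = 0; p < L; ++p) {
      int ov = std::min(alen, L - p);
      if (ov < minOverlap) break;
      int allow = (int) std::floor(maxErr * ov + 1e-9);
      int mm = 0;
      bool ok = true;
      for (int q = 0; q < ov; ++q) {
        if (r[p + q] != adapter[q]) { if (++mm > allow) { ok = false; break; } }
      }
      if (ok) { cut = p; break; }
    }
    keep[i] = cut;
  }
  return keep;
}
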