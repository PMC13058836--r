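// Banded semi-global alignment of short amplicon reads, fragment-level
// pileup reconciliation and bulk quantification.
//
// Alignment model: the read is aligned end-to-end, the reference has free
// end gaps (the amplicon is the known, short reference). Unit costs for
// mismatch and gap. A k-mer seed proposes candidate diagonals; an exact
// match along a seeded diagonal is accepted outright (edit distance 0 is
// globally optimal), otherwise the DP runs in a band of half-width
// `halfBand` around each candidate and the best alignment is kept. When
// no seed hits, or the best banded distance stays large, an unrestricted
// DP is run so banding never loses a recoverable alignment.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int INF = 1 << 28;
static const int SEED_K = 12;
// above this banded distance re-run without a band: a spurious seed
// diagonal may have been used
static const int FULLDP_RESCUE = 6;

static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char compBase(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static std::vector<int8_t> encode(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t)baseCode(s[i]);
  return v;
}

struct RefIndex {
  std::string seq;
  std::vector<int8_t> code;
  std::unordered_map<uint32_t, std::vector<int>> pos;  // 0-based starts

  void build(const std::string& r) {
    seq = r;
    code = encode(r);
    pos.clear();
    const int n = (int)r.size();
    if (n < SEED_K) return;
    uint32_t key = 0;
    const uint32_t mask = (1u << (2 * SEED_K)) - 1u;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int c = code[(size_t)i];
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)c) & mask;
      if (++valid >= SEED_K) pos[key].push_back(i - SEED_K + 1);
    }
  }
};

static bool kmerKey(const std::vector<int8_t>& rc, int at, uint32_t* key) {
  if (at < 0 || at + SEED_K > (int)rc.size()) return false;
  uint32_t k = 0;
  for (int i = 0; i < SEED_K; ++i) {
    int c = rc[(size_t)(at + i)];
    if (c < 0) return false;
    k = (k << 2) | (uint32_t)c;
  }
  *key = k;
  return true;
}

// One aligned call on the reference: code 0..3 = base, 4 = deletion.
// readPos is the 0-based read index providing the base (-1 for deletions).
struct RefCall {
  int refPos;
  int code;
  int readPos;
};

struct Aln {
  bool ok = false;
  int edist = INF;
  int refStart = 0;              // 0-based first aligned reference column
  std::vector<RefCall> calls;    // ascending refPos
  std::vector<int> insAnchors;   // 0-based ref column following an insertion
};

// Banded DP around diagonal d (ref_col ~ read_row + d). Physical column
// t = j - i - d + halfBand + 1 is constant along a diagonal; t = 0 and
// t = W-1 are INF sentinels.
static void bandedAlign(const std::vector<int8_t>& rc,
                        const std::vector<int8_t>& refc, int d, int halfBand,
                        Aln* out) {
  const int m = (int)rc.size(), n = (int)refc.size();
  const int W = 2 * halfBand + 3;
  std::vector<int> D((size_t)(m + 1) * W, INF);

  {
    int* row0 = D.data();
    for (int t = 1; t <= 2 * halfBand + 1; ++t) {
      int j = t + d - halfBand - 1;
      if (j >= 0 && j <= n) row0[t] = 0;  // free reference prefix
    }
  }
  for (int i = 1; i <= m; ++i) {
    int* cur = D.data() + (size_t)i * W;
    const int* prev = cur - W;
    const int jlo = std::max(0, i + d - halfBand);
    const int jhi = std::min(n, i + d + halfBand);
    if (jlo > jhi) continue;
    int t = jlo - i - d + halfBand + 1;
    const int8_t ci = rc[(size_t)(i - 1)];
    int j = jlo;
    if (j == 0) {  // read prefix consumed against nothing
      cur[t] = i;
      ++j; ++t;
    }
    const int8_t* rj = refc.data() + (j - 1);
    for (; j <= jhi; ++j, ++t, ++rj) {
      int best = prev[t] + (ci == *rj ? 0 : 1);   // diagonal
      int up = prev[t + 1] + 1;                    // insertion in read
      if (up < best) best = up;
      int left = cur[t - 1] + 1;                   // deletion
      if (left < best) best = left;
      cur[t] = best;
    }
  }

  // free reference suffix: best cell in the last row
  int bestJ = -1, bestV = INF;
  {
    const int* last = D.data() + (size_t)m * W;
    const int jlo = std::max(0, m + d - halfBand);
    const int jhi = std::min(n, m + d + halfBand);
    for (int j = jlo; j <= jhi; ++j) {
      int v = last[j - m - d + halfBand + 1];
      if (v < bestV) { bestV = v; bestJ = j; }
    }
  }
  if (bestJ < 0 || bestV >= out->edist) return;

  // traceback; deterministic preference: diagonal, then insertion, then
  // deletion (ties resolved toward substitutions)
  out->ok = true;
  out->edist = bestV;
  out->calls.clear();
  out->insAnchors.clear();
  auto cell = [&](int i, int j) -> int {
    int t = j - i - d + halfBand + 1;
    if (t < 0 || t >= W) return INF;
    return D[(size_t)i * W + t];
  };
  int i = m, j = bestJ;
  bool prevIns = false;
  while (i > 0) {
    const int cur = cell(i, j);
    const int8_t ci = rc[(size_t)(i - 1)];
    bool moved = false;
    if (j > 0) {
      int v = cell(i - 1, j - 1);
      int sub = (ci >= 0 && ci == refc[(size_t)(j - 1)]) ? 0 : 1;
      if (v < INF && v + sub == cur) {
        out->calls.push_back({j - 1, (int)ci, i - 1});
        --i; --j;
        prevIns = false;
        moved = true;
      }
    }
    if (!moved) {
      int v = cell(i - 1, j);
      if (v < INF && v + 1 == cur) {
        if (!prevIns) out->insAnchors.push_back(j);
        prevIns = true;
        --i;
        moved = true;
      }
    }
    if (!moved && j > 0) {
      int v = cell(i, j - 1);
      if (v < INF && v + 1 == cur) {
        out->calls.push_back({j - 1, 4, -1});
        --j;
        prevIns = false;
        moved = true;
      }
    }
    if (!moved) stop("internal: alignment traceback failed");
  }
  out->refStart = j;
  std::reverse(out->calls.begin(), out->calls.end());
  std::reverse(out->insAnchors.begin(), out->insAnchors.end());
}

static void alignRead(const std::string& read, const RefIndex& ridx,
                      int halfBand, Aln* out) {
  const int m = (int)read.size(), n = (int)ridx.seq.size();
  out->ok = false;
  out->edist = INF;
  out->calls.clear();
  out->insAnchors.clear();
  const std::vector<int8_t> rc = encode(read);

  std::vector<int> diags;
  const int probes[3] = {0, m / 2 - SEED_K / 2, m - SEED_K};
  for (int p = 0; p < 3; ++p) {
    uint32_t key;
    if (!kmerKey(rc, probes[p], &key)) continue;
    auto it = ridx.pos.find(key);
    if (it == ridx.pos.end()) continue;
    for (int rp : it->second) {
      int d = rp - probes[p];
      bool seen = false;
      for (int e : diags)
        if (std::abs(e - d) <= halfBand / 2) { seen = true; break; }
      if (!seen && (int)diags.size() < 8) diags.push_back(d);
    }
  }

  // exact-match fast path along a seeded diagonal
  for (int d : diags) {
    if (d < 0 || d + m > n) continue;
    const int8_t* a = rc.data();
    const int8_t* b = ridx.code.data() + d;
    int mm = 0;
    for (int i = 0; i < m && mm == 0; ++i) mm += (a[i] != b[i]);
    if (mm == 0) {
      out->ok = true;
      out->edist = 0;
      out->refStart = d;
      out->calls.resize((size_t)m);
      for (int i = 0; i < m; ++i) out->calls[(size_t)i] = {d + i, a[i], i};
      return;
    }
  }

  for (int d : diags) bandedAlign(rc, ridx.code, d, halfBand, out);
  if (!out->ok || out->edist > FULLDP_RESCUE) {
    // no/poor seed support: unrestricted DP (band covering every column)
    bandedAlign(rc, ridx.code, 0, n + m, out);
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = compBase(c);
  return r;
}

// ---------------------------------------------------------------------------
// exported: single-read alignment (unit-level interface)

// [[Rcpp::export(name = ".cppAlignRead")]]
List cppAlignRead(std::string read, std::string ref, int halfBand,
                  double maxEditFrac) {
  RefIndex ridx;
  ridx.build(ref);
  Aln a;
  alignRead(read, ridx, halfBand, &a);
  const int m = (int)read.size();
  bool mapped = a.ok && a.edist <= (int)std::floor(maxEditFrac * m);
  IntegerMatrix calls((int)a.calls.size(), 3);
  for (int i = 0; i < (int)a.calls.size(); ++i) {
    calls(i, 0) = a.calls[(size_t)i].refPos + 1;  // 1-based for R
    calls(i, 1) = a.calls[(size_t)i].code;
    calls(i, 2) = a.calls[(size_t)i].readPos + 1;  // 0 => deletion
  }
  IntegerVector ins((int)a.insAnchors.size());
  for (int i = 0; i < (int)a.insAnchors.size(); ++i)
    ins[i] = a.insAnchors[(size_t)i] + 1;
  return List::create(_["mapped"] = mapped, _["edit_distance"] = a.edist,
                      _["offset"] = a.refStart, _["calls"] = calls,
                      _["insertion_anchors"] = ins);
}

// ---------------------------------------------------------------------------
// fragment reconciliation into a per-reference-column call array
//
// codes in the fragment array: -1 no call, -2 masked conflict, 0..4 call

static void addMateCalls(const Aln& a, const std::string& qual, int qualFloor,
                         int qualOffset, std::vector<int8_t>* frag) {
  for (const RefCall& rc : a.calls) {
    if (rc.code <= 3 && rc.readPos >= 0 && !qual.empty()) {
      int q = (int)qual[(size_t)rc.readPos] - qualOffset;
      if (q < qualFloor) continue;  // low-quality base: no call
    }
    int8_t& cell = (*frag)[(size_t)rc.refPos];
    if (cell == -1) cell = (int8_t)rc.code;
    else if (cell != (int8_t)rc.code) cell = -2;  // mates disagree: mask
  }
}

// [[Rcpp::export(name = ".cppQuantifyPairs")]]
List cppQuantifyPairs(CharacterVector r1, CharacterVector q1,
                      CharacterVector r2, CharacterVector q2,
                      std::string ref, int halfBand, double maxEditFrac,
                      int qualFloor, int qualOffset, IntegerVector watchPos) {
  const int n = (int)ref.size();
  const int nfrag = r1.size();
  if (r2.size() != nfrag || q1.size() != nfrag || q2.size() != nfrag)
    stop("R1/R2 record counts differ");
  RefIndex ridx;
  ridx.build(ref);

  IntegerMatrix counts(6, n);  // rows A,C,G,T,del,insStart
  const int nw = watchPos.size();
  IntegerMatrix watch(nfrag, std::max(nw, 0));
  std::fill(watch.begin(), watch.end(), -1);

  int nMappedFragments = 0, nUnmappedReads = 0;
  std::vector<int8_t> frag((size_t)n);
  std::vector<uint8_t> insSeen((size_t)n);
  Aln a;

  for (int f = 0; f < nfrag; ++f) {
    std::fill(frag.begin(), frag.end(), (int8_t)-1);
    std::fill(insSeen.begin(), insSeen.end(), (uint8_t)0);
    int matesMapped = 0;
    bool anyIns = false;

    for (int mate = 0; mate < 2; ++mate) {
      std::string s = as<std::string>(mate == 0 ? r1[f] : r2[f]);
      std::string q = as<std::string>(mate == 0 ? q1[f] : q2[f]);
      if (s.empty()) continue;
      if (mate == 1) {  // R2 is sequenced from the opposite strand
        s = revcomp(s);
        std::reverse(q.begin(), q.end());
      }
      alignRead(s, ridx, halfBand, &a);
      const int m = (int)s.size();
      if (!a.ok || a.edist > (int)std::floor(maxEditFrac * m)) {
        ++nUnmappedReads;
        continue;
      }
      ++matesMapped;
      addMateCalls(a, q, qualFloor, qualOffset, &frag);
      for (int anchor : a.insAnchors)
        if (anchor >= 0 && anchor < n) { insSeen[(size_t)anchor] = 1;
                                         anyIns = true; }
    }

    if (matesMapped > 0) ++nMappedFragments;
    for (int j = 0; j < n; ++j) {
      int8_t c = frag[(size_t)j];
      if (c >= 0) ++counts(c, j);
    }
    if (anyIns)
      for (int j = 0; j < n; ++j)
        if (insSeen[(size_t)j]) ++counts(5, j);
    for (int w = 0; w < nw; ++w) {
      int j = watchPos[w] - 1;  // 1-based in R
      if (j >= 0 && j < n) {
        int8_t c = frag[(size_t)j];
        watch(f, w) = (c >= 0) ? (int)c : -1;
      }
    }
  }

  return List::create(_["counts"] = counts,
                      _["n_fragments"] = nfrag,
                      _["n_mapped_fragments"] = nMappedFragments,
                      _["n_unmapped_reads"] = nUnmappedReads,
                      _["watch_calls"] = watch);
}

// ---------------------------------------------------------------------------
// adapter trimming: best 3' adapter match with <= 10% mismatches

// [[Rcpp::export(name = ".cppTrimStarts")]]
IntegerVector cppTrimStarts(CharacterVector reads, std::string adapter,
                            double maxMismFrac, int minLen) {
  const int alen = (int)adapter.size();
  IntegerVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    const int len = (int)s.size();
    int bestS = 0;           // 1-based trim start; 0 = no trim
    double bestRate = 2.0;
    for (int st = 0; st < len; ++st) {
      int L = std::min(alen, len - st);
      if (L < minLen) break;
      int mm = 0;
      for (int k = 0; k < L; ++k)
        if (s[(size_t)(st + k)] != adapter[(size_t)k]) ++mm;
      double rate = (double)mm / L;
      if (mm <= (int)std::floor(maxMismFrac * L) && rate < bestRate) {
        bestRate = rate;
        bestS = st + 1;
      }
    }
    out[i] = bestS;
  }
  return out;
}
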