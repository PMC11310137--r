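#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// 2-bit base codes; -1 for anything outside ACGT (N breaks k-mer windows).
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// ---------------------------------------------------------------------------
// Canonical k-mer extraction (lexicographic min of k-mer and reverse
// complement; windows containing non-ACGT characters are skipped).
// [[Rcpp::export(name = ".canonical_kmers_cpp")]]
CharacterVector canonical_kmers_cpp(CharacterVector seqs, int k) {
  if (k < 2 || k > 31) stop("k must be between 2 and 31");
  std::vector<std::string> out;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::string buf(k, 'A');
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *seq = CHAR(STRING_ELT(seqs, s));
    size_t n = std::strlen(seq);
    if ((int)n < k) continue;
    uint64_t fwd = 0, rc = 0;
    int valid = 0;
    for (size_t i = 0; i < n; ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++valid >= k) {
        uint64_t canon = fwd < rc ? fwd : rc;
        for (int b = k - 1; b >= 0; --b) {
          buf[b] = BASES[canon & 3ULL];
          canon >>= 2;
        }
        out.push_back(buf);
      }
    }
  }
  return wrap(out);
}

// Canonical k-mers of one sequence with their 0-based window positions.
// [[Rcpp::export(name = ".kmer_track_cpp")]]
List kmer_track_cpp(std::string seq, int k) {
  if (k < 2 || k > 31) stop("k must be between 2 and 31");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::vector<int> pos;
  std::vector<std::string> kmers;
  std::string buf(k, 'A');
  uint64_t fwd = 0, rc = 0;
  int valid = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++valid >= k) {
      uint64_t canon = fwd < rc ? fwd : rc;
      for (int b = k - 1; b >= 0; --b) {
        buf[b] = BASES[canon & 3ULL];
        canon >>= 2;
      }
      pos.push_back((int)(i - k + 1));
      kmers.push_back(buf);
    }
  }
  return List::create(_["pos"] = pos, _["kmer"] = wrap(kmers));
}

// ---------------------------------------------------------------------------
// Exact k-mer anchor hits between a query sequence and a set of target
// sequences.  Only k-mers occurring exactly once across all targets are used
// as anchors.  A '-' hit means query forward interval [qpos, qpos+k) matches
// target [tpos, tpos+k) reverse-complemented.  Positions are 0-based.
// [[Rcpp::export(name = ".anchor_hits_cpp")]]
DataFrame anchor_hits_cpp(CharacterVector targets, std::string query, int k) {
  if (k < 8 || k > 31) stop("anchor k must be between 8 and 31");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_map<uint64_t, int64_t> index;
  index.reserve(1 << 20);
  for (R_xlen_t t = 0; t < targets.size(); ++t) {
    const char *seq = CHAR(STRING_ELT(targets, t));
    size_t n = std::strlen(seq);
    uint64_t fwd = 0;
    int valid = 0;
    for (size_t i = 0; i < n; ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        uint64_t key = fwd;
        int64_t val = (((int64_t)t) << 40) | (int64_t)(i - k + 1);
        auto it = index.find(key);
        if (it == index.end()) index.emplace(key, val);
        else it->second = -1;  // duplicated k-mer: unusable as anchor
      }
    }
  }
  std::vector<int> qpos, tid, tpos;
  std::vector<int> strand;  // 1 = '+', 0 = '-'
  uint64_t fwd = 0, rc = 0;
  int valid = 0;
  size_t n = query.size();
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(query[i]);
    if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++valid >= k) {
      auto it = index.find(fwd);
      if (it != index.end() && it->second >= 0) {
        qpos.push_back((int)(i - k + 1));
        tid.push_back((int)(it->second >> 40) + 1);
        tpos.push_back((int)(it->second & ((1LL << 40) - 1)));
        strand.push_back(1);
      }
      it = index.find(rc);
      if (it != index.end() && it->second >= 0) {
        qpos.push_back((int)(i - k + 1));
        tid.push_back((int)(it->second >> 40) + 1);
        tpos.push_back((int)(it->second & ((1LL << 40) - 1)));
        strand.push_back(0);
      }
    }
  }
  CharacterVector strand_chr(strand.size());
  for (size_t i = 0; i < strand.size(); ++i)
    strand_chr[i] = strand[i] ? "+" : "-";
  return DataFrame::create(_["qpos"] = qpos, _["tid"] = tid,
                           _["tpos"] = tpos, _["strand"] = strand_chr,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Banded global alignment with affine gap costs (Gotoh), returning a
// minimap2 short-form cs difference string with the target as reference.
// The band is adaptively doubled when the optimal path touches its edge.

static const int INF = 1 << 28;

struct AlnResult {
  std::string cs;
  int cost;
  int n_match;
  bool touched;
  bool ok;
};

static AlnResult banded_align_once(const std::string &target,
                                   const std::string &query,
                                   int w, int mismatch, int gap_open,
                                   int gap_extend) {
  AlnResult res;
  res.ok = false;
  res.touched = false;
  const int n = (int)target.size();
  const int m = (int)query.size();
  const int mdiff = m - n;
  const int lo = std::min(0, mdiff) - w;
  const int hi = std::max(0, mdiff) + w;
  const int W = hi - lo + 1;
  const double cells = (double)(n + 1) * (double)W;
  if (cells > 1.6e9) stop("alignment band too large (%d x %d)", n + 1, W);

  // Backpointers: bits 0-1 M-source (0 M, 1 I, 2 D, 3 none);
  // bit 2 I-source (0 open-from-M, 1 extend); bit 3 D-source (0 M, 1 D).
  std::vector<uint8_t> ptr((size_t)(n + 1) * W, 0);
  std::vector<int> Mp(W, INF), Ip(W, INF), Dp(W, INF);
  std::vector<int> Mc(W, INF), Ic(W, INF), Dc(W, INF);

  // Row 0
  for (int o = 0; o < W; ++o) {
    int j = 0 + lo + o;
    if (j < 0 || j > m) continue;
    if (j == 0) { Mp[o] = 0; }
    else {
      Ip[o] = gap_open + j * gap_extend;
      ptr[(size_t)0 * W + o] |= (j > 1 ? 4 : 0);
    }
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(Mc.begin(), Mc.end(), INF);
    std::fill(Ic.begin(), Ic.end(), INF);
    std::fill(Dc.begin(), Dc.end(), INF);
    uint8_t *prow = &ptr[(size_t)i * W];
    for (int o = 0; o < W; ++o) {
      int j = i + lo + o;
      if (j < 0 || j > m) continue;
      uint8_t p = 0;
      // D: consume target base i (from row i-1, same j => offset o+1)
      if (o + 1 < W) {
        int fromM = Mp[o + 1] >= INF ? INF : Mp[o + 1] + gap_open + gap_extend;
        int fromD = Dp[o + 1] >= INF ? INF : Dp[o + 1] + gap_extend;
        if (fromD < fromM) { Dc[o] = fromD; p |= 8; }
        else if (fromM < INF) { Dc[o] = fromM; }
      }
      if (j == 0 && i > 0 && Dc[o] >= INF) {
        // left edge: pure-deletion prefix
        Dc[o] = gap_open + i * gap_extend;
        p |= (i > 1 ? 8 : 0);
      }
      // I: consume query base j (same row, offset o-1)
      if (j >= 1 && o - 1 >= 0) {
        int fromM = Mc[o - 1] >= INF ? INF : Mc[o - 1] + gap_open + gap_extend;
        int fromI = Ic[o - 1] >= INF ? INF : Ic[o - 1] + gap_extend;
        if (fromI < fromM) { Ic[o] = fromI; p |= 4; }
        else if (fromM < INF) { Ic[o] = fromM; }
      }
      // M: diagonal (row i-1, offset o)
      if (j >= 1) {
        int best = Mp[o]; uint8_t src = 0;
        if (Ip[o] < best) { best = Ip[o]; src = 1; }
        if (Dp[o] < best) { best = Dp[o]; src = 2; }
        if (best < INF) {
          int cq = base_code(query[j - 1]);
          int ct = base_code(target[i - 1]);
          int sub = (cq >= 0 && cq == ct) ? 0 : mismatch;
          Mc[o] = best + sub;
          p |= src;
        } else p |= 3;
      } else p |= 3;
      prow[o] = p;
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }
  const int oe = m - n - lo;
  int best = Mp[oe]; int state = 0;  // 0 M, 1 I, 2 D
  if (Ip[oe] < best) { best = Ip[oe]; state = 1; }
  if (Dp[oe] < best) { best = Dp[oe]; state = 2; }
  if (best >= INF) return res;

  // Traceback; ops: 0 match, 1 mismatch, 2 insertion, 3 deletion
  std::vector<uint8_t> ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int o = j - i - lo;
    if (j > 0 && j < m && (o == 0 || o == W - 1)) res.touched = true;
    uint8_t p = ptr[(size_t)i * W + o];
    if (state == 0) {
      int cq = base_code(query[j - 1]);
      int ct = base_code(target[i - 1]);
      ops.push_back((cq >= 0 && cq == ct) ? 0 : 1);
      state = p & 3;
      --i; --j;
    } else if (state == 1) {
      ops.push_back(2);
      state = (p & 4) ? 1 : 0;
      --j;
    } else {
      ops.push_back(3);
      state = (p & 8) ? 2 : 0;
      --i;
    }
  }
  // Build cs string (forward order)
  std::string cs;
  cs.reserve(ops.size() / 4 + 16);
  int ti = 0, qi = 0, run = 0, nm = 0;
  auto flush_match = [&]() {
    if (run > 0) { cs += ':'; cs += std::to_string(run); run = 0; }
  };
  for (int idx = (int)ops.size() - 1; idx >= 0; --idx) {
    uint8_t op = ops[idx];
    if (op == 0) { ++run; ++nm; ++ti; ++qi; }
    else if (op == 1) {
      flush_match();
      cs += '*';
      cs += (char)std::tolower(target[ti]);
      cs += (char)std::tolower(query[qi]);
      ++ti; ++qi;
    } else if (op == 2) {
      flush_match();
      cs += '+';
      while (idx >= 0 && ops[idx] == 2) {
        cs += (char)std::tolower(query[qi]); ++qi; --idx;
      }
      ++idx;
    } else {
      flush_match();
      cs += '-';
      while (idx >= 0 && ops[idx] == 3) {
        cs += (char)std::tolower(target[ti]); ++ti; --idx;
      }
      ++idx;
    }
  }
  flush_match();
  res.cs = cs;
  res.cost = best;
  res.n_match = nm;
  res.ok = true;
  return res;
}

// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string target, std::string query,
                      int band = 64, int max_band = 4096,
                      int mismatch = 4, int gap_open = 12,
                      int gap_extend = 1) {
  // A path confined to a too-narrow band is not always detectable from the
  // band edge alone, so widen until the cost stops improving (or the cap).
  int w = std::max(8, band);
  AlnResult res = banded_align_once(target, query, w, mismatch, gap_open,
                                    gap_extend);
  while (w < max_band) {
    int w2 = std::min(max_band, w * 2);
    AlnResult res2 = banded_align_once(target, query, w2, mismatch, gap_open,
                                       gap_extend);
    bool stable = res.ok && res2.ok && res2.cost == res.cost &&
      !res2.touched;
    res = res2;
    w = w2;
    if (stable) break;
  }
  if (!res.ok) stop("banded alignment failed (band %d)", w);
  return List::create(_["cs"] = res.cs, _["cost"] = res.cost,
                      _["n_match"] = res.n_match, _["band"] = w,
                      _["touched"] = res.touched);
}
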