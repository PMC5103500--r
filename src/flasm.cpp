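// Bit-parallel cores for fixed-length approximate string matching (FLASM).
//
// Both cores operate on ell-bit state vectors packed into 64-bit words so
// that factor lengths well beyond the machine word are supported; the word
// loops below are the only place the ceil(ell/w) factor of the run time
// lives.
//
//  * Hamming model: MaxShiftM-style DP. One column of m+1 mismatch vectors
//    is kept while the text is streamed; cell update is
//      M[i][j] = (M[i-1][j-1] << 1) | (x[i-1] != t[j-1]),
//    truncated to ell bits, and popcount(M[i][j]) is the Hamming distance
//    of the two length-ell windows ending at i and j once both are full.
//  * Edit model: Myers' bit-vector approximate matcher run once per
//    length-ell factor of the pattern (semi-global: text start is free),
//    with carry-propagating multi-word addition in the Xh chain.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

typedef uint64_t u64;
static const int WBITS = 64;

static inline int nwords(int ell) { return (ell + WBITS - 1) / WBITS; }
static inline u64 topmask(int ell) {
  int r = ell % WBITS;
  return r ? ((u64(1) << r) - 1) : ~u64(0);
}

// dst = (src << 1) | b, truncated to ell bits (mask applies to last word)
static inline void shl1_or(const u64* src, u64* dst, int nw, u64 mask, u64 b) {
  u64 carry = b & 1;
  for (int w = 0; w < nw; ++w) {
    u64 v = src[w];
    dst[w] = (v << 1) | carry;
    carry = v >> (WBITS - 1);
  }
  dst[nw - 1] &= mask;
}

static inline int popcnt_mw(const u64* v, int nw) {
  int s = 0;
  for (int w = 0; w < nw; ++w) s += __builtin_popcountll(v[w]);
  return s;
}

// dst = (a + b) mod 2^ell, carries propagate across word boundaries
static inline void add_mw(const u64* a, const u64* b, u64* dst, int nw, u64 mask) {
  u64 carry = 0;
  for (int w = 0; w < nw; ++w) {
    u64 s = a[w] + b[w];
    u64 c1 = (s < a[w]) ? 1 : 0;
    u64 s2 = s + carry;
    u64 c2 = (s2 < s) ? 1 : 0;
    dst[w] = s2;
    carry = c1 | c2;
  }
  dst[nw - 1] &= mask;
}

static inline bool getbit_mw(const u64* v, int p) {
  return (v[p / WBITS] >> (p % WBITS)) & 1;
}

// ---------------------------------------------------------------------------
// Hamming core (MaxShiftM)
// ---------------------------------------------------------------------------

// Shared scan. For every (i, j) with i >= ell, j >= ell (1-based) the
// popcount of the current cell is delta_H of the two windows; `emit` is
// called with 0-based ending positions.
//
// The text is consumed in blocks of BCOLS columns and the state vectors are
// swept one 64-bit word plane at a time: plane 0 shifts in the mismatch
// bits (taken from per-letter text masks), each later plane shifts in the
// carries its predecessor recorded in a per-block bit matrix, and every
// plane adds its words' popcounts into a per-block count matrix the match
// region is then read from. Per-pattern-row state across blocks is one
// column of BitRows, so space stays O(m ceil(ell/w)) with the text
// streamed, and the work per cell is the O(ceil(ell/w)) word loop.
static const int BCOLS = 256;            // text columns per block
static const int BW = BCOLS / WBITS;

template <class Emit>
static void hamming_scan(const std::string& t, const std::string& x, int ell,
                         Emit emit) {
  const int n = (int)t.size(), m = (int)x.size();
  const int nw = nwords(ell);
  const u64 mask = topmask(ell);
  std::vector<u64> boundary((size_t)(m + 1) * nw, 0),
      nextb((size_t)(m + 1) * nw, 0);
  std::vector<u64> peq((size_t)256 * BW);
  std::vector<u64> cin_((size_t)(m + 1) * BW), cout_((size_t)(m + 1) * BW);
  std::vector<u64> pcol(m + 1);
  std::vector<int> pc((size_t)BCOLS * (m + 1));
  for (int j0 = 1; j0 <= n; j0 += BCOLS) {
    const int L = std::min(BCOLS, n - j0 + 1);
    std::fill(peq.begin(), peq.end(), 0);
    for (int jl = 0; jl < L; ++jl)
      peq[(size_t)(unsigned char)t[j0 - 1 + jl] * BW + (jl >> 6)] |=
          u64(1) << (jl & 63);
    u64* bufs[2] = {cin_.data(), cout_.data()};
    const u64* cin = NULL;
    for (int w = 0; w < nw; ++w) {
      const bool top = (w == nw - 1);
      u64* co = bufs[w & 1];
      std::fill(co, co + (size_t)(m + 1) * BW, 0);
      for (int i = 0; i <= m; ++i) pcol[i] = boundary[(size_t)i * nw + w];
      for (int jl = 0; jl < L; ++jl) {
        const int jw = jl >> 6, jb = jl & 63;
        u64 diag = pcol[0];                // row 0 stays zero
        int* pcj = &pc[(size_t)jl * (m + 1)];
        if (w == 0) {
          for (int i = 1; i <= m; ++i) {
            u64 vi = pcol[i];
            u64 cb = (~peq[(size_t)(unsigned char)x[i - 1] * BW + jw] >> jb) & 1;
            u64 nv = (diag << 1) | cb;
            if (top) nv &= mask;
            co[(size_t)i * BW + jw] |= (diag >> (WBITS - 1)) << jb;
            pcol[i] = nv;
            pcj[i] = __builtin_popcountll(nv);
            diag = vi;
          }
        } else {
          for (int i = 1; i <= m; ++i) {
            u64 vi = pcol[i];
            u64 cb = (cin[(size_t)i * BW + jw] >> jb) & 1;
            u64 nv = (diag << 1) | cb;
            if (top) nv &= mask;
            co[(size_t)i * BW + jw] |= (diag >> (WBITS - 1)) << jb;
            pcol[i] = nv;
            pcj[i] += __builtin_popcountll(nv);
            diag = vi;
          }
        }
      }
      for (int i = 0; i <= m; ++i) nextb[(size_t)i * nw + w] = pcol[i];
      cin = co;
    }
    for (int jl = 0; jl < L; ++jl) {
      const int j = j0 + jl;
      if (j < ell) continue;
      const int* pcj = &pc[(size_t)jl * (m + 1)];
      for (int i = ell; i <= m; ++i) emit(j - 1, i - 1, pcj[i]);
    }
    std::swap(boundary, nextb);
  }
}

// ---------------------------------------------------------------------------
// Edit core (Myers per pattern factor)
// ---------------------------------------------------------------------------

// Scan text t against the window win[0..ell-1]; scores[j] receives
// min over start positions s <= j of deltaE(t[s..j], win).
static void myers_scan(const std::string& t, const char* win, int ell, int nw,
                       u64 mask, std::vector<u64>& peq, std::vector<u64>& work,
                       std::vector<int>& scores) {
  const int n = (int)t.size();
  std::fill(peq.begin(), peq.end(), 0);
  for (int p = 0; p < ell; ++p) {
    unsigned char c = (unsigned char)win[p];
    peq[(size_t)c * nw + p / WBITS] |= u64(1) << (p % WBITS);
  }
  u64* Pv = &work[0];
  u64* Mv = &work[(size_t)nw];
  u64* Xv = &work[(size_t)2 * nw];
  u64* Xh = &work[(size_t)3 * nw];
  u64* Ph = &work[(size_t)4 * nw];
  u64* Mh = &work[(size_t)5 * nw];
  u64* Sm = &work[(size_t)6 * nw];
  for (int w = 0; w < nw; ++w) { Pv[w] = ~u64(0); Mv[w] = 0; }
  Pv[nw - 1] &= mask;
  int score = ell;
  const int hb = ell - 1;
  for (int j = 0; j < n; ++j) {
    const u64* Eq = &peq[(size_t)(unsigned char)t[j] * nw];
    // Sm = (Eq & Pv) + Pv, with multi-word carry
    u64 carry = 0;
    for (int w = 0; w < nw; ++w) {
      u64 X = Eq[w] & Pv[w];
      u64 s = X + Pv[w];
      u64 c1 = (s < X) ? 1 : 0;
      u64 s2 = s + carry;
      u64 c2 = (s2 < s) ? 1 : 0;
      Sm[w] = s2;
      carry = c1 | c2;
    }
    for (int w = 0; w < nw; ++w) {
      Xh[w] = (Sm[w] ^ Pv[w]) | Eq[w];
      Xv[w] = Eq[w] | Mv[w];
      Ph[w] = Mv[w] | ~(Xh[w] | Pv[w]);
      Mh[w] = Pv[w] & Xh[w];
    }
    Ph[nw - 1] &= mask;
    Mh[nw - 1] &= mask;
    if (getbit_mw(Ph, hb)) ++score;
    else if (getbit_mw(Mh, hb)) --score;
    // shift horizontal deltas up one row (bit 0 becomes the free first row)
    u64 cp = 0, cm = 0;
    for (int w = 0; w < nw; ++w) {
      u64 p0 = Ph[w], m0 = Mh[w];
      Ph[w] = (p0 << 1) | cp; cp = p0 >> (WBITS - 1);
      Mh[w] = (m0 << 1) | cm; cm = m0 >> (WBITS - 1);
    }
    Ph[nw - 1] &= mask;
    Mh[nw - 1] &= mask;
    for (int w = 0; w < nw; ++w) {
      Pv[w] = Mh[w] | ~(Xv[w] | Ph[w]);
      Mv[w] = Ph[w] & Xv[w];
    }
    Pv[nw - 1] &= mask;
    scores[j] = score;
  }
}

template <class Emit>
static void edit_scan_all(const std::string& t, const std::string& x, int ell,
                          Emit emit) {
  const int n = (int)t.size(), m = (int)x.size();
  const int nw = nwords(ell);
  const u64 mask = topmask(ell);
  std::vector<u64> peq((size_t)256 * nw, 0);
  std::vector<u64> work((size_t)7 * nw, 0);
  std::vector<int> scores(n, 0);
  for (int fi = ell; fi <= m; ++fi) {  // 1-based factor ending position
    myers_scan(t, x.data() + (fi - ell), ell, nw, mask, peq, work, scores);
    for (int j = 0; j < n; ++j) emit(j, fi - 1, scores[j]);
  }
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

static DataFrame tuples_df(std::vector<int>& j, std::vector<int>& i,
                           std::vector<int>& e) {
  return DataFrame::create(_["text_end"] = wrap(j), _["pattern_end"] = wrap(i),
                           _["distance"] = wrap(e));
}

// model: 0 = hamming, 1 = edit; best_only: keep single (e, j, i)-minimal tuple
// [[Rcpp::export]]
DataFrame cpp_flasm(std::string t, std::string x, int ell, int k, int model,
                    bool best_only) {
  std::vector<int> rj, ri, re;
  int be = k + 1, bj = -1, bi = -1;
  auto emit = [&](int j, int i, int e) {
    if (e > k) return;
    if (best_only) {
      if (e < be || (e == be && (j < bj || (j == bj && i < bi)))) {
        be = e; bj = j; bi = i;
      }
    } else {
      rj.push_back(j); ri.push_back(i); re.push_back(e);
    }
  };
  if (model == 0) hamming_scan(t, x, ell, emit);
  else edit_scan_all(t, x, ell, emit);
  if (best_only) {
    if (bj >= 0) { rj.push_back(bj); ri.push_back(bi); re.push_back(be); }
    return tuples_df(rj, ri, re);
  }
  if (model != 0) {
    // edit scan is factor-major; order rows by (text_end, pattern_end)
    std::vector<int> idx(rj.size());
    for (size_t p = 0; p < idx.size(); ++p) idx[p] = (int)p;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      if (rj[a] != rj[b]) return rj[a] < rj[b];
      return ri[a] < ri[b];
    });
    std::vector<int> sj(rj.size()), si(rj.size()), se(rj.size());
    for (size_t p = 0; p < idx.size(); ++p) {
      sj[p] = rj[idx[p]]; si[p] = ri[idx[p]]; se[p] = re[idx[p]];
    }
    return tuples_df(sj, si, se);
  }
  return tuples_df(rj, ri, re);
}

// Per pattern ending position i (0-based): minimal distance over all text
// positions, and the number of text positions with distance <= k.
// Entries for i < ell-1 are NA.
// [[Rcpp::export]]
List cpp_flasm_profile(std::string t, std::string x, int ell, int k,
                       int model) {
  const int m = (int)x.size();
  IntegerVector min_e(m, NA_INTEGER), hits(m, NA_INTEGER);
  for (int i = ell - 1; i < m; ++i) { min_e[i] = ell + 1; hits[i] = 0; }
  auto emit = [&](int j, int i, int e) {
    (void)j;
    if (e < min_e[i]) min_e[i] = e;
    if (e <= k) hits[i] = hits[i] + 1;
  };
  if (model == 0) hamming_scan(t, x, ell, emit);
  else edit_scan_all(t, x, ell, emit);
  // a window never matched at all (n < ell under Hamming) stays ell + 1
  return List::create(_["min_e"] = min_e, _["hits"] = hits);
}

// Occurrence intervals of a single box in a text. Hamming: sliding window.
// [[Rcpp::export]]
DataFrame cpp_box_occ_hamming(std::string t, std::string box, int k) {
  const int n = (int)t.size(), l = (int)box.size();
  std::vector<int> rs, re_, rd;
  for (int s = 0; s + l <= n; ++s) {
    int e = 0;
    for (int p = 0; p < l && e <= k; ++p) e += (t[s + p] != box[p]);
    if (e <= k) { rs.push_back(s); re_.push_back(s + l - 1); rd.push_back(e); }
  }
  return DataFrame::create(_["start"] = wrap(rs), _["end"] = wrap(re_),
                           _["distance"] = wrap(rd));
}

// Edit model: for every text ending position with semi-global distance <= k,
// report the start attaining the minimal distance (smallest start on ties).
// Plain DP with start-pointer propagation, O(l * n).
// [[Rcpp::export]]
DataFrame cpp_box_occ_edit(std::string t, std::string box, int k) {
  const int n = (int)t.size(), l = (int)box.size();
  std::vector<int> Dp(n + 1), Dc(n + 1), Sp(n + 1), Sc(n + 1);
  for (int j = 0; j <= n; ++j) { Dp[j] = 0; Sp[j] = j; }
  for (int i = 1; i <= l; ++i) {
    Dc[0] = i; Sc[0] = 0;
    for (int j = 1; j <= n; ++j) {
      int d = Dp[j - 1] + (box[i - 1] != t[j - 1] ? 1 : 0);
      int s = Sp[j - 1];
      int du = Dp[j] + 1;
      if (du < d || (du == d && Sp[j] < s)) { d = du; s = Sp[j]; }
      int dl = Dc[j - 1] + 1;
      if (dl < d || (dl == d && Sc[j - 1] < s)) { d = dl; s = Sc[j - 1]; }
      Dc[j] = d; Sc[j] = s;
    }
    std::swap(Dp, Dc);
    std::swap(Sp, Sc);
  }
  std::vector<int> rs, re_, rd;
  for (int j = 1; j <= n; ++j) {
    if (Dp[j] <= k) { rs.push_back(Sp[j]); re_.push_back(j - 1); rd.push_back(Dp[j]); }
  }
  // sort by (start, end)
  std::vector<int> idx(rs.size());
  for (size_t p = 0; p < idx.size(); ++p) idx[p] = (int)p;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (rs[a] != rs[b]) return rs[a] < rs[b];
    return re_[a] < re_[b];
  });
  std::vector<int> os(rs.size()), oe(rs.size()), od(rs.size());
  for (size_t p = 0; p < idx.size(); ++p) {
    os[p] = rs[idx[p]]; oe[p] = re_[idx[p]]; od[p] = rd[idx[p]];
  }
  return DataFrame::create(_["start"] = wrap(os), _["end"] = wrap(oe),
                           _["distance"] = wrap(od));
}

// ---------------------------------------------------------------------------
// BitRow surface: R sees 0/1 integer vectors (bit 0 first); the packing and
// the word-level kernels here are the same ones the cores use.
// ---------------------------------------------------------------------------

static std::vector<u64> pack_bits(const IntegerVector& bits) {
  int ell = (int)bits.size();
  std::vector<u64> w(nwords(ell), 0);
  for (int p = 0; p < ell; ++p)
    if (bits[p]) w[p / WBITS] |= u64(1) << (p % WBITS);
  return w;
}

static IntegerVector unpack_bits(const std::vector<u64>& w, int ell) {
  IntegerVector bits(ell);
  for (int p = 0; p < ell; ++p)
    bits[p] = (int)((w[p / WBITS] >> (p % WBITS)) & 1);
  return bits;
}

// [[Rcpp::export]]
IntegerVector cpp_bv_shl1(IntegerVector bits) {
  int ell = (int)bits.size();
  std::vector<u64> a = pack_bits(bits), d(a.size());
  shl1_or(a.data(), d.data(), (int)a.size(), topmask(ell), 0);
  return unpack_bits(d, ell);
}

// [[Rcpp::export]]
IntegerVector cpp_bv_add(IntegerVector a, IntegerVector b) {
  int ell = (int)a.size();
  std::vector<u64> wa = pack_bits(a), wb = pack_bits(b), d(wa.size());
  add_mw(wa.data(), wb.data(), d.data(), (int)wa.size(), topmask(ell));
  return unpack_bits(d, ell);
}

// [[Rcpp::export]]
int cpp_bv_popcount(IntegerVector bits) {
  std::vector<u64> w = pack_bits(bits);
  return popcnt_mw(w.data(), (int)w.size());
}

// op: 0 = and, 1 = or, 2 = xor
// [[Rcpp::export]]
IntegerVector cpp_bv_bitop(IntegerVector a, IntegerVector b, int op) {
  int ell = (int)a.size();
  std::vector<u64> wa = pack_bits(a), wb = pack_bits(b), d(wa.size());
  for (size_t w = 0; w < wa.size(); ++w) {
    if (op == 0) d[w] = wa[w] & wb[w];
    else if (op == 1) d[w] = wa[w] | wb[w];
    else d[w] = wa[w] ^ wb[w];
  }
  return unpack_bits(d, ell);
}

// [[Rcpp::export]]
IntegerVector cpp_bv_not(IntegerVector bits) {
  int ell = (int)bits.size();
  std::vector<u64> w = pack_bits(bits);
  for (size_t i = 0; i < w.size(); ++i) w[i] = ~w[i];
  w[w.size() - 1] &= topmask(ell);
  return unpack_bits(w, ell);
}

// [[Rcpp::export]]
int cpp_word_size() { return WBITS; }
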