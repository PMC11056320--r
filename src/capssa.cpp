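#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct Counters {
  int64_t matching = 0;
  int64_t mismatching = 0;
};

// Compare the suffixes starting at a and b of t (length n, with a unique
// smallest terminator at n-1), resuming from a caller-asserted common
// prefix `skip`. cap > 0 bounds the context: the comparison stops and ties
// once the common prefix reaches cap symbols. Returns -1/0/1; the (capped)
// LCP goes to *lcp_out. Every symbol read is counted, equal reads as
// matching and the final unequal read as mismatching.
inline int suf_cmp(const uint8_t* t, int n, int a, int b, int skip, int cap,
                   int* lcp_out, Counters& c) {
  int limit = (cap > 0 && cap < n) ? cap : n;
  if (a == b) {
    int len = n - a;
    *lcp_out = len < limit ? len : limit;
    return 0;
  }
  int l = skip, i = a + skip, j = b + skip;
  // distinct suffixes always mismatch at or before the terminator, so i and
  // j stay in range while l < limit <= n
  while (l < limit) {
    uint8_t ca = t[i], cb = t[j];
    if (ca == cb) {
      ++c.matching;
      ++l; ++i; ++j;
    } else {
      ++c.mismatching;
      *lcp_out = l;
      return ca < cb ? -1 : 1;
    }
  }
  *lcp_out = limit;
  return 0;
}

// Merge sorted runs (xp, xl) and (yp, yl) into (zp, zl). m tracks the LCP
// of the last compared pair; runs of the comparison are skipped entirely
// when the run-internal LCP of the advancing side differs from m, and
// resumed at offset m when equal. Context-bound ties take the x side first.
void lcp_merge_core(const uint8_t* t, int n, int k,
                    const int* xp, const int* xl, int nx,
                    const int* yp, const int* yl, int ny,
                    int* zp, int* zl, Counters& c) {
  if (nx == 0) {
    for (int q = 0; q < ny; ++q) { zp[q] = yp[q]; zl[q] = q == 0 ? 0 : yl[q]; }
    return;
  }
  if (ny == 0) {
    for (int q = 0; q < nx; ++q) { zp[q] = xp[q]; zl[q] = q == 0 ? 0 : xl[q]; }
    return;
  }
  int i = 0, j = 0, o = 0, m = 0;
  int rel = suf_cmp(t, n, xp[0], yp[0], 0, k, &m, c);
  bool from_x = rel <= 0;
  if (from_x) { zp[o] = xp[i]; zl[o] = 0; ++i; }
  else        { zp[o] = yp[j]; zl[o] = 0; ++j; }
  ++o;
  while (i < nx && j < ny) {
    if (from_x) {
      // last output was X[i-1]; m = LCP(X[i-1], Y[j])
      int lx = xl[i];
      if (lx > m) {
        zp[o] = xp[i]; zl[o] = lx; ++i;                  // X[i] < Y[j], no reads
      } else if (lx < m) {
        zp[o] = yp[j]; zl[o] = m; m = lx; ++j; from_x = false;  // Y[j] < X[i]
      } else {
        int nl;
        int r = suf_cmp(t, n, xp[i], yp[j], m, k, &nl, c);
        if (r <= 0) { zp[o] = xp[i]; zl[o] = lx; ++i; }
        else        { zp[o] = yp[j]; zl[o] = m; ++j; from_x = false; }
        m = nl;
      }
    } else {
      // last output was Y[j-1]; m = LCP(Y[j-1], X[i])
      int ly = yl[j];
      if (ly > m) {
        zp[o] = yp[j]; zl[o] = ly; ++j;
      } else if (ly < m) {
        zp[o] = xp[i]; zl[o] = m; m = ly; ++i; from_x = true;
      } else {
        int nl;
        int r = suf_cmp(t, n, xp[i], yp[j], m, k, &nl, c);
        if (r <= 0) { zp[o] = xp[i]; zl[o] = m; ++i; from_x = true; }
        else        { zp[o] = yp[j]; zl[o] = ly; ++j; }
        m = nl;
      }
    }
    ++o;
  }
  // the first copied entry's predecessor in z is the last winner from the
  // other run, whose LCP with it is exactly the current m
  if (i < nx) {
    zp[o] = xp[i]; zl[o] = m; ++o; ++i;
    for (; i < nx; ++i, ++o) { zp[o] = xp[i]; zl[o] = xl[i]; }
  } else if (j < ny) {
    zp[o] = yp[j]; zl[o] = m; ++o; ++j;
    for (; j < ny; ++j, ++o) { zp[o] = yp[j]; zl[o] = yl[j]; }
  }
}

// Mergesort of ap[lo, hi) ping-ponging between the (ap, al) and (bp, bl)
// buffer pairs; the result lands in b when into_b, else in a.
void merge_sort_rec(const uint8_t* t, int n, int k,
                    int* ap, int* al, int* bp, int* bl,
                    int lo, int hi, bool into_b, Counters& c) {
  int len = hi - lo;
  if (len <= 0) return;
  if (len == 1) {
    if (into_b) { bp[lo] = ap[lo]; bl[lo] = 0; } else { al[lo] = 0; }
    return;
  }
  int mid = lo + len / 2;
  merge_sort_rec(t, n, k, ap, al, bp, bl, lo, mid, !into_b, c);
  merge_sort_rec(t, n, k, ap, al, bp, bl, mid, hi, !into_b, c);
  const int* sp = into_b ? ap : bp;
  const int* sl = into_b ? al : bl;
  int* dp = into_b ? bp : ap;
  int* dl = into_b ? bl : al;
  lcp_merge_core(t, n, k, sp + lo, sl + lo, mid - lo,
                 sp + mid, sl + mid, hi - mid, dp + lo, dl + lo, c);
}

// Balanced binary merge of the sorted groups gofs[glo..ghi] of (ap, al),
// same ping-pong discipline as merge_sort_rec but bottoming out at groups.
void merge_partition_rec(const uint8_t* t, int n, int k,
                         int* ap, int* al, int* bp, int* bl,
                         const int* gofs, int glo, int ghi, bool into_b,
                         Counters& c) {
  if (ghi - glo <= 0) return;
  if (ghi - glo == 1) {
    if (into_b)
      for (int q = gofs[glo]; q < gofs[glo + 1]; ++q) { bp[q] = ap[q]; bl[q] = al[q]; }
    return;
  }
  int gmid = glo + (ghi - glo) / 2;
  merge_partition_rec(t, n, k, ap, al, bp, bl, gofs, glo, gmid, !into_b, c);
  merge_partition_rec(t, n, k, ap, al, bp, bl, gofs, gmid, ghi, !into_b, c);
  int lo = gofs[glo], mi = gofs[gmid], hi = gofs[ghi];
  const int* sp = into_b ? ap : bp;
  const int* sl = into_b ? al : bl;
  int* dp = into_b ? bp : ap;
  int* dl = into_b ? bl : al;
  lcp_merge_core(t, n, k, sp + lo, sl + lo, mi - lo,
                 sp + mi, sl + mi, hi - mi, dp + lo, dl + lo, c);
}

// Upper-bound binary search of pivot suffix v in the sorted run: the
// smallest idx whose suffix compares greater than v's searched prefix.
// The search prefix is capped by prefix_limit and the context bound k; a
// run suffix that matches the whole (truncated) prefix and extends beyond
// it counts as greater, so the boundary is the start of the prefix block
// in every run. Simple accelerant: each probe resumes at the smaller of
// the LCPs of v with the current lo/hi brackets.
int locate_pivot_core(const uint8_t* t, int n, const int* run, int len, int v,
                      int prefix_limit, int k, Counters& c) {
  int vlen = n - v;
  int lim = vlen;
  if (prefix_limit > 0 && prefix_limit < lim) lim = prefix_limit;
  if (k > 0 && k < lim) lim = k;
  bool truncated = lim < vlen;
  int lo = -1, hi = len, llo = 0, lhi = 0;
  while (hi - lo > 1) {
    int mid = lo + (hi - lo) / 2;
    int skip = llo < lhi ? llo : lhi;
    int u = run[mid];
    int l;
    bool gt;
    if (u == v) {
      l = lim;
      gt = truncated;  // v itself extends beyond a searched proper prefix
    } else {
      int rel = suf_cmp(t, n, u, v, skip, lim, &l, c);
      gt = rel != 0 ? rel > 0 : truncated;
    }
    if (gt) { hi = mid; lhi = l; } else { lo = mid; llo = l; }
  }
  return hi;
}

}  // namespace

// [[Rcpp::export]]
List cpp_suffix_compare(RawVector text, int a, int b, int skip, int k) {
  Counters c;
  int lcp;
  int rel = suf_cmp(RAW(text), (int)text.size(), a, b, skip, k, &lcp, c);
  return List::create(_["rel"] = rel, _["lcp"] = lcp,
                      _["matching"] = (double)c.matching,
                      _["mismatching"] = (double)c.mismatching,
                      _["reads"] = (double)(c.matching + c.mismatching));
}

// [[Rcpp::export]]
List cpp_lcp_merge(RawVector text, IntegerVector xp, IntegerVector xl,
                   IntegerVector yp, IntegerVector yl, int k) {
  int nx = xp.size(), ny = yp.size(), n = text.size();
  std::vector<int> zp(nx + ny), zl(nx + ny);
  Counters c;
  lcp_merge_core(RAW(text), n, k, xp.begin(), xl.begin(), nx,
                 yp.begin(), yl.begin(), ny, zp.data(), zl.data(), c);
  return List::create(_["pos"] = IntegerVector(zp.begin(), zp.end()),
                      _["lcp"] = IntegerVector(zl.begin(), zl.end()),
                      _["matching"] = (double)c.matching,
                      _["mismatching"] = (double)c.mismatching);
}

// [[Rcpp::export]]
List cpp_merge_sort(RawVector text, IntegerVector positions, int k) {
  int m = positions.size(), n = text.size();
  std::vector<int> ap(positions.begin(), positions.end());
  std::vector<int> al(m), bp(m), bl(m);
  Counters c;
  merge_sort_rec(RAW(text), n, k, ap.data(), al.data(), bp.data(), bl.data(),
                 0, m, false, c);
  return List::create(_["pos"] = IntegerVector(ap.begin(), ap.end()),
                      _["lcp"] = IntegerVector(al.begin(), al.end()),
                      _["matching"] = (double)c.matching,
                      _["mismatching"] = (double)c.mismatching);
}

// [[Rcpp::export]]
List cpp_locate_pivot(RawVector text, IntegerVector run, int v,
                      int prefix_limit, int k) {
  Counters c;
  int idx = locate_pivot_core(RAW(text), (int)text.size(), run.begin(),
                              run.size(), v, prefix_limit, k, c);
  return List::create(_["idx"] = idx,
                      _["matching"] = (double)c.matching,
                      _["mismatching"] = (double)c.mismatching);
}

// [[Rcpp::export]]
List cpp_merge_partition(RawVector text, IntegerVector positions,
                         IntegerVector lcps, IntegerVector gofs, int k) {
  int m = positions.size(), n = text.size(), g = gofs.size() - 1;
  std::vector<int> ap(positions.begin(), positions.end());
  std::vector<int> al(lcps.begin(), lcps.end());
  std::vector<int> bp(m), bl(m);
  Counters c;
  merge_partition_rec(RAW(text), n, k, ap.data(), al.data(), bp.data(),
                      bl.data(), gofs.begin(), 0, g, false, c);
  return List::create(_["pos"] = IntegerVector(ap.begin(), ap.end()),
                      _["lcp"] = IntegerVector(al.begin(), al.end()),
                      _["matching"] = (double)c.matching,
                      _["mismatching"] = (double)c.mismatching);
}

// Full pipeline: identity SA -> p uniform subarray mergesorts -> pivot
// sampling (sample indices are drawn R-side and passed 1-based into each
// sorted run) -> accelerated binary-search pivot location -> collation ->
// balanced binary partition merges -> boundary LCP fix-up. Auxiliary space
// (every workspace entry beyond the returned SA and LCP arrays) is
// tracked; sample sorting reuses the free scratch halves when it fits.
// [[Rcpp::export]]
List cpp_construct(RawVector text, int p, int k, int prefix_limit,
                   List samples) {
  const uint8_t* t = RAW(text);
  int n = text.size();
  Counters c;
  double aux_cur = 0, aux_peak = 0;
  auto aux_add = [&](double x) { aux_cur += x; if (aux_cur > aux_peak) aux_peak = aux_cur; };

  std::vector<int> A(n), LA(n), B(n), LB(n);
  aux_add(2.0 * n);  // A/LA; B/LB back the returned arrays
  for (int q = 0; q < n; ++q) A[q] = q;

  std::vector<int> off(p + 1);
  for (int r = 0; r <= p; ++r) off[r] = (int)(((long long)r * n) / p);
  for (int r = 0; r < p; ++r)
    merge_sort_rec(t, n, k, A.data(), LA.data(), B.data(), LB.data(),
                   off[r], off[r + 1], false, c);

  if (p == 1) {
    IntegerVector C = IntegerVector::create(0, n);
    return List::create(_["sa"] = IntegerVector(A.begin(), A.end()),
                        _["lcp"] = IntegerVector(LA.begin(), LA.end()),
                        _["C"] = C,
                        _["matching"] = (double)c.matching,
                        _["mismatching"] = (double)c.mismatching,
                        _["peak_aux"] = aux_peak);
  }

  // --- pivot sampling over the sorted runs
  int s_eff = ((IntegerVector)samples[0]).size();
  int S = s_eff * p;
  bool scratch = 2 * S <= n;
  std::vector<int> xs;
  int *sa_a, *sl_a, *sa_b, *sl_b;
  if (scratch) {
    sa_a = B.data();  sa_b = B.data() + S;
    sl_a = LB.data(); sl_b = LB.data() + S;
  } else {
    xs.resize((size_t)4 * S);
    sa_a = xs.data();         sa_b = xs.data() + S;
    sl_a = xs.data() + 2 * S; sl_b = xs.data() + 3 * S;
    aux_add(4.0 * S);
  }
  for (int r = 0; r < p; ++r) {
    IntegerVector idx = samples[r];
    for (int q = 0; q < s_eff; ++q)
      sa_a[r * s_eff + q] = A[off[r] + idx[q] - 1];
  }
  merge_sort_rec(t, n, k, sa_a, sl_a, sa_b, sl_b, 0, S, false, c);
  std::vector<int> piv(p - 1);
  aux_add(p - 1.0);
  for (int j = 1; j < p; ++j) piv[j - 1] = sa_a[j * s_eff];
  if (!scratch) { std::vector<int>().swap(xs); aux_cur -= 4.0 * S; }

  // --- locate every pivot in every sorted run
  std::vector<int> bnd((size_t)p * (p - 1));
  aux_add((double)p * (p - 1));
  for (int r = 0; r < p; ++r) {
    int len_r = off[r + 1] - off[r];
    for (int j = 0; j < p - 1; ++j)
      bnd[(size_t)r * (p - 1) + j] = locate_pivot_core(
          t, n, A.data() + off[r], len_r, piv[j], prefix_limit, k, c);
  }

  // --- cumulative partition layout C_0..C_p
  std::vector<int> C(p + 1, 0);
  aux_add(p + 1.0);
  for (int j = 0; j < p; ++j) {
    long long sz = 0;
    for (int r = 0; r < p; ++r) {
      int len_r = off[r + 1] - off[r];
      int sgs = j == 0 ? 0 : bnd[(size_t)r * (p - 1) + (j - 1)];
      int sge = j == p - 1 ? len_r : bnd[(size_t)r * (p - 1) + j];
      sz += sge - sgs;
    }
    C[j + 1] = C[j] + (int)sz;
  }

  // --- collate sub-subarrays; each group's leading LCP entry is reset
  for (int j = 0; j < p; ++j) {
    int out = C[j];
    for (int r = 0; r < p; ++r) {
      int len_r = off[r + 1] - off[r];
      int sgs = j == 0 ? 0 : bnd[(size_t)r * (p - 1) + (j - 1)];
      int sge = j == p - 1 ? len_r : bnd[(size_t)r * (p - 1) + j];
      for (int q = sgs; q < sge; ++q) {
        B[out] = A[off[r] + q];
        LB[out] = q == sgs ? 0 : LA[off[r] + q];
        ++out;
      }
    }
  }

  // --- merge each partition's p groups (ping-pong B/LB <-> A/LA)
  std::vector<int> gofs(p + 1);
  aux_add(p + 1.0);
  for (int j = 0; j < p; ++j) {
    gofs[0] = C[j];
    for (int r = 0; r < p; ++r) {
      int len_r = off[r + 1] - off[r];
      int sgs = j == 0 ? 0 : bnd[(size_t)r * (p - 1) + (j - 1)];
      int sge = j == p - 1 ? len_r : bnd[(size_t)r * (p - 1) + j];
      gofs[r + 1] = gofs[r] + (sge - sgs);
    }
    merge_partition_rec(t, n, k, B.data(), LB.data(), A.data(), LA.data(),
                        gofs.data(), 0, p, false, c);
  }

  // --- boundary LCPs across partition joins
  LB[0] = 0;
  for (int j = 1; j < p; ++j) {
    int b = C[j];
    if (b > 0 && b < n) {
      int l;
      suf_cmp(t, n, B[b - 1], B[b], 0, k, &l, c);
      LB[b] = l;
    }
  }

  return List::create(_["sa"] = IntegerVector(B.begin(), B.end()),
                      _["lcp"] = IntegerVector(LB.begin(), LB.end()),
                      _["C"] = IntegerVector(C.begin(), C.end()),
                      _["matching"] = (double)c.matching,
                      _["mismatching"] = (double)c.mismatching,
                      _["peak_aux"] = aux_peak);
}

// [[Rcpp::export]]
std::string cpp_fnv64(RawVector x) {
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    h ^= (uint64_t)x[i];
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
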