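#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C';
    case 'T': return 'A'; default: return 'N';
  }
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) {
  size_t n = s.size();
  std::string out(n, 'N');
  for (size_t i = 0; i < n; ++i) out[i] = comp_base(s[n - 1 - i]);
  return out;
}

// ---------------------------------------------------------------------------
// Exact Smith-Waterman with affine gaps (Gotoh), full byte traceback.
// Oracle-scale only: |a|,|b| <= 5000 enforced by the R wrapper.
// Coordinates returned 0-based half-open on the forward strands.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_extend) {
  int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const int NEG = INT_MIN / 4;
  size_t W = (size_t)n + 1;
  // byte per cell: bits 0-1 H-direction (0 stop, 1 diag, 2 left/E, 3 up/F),
  // bit 2: E extended from E, bit 3: F extended from F
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);
  std::vector<int> Hp(n + 1, 0), Hc(n + 1, 0), Fcol(n + 1, NEG);
  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    int Erow = NEG;
    Hc[0] = 0;
    for (int j = 1; j <= n; ++j) {
      size_t idx = (size_t)i * W + j;
      uint8_t t = 0;
      int e_open = Hc[j - 1] - gap_open - gap_extend;
      int e_ext = Erow - gap_extend;
      if (e_open >= e_ext) Erow = e_open; else { Erow = e_ext; t |= 4; }
      int f_open = Hp[j] - gap_open - gap_extend;
      int f_ext = Fcol[j] - gap_extend;
      if (f_open >= f_ext) Fcol[j] = f_open; else { Fcol[j] = f_ext; t |= 8; }
      bool eq = (a[i - 1] == b[j - 1]) && a[i - 1] != 'N';
      int diag = Hp[j - 1] + (eq ? match : mismatch);
      int h = 0, dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (Erow > h) { h = Erow; dir = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; dir = 3; }
      t |= (uint8_t)dir;
      tb[idx] = t;
      Hc[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hp, Hc);
  }
  if (best <= 0) {
    return List::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["matches"] = 0,
                        _["length"] = 0, _["gaps"] = 0,
                        _["ops"] = IntegerVector(0));
  }
  // ops per alignment column (recorded back-to-front, reversed at the
  // end): 0 match, 1 mismatch, 2 gap in query (consumes subject),
  // 3 gap in subject (consumes query)
  std::vector<int> ops;
  int i = bi, j = bj, matches = 0, cols = 0, gaps = 0;
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * W + j];
    int dir = t & 3;
    if (dir == 0) break;
    if (dir == 1) {
      cols++;
      bool eq = (a[i - 1] == b[j - 1]) && a[i - 1] != 'N';
      if (eq) matches++;
      ops.push_back(eq ? 0 : 1);
      i--; j--;
    } else if (dir == 2) {
      while (true) {
        bool ext = tb[(size_t)i * W + j] & 4;
        cols++; gaps++; j--;
        ops.push_back(2);
        if (!ext || j == 0) break;
      }
    } else {
      while (true) {
        bool ext = tb[(size_t)i * W + j] & 8;
        cols++; gaps++; i--;
        ops.push_back(3);
        if (!ext || i == 0) break;
      }
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["q_start"] = i, _["q_end"] = bi,
                      _["s_start"] = j, _["s_end"] = bj,
                      _["matches"] = matches, _["length"] = cols,
                      _["gaps"] = gaps, _["ops"] = ops);
}

// ---------------------------------------------------------------------------
// Seed-and-extend aligner: exact k-mer seeds, same-diagonal segment merging,
// collinear chaining, piecewise gap filling with small global Gotoh blocks,
// X-drop ungapped end extension.
// ---------------------------------------------------------------------------

struct Seg { int qs, qe, d; };
struct Hit {
  int qs, qe, ss, se, score, matches, cols, gaps;
};

typedef std::unordered_map<uint64_t, std::vector<int> > KIndex;

static void build_index(const std::string& s, int k, KIndex& idx) {
  uint64_t key = 0, mask = (1ULL << (2 * k)) - 1;
  int run = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    run++;
    if (run >= k) idx[key].push_back(i - k + 1);
  }
}

// global affine alignment of two short strings, accumulate stats
static void nw_fill(const std::string& a, int a0, int a1,
                    const std::string& b, int b0, int b1,
                    int match, int mismatch, int go, int ge,
                    int& matches, int& cols, int& gaps, int& score) {
  int m = a1 - a0, n = b1 - b0;
  if (m == 0 && n == 0) return;
  if (m == 0) { cols += n; gaps += n; score -= go + ge * n; return; }
  if (n == 0) { cols += m; gaps += m; score -= go + ge * m; return; }
  if ((long long)m * n > 4000000LL) {
    // degenerate fallback for very large gaps: diagonal run + pure gap
    int d = std::min(m, n), extra = std::abs(m - n);
    int mt = 0;
    for (int t = 0; t < d; ++t)
      if (a[a0 + t] == b[b0 + t] && a[a0 + t] != 'N') mt++;
    matches += mt; cols += d + extra; gaps += extra;
    score += mt * match + (d - mt) * mismatch;
    if (extra > 0) score -= go + ge * extra;
    return;
  }
  const int NEG = INT_MIN / 4;
  size_t W = (size_t)n + 1;
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);
  std::vector<int> Hp(n + 1), Hc(n + 1), Fc(n + 1, NEG);
  Hp[0] = 0;
  for (int j = 1; j <= n; ++j) { Hp[j] = -go - ge * j; tb[j] = 2 | 4; }
  tb[1] = 2; // first gap opens
  for (int i = 1; i <= m; ++i) {
    int Erow = NEG;
    Hc[0] = -go - ge * i;
    tb[(size_t)i * W] = 3 | ((i > 1) ? 8 : 0);
    for (int j = 1; j <= n; ++j) {
      size_t idx = (size_t)i * W + j;
      uint8_t t = 0;
      int e_open = Hc[j - 1] - go - ge, e_ext = Erow - ge;
      if (e_open >= e_ext) Erow = e_open; else { Erow = e_ext; t |= 4; }
      int f_open = Hp[j] - go - ge, f_ext = Fc[j] - ge;
      if (f_open >= f_ext) Fc[j] = f_open; else { Fc[j] = f_ext; t |= 8; }
      bool eq = (a[a0 + i - 1] == b[b0 + j - 1]) && a[a0 + i - 1] != 'N';
      int diag = Hp[j - 1] + (eq ? match : mismatch);
      int h = diag, dir = 1;
      if (Erow > h) { h = Erow; dir = 2; }
      if (Fc[j] > h) { h = Fc[j]; dir = 3; }
      t |= (uint8_t)dir;
      tb[idx] = t;
      Hc[j] = h;
    }
    std::swap(Hp, Hc);
  }
  score += Hp[n];
  int i = m, j = n;
  while (i > 0 || j > 0) {
    uint8_t t = tb[(size_t)i * W + j];
    int dir = t & 3;
    if (dir == 1) {
      cols++;
      if (a[a0 + i - 1] == b[b0 + j - 1] && a[a0 + i - 1] != 'N') matches++;
      i--; j--;
    } else if (dir == 2) {
      while (j > 0) {
        bool ext = tb[(size_t)i * W + j] & 4;
        cols++; gaps++; j--;
        if (!ext) break;
      }
    } else if (dir == 3) {
      while (i > 0) {
        bool ext = tb[(size_t)i * W + j] & 8;
        cols++; gaps++; i--;
        if (!ext) break;
      }
    } else break;
  }
}

// ungapped X-drop extension; dir = +1 right (from q0,s0 inclusive) or -1 left
// (from q0,s0 exclusive); returns accepted length, accumulates matches/score
static int xdrop_extend(const std::string& q, const std::string& s,
                        int q0, int s0, int dir, int xdrop,
                        int match, int mismatch,
                        int& matches, int& score) {
  int cur = 0, bestv = 0, bestt = 0, bestm = 0, mt = 0;
  int nq = (int)q.size(), ns = (int)s.size();
  for (int t = 0; ; ++t) {
    int qi = (dir > 0) ? q0 + t : q0 - 1 - t;
    int si = (dir > 0) ? s0 + t : s0 - 1 - t;
    if (qi < 0 || si < 0 || qi >= nq || si >= ns) break;
    bool eq = (q[qi] == s[si]) && q[qi] != 'N';
    cur += eq ? match : mismatch;
    if (eq) mt++;
    if (cur > bestv) { bestv = cur; bestt = t + 1; bestm = mt; }
    if (bestv - cur > xdrop) break;
  }
  matches += bestm;
  score += bestv;
  return bestt;
}

static void align_chain(const std::string& q, const std::string& s,
                        const std::vector<Seg>& segs,
                        const std::vector<int>& chain, // indices, ascending q
                        int k, int xdrop,
                        int match, int mismatch, int go, int ge,
                        std::vector<Hit>& out) {
  int matches = 0, cols = 0, gaps = 0, score = 0;
  int aq = -1, as = -1, q0 = -1, s0 = -1;
  for (size_t ci = 0; ci < chain.size(); ++ci) {
    Seg sg = segs[chain[ci]];
    int ss = sg.qs - sg.d, se = sg.qe - sg.d;
    int qs = sg.qs, qe = sg.qe;
    if (aq >= 0) {
      int shift = std::max(0, std::max(aq - qs, as - ss));
      qs += shift; ss += shift;
      if (qs >= qe) continue;
      nw_fill(q, aq, qs, s, as, ss, match, mismatch, go, ge,
              matches, cols, gaps, score);
    } else { q0 = qs; s0 = ss; }
    int mt = 0;
    for (int t = qs; t < qe; ++t) {
      if (q[t] == s[ss + (t - qs)] && q[t] != 'N') mt++;
    }
    matches += mt; cols += qe - qs;
    score += mt * match + (qe - qs - mt) * mismatch;
    aq = qe; as = se;
  }
  if (aq < 0) return;
  int extl = xdrop_extend(q, s, q0, s0, -1, xdrop, match, mismatch,
                          matches, score);
  q0 -= extl; s0 -= extl; cols += extl;
  int extr = xdrop_extend(q, s, aq, as, +1, xdrop, match, mismatch,
                          matches, score);
  aq += extr; as += extr; cols += extr;
  Hit h;
  h.qs = q0; h.qe = aq; h.ss = s0; h.se = as;
  h.score = score; h.matches = matches; h.cols = cols; h.gaps = gaps;
  out.push_back(h);
}

static void align_one_strand(const std::string& q, const std::string& s,
                             const KIndex& idx, int k, int max_occ,
                             int seg_join, int chain_gap, int max_lookback,
                             int min_chain_bp, int xdrop,
                             int match, int mismatch, int go, int ge,
                             bool skip_self, std::vector<Hit>& out) {
  // anchors (q, d = q - s)
  std::vector<std::pair<int, int> > anchors; // (d, q)
  uint64_t key = 0, mask = (1ULL << (2 * k)) - 1;
  int run = 0;
  for (int i = 0; i < (int)q.size(); ++i) {
    int c = base_code(q[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    run++;
    if (run < k) continue;
    KIndex::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    const std::vector<int>& occ = it->second;
    if ((int)occ.size() > max_occ) continue;
    int qpos = i - k + 1;
    for (size_t o = 0; o < occ.size(); ++o) {
      if (skip_self && occ[o] == qpos) continue;
      anchors.push_back(std::make_pair(qpos - occ[o], qpos));
    }
  }
  if (anchors.empty()) return;
  std::sort(anchors.begin(), anchors.end());
  // merge same-diagonal anchors into segments
  std::vector<Seg> segs;
  Seg cur; cur.d = anchors[0].first; cur.qs = anchors[0].second;
  cur.qe = cur.qs + k;
  for (size_t a = 1; a < anchors.size(); ++a) {
    int d = anchors[a].first, qp = anchors[a].second;
    if (d == cur.d && qp <= cur.qe + seg_join) {
      if (qp + k > cur.qe) cur.qe = qp + k;
    } else {
      segs.push_back(cur);
      cur.d = d; cur.qs = qp; cur.qe = qp + k;
    }
  }
  segs.push_back(cur);
  // chain: sort by q start then diagonal
  std::sort(segs.begin(), segs.end(),
            [](const Seg& x, const Seg& y) {
              if (x.qs != y.qs) return x.qs < y.qs;
              return x.d < y.d;
            });
  int S = (int)segs.size();
  std::vector<int> sc(S), prev(S, -1);
  for (int i = 0; i < S; ++i) {
    sc[i] = segs[i].qe - segs[i].qs;
    int lo = std::max(0, i - max_lookback);
    for (int j = i - 1; j >= lo; --j) {
      if (segs[i].qs - segs[j].qs > chain_gap + 20000) break;
      int gq = segs[i].qs - segs[j].qe;
      int gs = (segs[i].qs - segs[i].d) - (segs[j].qe - segs[j].d);
      if (gq > chain_gap || gs > chain_gap) continue;
      if (gq < -((segs[j].qe - segs[j].qs) / 2)) continue;
      if (gs < -((segs[j].qe - segs[j].qs) / 2)) continue;
      int dd = std::abs(segs[i].d - segs[j].d);
      int cand = sc[j] + (segs[i].qe - segs[i].qs) - dd
        - std::max(gq, 0) / 50;
      if (cand > sc[i]) { sc[i] = cand; prev[i] = j; }
    }
  }
  // extract chains best-first
  std::vector<int> order(S);
  for (int i = 0; i < S; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&sc](int x, int y) { return sc[x] > sc[y]; });
  std::vector<char> used(S, 0);
  for (int oi = 0; oi < S; ++oi) {
    int i = order[oi];
    if (used[i] || sc[i] < min_chain_bp) continue;
    std::vector<int> chain;
    int c = i;
    while (c >= 0 && !used[c]) {
      chain.push_back(c);
      used[c] = 1;
      c = prev[c];
    }
    std::reverse(chain.begin(), chain.end());
    align_chain(q, s, segs, chain, k, xdrop, match, mismatch, go, ge, out);
  }
}

// [[Rcpp::export]]
DataFrame chain_align_cpp(CharacterVector queries, std::string subject,
                          int k, int max_occ, int seg_join, int chain_gap,
                          int max_lookback, int min_chain_bp, int xdrop,
                          int match, int mismatch, int gap_open,
                          int gap_extend, bool skip_self, bool both_strands) {
  if (k < 3 || k > 31) stop("k out of range");
  KIndex idx;
  build_index(subject, k, idx);
  std::vector<int> o_query, o_qs, o_qe, o_ss, o_se, o_score, o_matches,
    o_cols, o_gaps;
  std::vector<std::string> o_strand;
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    int Lq = (int)q.size();
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      std::string qs_ = (strand == 0) ? q : revcomp_cpp(q);
      std::vector<Hit> hits;
      align_one_strand(qs_, subject, idx, k, max_occ, seg_join, chain_gap,
                       max_lookback, min_chain_bp, xdrop, match, mismatch,
                       gap_open, gap_extend, skip_self && strand == 0, hits);
      for (size_t h = 0; h < hits.size(); ++h) {
        Hit& ht = hits[h];
        int qs0 = ht.qs, qe0 = ht.qe;
        if (strand == 1) { qs0 = Lq - ht.qe; qe0 = Lq - ht.qs; }
        o_query.push_back(qi + 1);
        o_strand.push_back(strand == 0 ? "+" : "-");
        o_qs.push_back(qs0); o_qe.push_back(qe0);
        o_ss.push_back(ht.ss); o_se.push_back(ht.se);
        o_score.push_back(ht.score); o_matches.push_back(ht.matches);
        o_cols.push_back(ht.cols); o_gaps.push_back(ht.gaps);
      }
    }
  }
  return DataFrame::create(_["query"] = o_query, _["strand"] = o_strand,
                           _["q_start"] = o_qs, _["q_end"] = o_qe,
                           _["s_start"] = o_ss, _["s_end"] = o_se,
                           _["score"] = o_score, _["matches"] = o_matches,
                           _["length"] = o_cols, _["gaps"] = o_gaps,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Maximal equal-length substring pairs within a Hamming budget, per diagonal.
// same = TRUE restricts to offsets j > i within one sequence (t must be s).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame hamming_pairs_cpp(std::string s, std::string t, int min_len,
                            int max_mm, bool same) {
  int ns = (int)s.size(), nt = (int)t.size();
  std::vector<int> o_i, o_j, o_len, o_mm;
  std::vector<int> mp;
  int off_lo = same ? 1 : -(ns - 1);
  int off_hi = nt - 1;
  for (int off = off_lo; off <= off_hi; ++off) {
    // off = j - i; for same mode only off >= 1 (each pair once)
    int i0 = std::max(-off, 0);
    int j0 = i0 + off;
    int L = std::min(ns - i0, nt - j0);
    if (L < min_len) continue;
    mp.clear();
    mp.push_back(-1);
    for (int x = 0; x < L; ++x) {
      char c1 = s[i0 + x], c2 = t[j0 + x];
      if (c1 != c2 || c1 == 'N') mp.push_back(x);
    }
    mp.push_back(L);
    int r = (int)mp.size() - 2; // real mismatches
    if (r <= max_mm) {
      if (L >= min_len) {
        o_i.push_back(i0); o_j.push_back(j0);
        o_len.push_back(L); o_mm.push_back(r);
      }
    } else {
      for (int a = 0; a + max_mm + 1 <= r + 1; ++a) {
        int b = a + max_mm + 1;
        int st = mp[a] + 1, en = mp[b] - 1;
        int len = en - st + 1;
        if (len >= min_len) {
          o_i.push_back(i0 + st); o_j.push_back(j0 + st);
          o_len.push_back(len); o_mm.push_back(max_mm);
        }
      }
    }
  }
  return DataFrame::create(_["i"] = o_i, _["j"] = o_j, _["len"] = o_len,
                           _["mismatches"] = o_mm);
}
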