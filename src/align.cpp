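#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// base encoding: A=0 C=1 G=2 T=3, anything else (N) = -1
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

// ---------------------------------------------------------------------------
// Affine-gap pairwise DP.  mode: 0 = local (Smith-Waterman), 1 = global
// (Needleman-Wunsch), 2 = extension (start anchored at (0,0), best cell wins).
// A gap of length L costs gap_open + L * gap_extend (both parameters <= 0).
// Tie-breaking is deterministic: best cell is the first maximum in row-major
// order; traceback prefers diagonal, then gap-in-b (up), then gap-in-a (left).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List affine_dp_cpp(std::string a, std::string b,
                   double match, double mismatch,
                   double gap_open, double gap_extend,
                   int mode) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  std::vector<double> H((n + 1) * (m + 1)), E((n + 1) * (m + 1)),
      F((n + 1) * (m + 1));
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  const bool local = (mode == 0);
  H[idx(0, 0)] = 0.0; E[idx(0, 0)] = NEG; F[idx(0, 0)] = NEG;
  for (int j = 1; j <= m; ++j) {
    E[idx(0, j)] = (mode == 1 || mode == 2) ? gap_open + j * gap_extend : NEG;
    F[idx(0, j)] = NEG;
    H[idx(0, j)] = local ? 0.0 : E[idx(0, j)];
  }
  for (int i = 1; i <= n; ++i) {
    F[idx(i, 0)] = (mode == 1 || mode == 2) ? gap_open + i * gap_extend : NEG;
    E[idx(i, 0)] = NEG;
    H[idx(i, 0)] = local ? 0.0 : F[idx(i, 0)];
  }

  double best = local ? 0.0 : NEG;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int ai = enc(a[i - 1]);
    for (int j = 1; j <= m; ++j) {
      const int bj_ = enc(b[j - 1]);
      const double s = (ai >= 0 && ai == bj_) ? match : mismatch;
      double e = std::max(H[idx(i, j - 1)] + gap_open + gap_extend,
                          E[idx(i, j - 1)] + gap_extend);
      double f = std::max(H[idx(i - 1, j)] + gap_open + gap_extend,
                          F[idx(i - 1, j)] + gap_extend);
      double h = H[idx(i - 1, j - 1)] + s;
      h = std::max(h, std::max(e, f));
      if (local && h < 0) h = 0;
      E[idx(i, j)] = e; F[idx(i, j)] = f; H[idx(i, j)] = h;
      if (mode != 1 && h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (mode == 1) { best = H[idx(n, m)]; bi = n; bj = m; }

  // traceback
  std::string aa, ab;
  int i = bi, j = bj;
  int state = 0; // 0 = in H, 1 = in E (gap in a), 2 = in F (gap in b)
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (local && state == 0 && H[idx(i, j)] <= 0) break;
    if (mode == 2 && i == 0 && j == 0) break;
    if (state == 0) {
      double h = H[idx(i, j)];
      if (i > 0 && j > 0) {
        const double s = (enc(a[i - 1]) >= 0 && enc(a[i - 1]) == enc(b[j - 1]))
                             ? match : mismatch;
        if (std::abs(H[idx(i - 1, j - 1)] + s - h) < eps) {
          aa += a[i - 1]; ab += b[j - 1]; --i; --j; continue;
        }
      }
      if (i > 0 && std::abs(F[idx(i, j)] - h) < eps) { state = 2; continue; }
      if (j > 0 && std::abs(E[idx(i, j)] - h) < eps) { state = 1; continue; }
      // global border cells
      if (i > 0) { aa += a[i - 1]; ab += '-'; --i; continue; }
      if (j > 0) { aa += '-'; ab += b[j - 1]; --j; continue; }
      break;
    } else if (state == 1) { // gap in a, consume b
      double e = E[idx(i, j)];
      aa += '-'; ab += b[j - 1];
      if (j > 1 && std::abs(E[idx(i, j - 1)] + gap_extend - e) < eps &&
          !(std::abs(H[idx(i, j - 1)] + gap_open + gap_extend - e) < eps)) {
        --j; // stay in E
      } else { --j; state = 0; }
    } else { // gap in b, consume a
      double f = F[idx(i, j)];
      aa += a[i - 1]; ab += '-';
      if (i > 1 && std::abs(F[idx(i - 1, j)] + gap_extend - f) < eps &&
          !(std::abs(H[idx(i - 1, j)] + gap_open + gap_extend - f) < eps)) {
        --i;
      } else { --i; state = 0; }
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ab.begin(), ab.end());

  int matches = 0, cols = aa.size();
  for (size_t c = 0; c < aa.size(); ++c)
    if (aa[c] != '-' && ab[c] != '-' && enc(aa[c]) >= 0 &&
        enc(aa[c]) == enc(ab[c]))
      ++matches;

  return List::create(
      _["score"] = best,
      _["a_start"] = i, _["a_end"] = bi,   // 0-based half-open in a
      _["b_start"] = j, _["b_end"] = bj,
      _["aln_a"] = aa, _["aln_b"] = ab,
      _["matches"] = matches, _["columns"] = cols);
}

// ---------------------------------------------------------------------------
// Exact k-mer matches between a and b, merged into maximal exact segments on
// each diagonal.  Returns an integer matrix with columns q_start, s_start,
// len (all 0-based).  k-mers occurring more than max_occ times in b are
// skipped.  self_mode = 1 restricts output to q_start < s_start (upper
// triangle of a self-comparison; the main diagonal is excluded).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix kmer_segments_cpp(std::string a, std::string b, int k,
                                int max_occ, int self_mode) {
  const int n = a.size(), m = b.size();
  IntegerMatrix empty(0, 3);
  if (n < k || m < k || k < 1 || k > 31) return empty;

  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  // hash b k-mers
  std::unordered_map<uint64_t, std::vector<int>> tab;
  tab.reserve(m);
  {
    uint64_t h = 0; int run = 0;
    for (int j = 0; j < m; ++j) {
      int c = enc(b[j]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) tab[h].push_back(j - k + 1);
    }
  }
  std::vector<int64_t> keys; // (diag << 32) | q  for sorting
  std::vector<std::pair<int,int>> pairs; // (q, s)
  {
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = enc(a[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto it = tab.find(h);
        if (it == tab.end()) continue;
        if ((int)it->second.size() > max_occ) continue;
        int q = i - k + 1;
        for (int s : it->second) {
          // self comparison: upper triangle only; offsets closer than k are
          // tandem-array territory (SSR detector), not dispersed repeats
          if (self_mode == 1 && s - q < k) continue;
          pairs.push_back(std::make_pair(q, s));
        }
      }
    }
  }
  if (pairs.empty()) return empty;
  // sort by (diagonal, q)
  std::sort(pairs.begin(), pairs.end(),
            [](const std::pair<int,int> &x, const std::pair<int,int> &y) {
              long dx = (long)x.first - x.second, dy = (long)y.first - y.second;
              if (dx != dy) return dx < dy;
              return x.first < y.first;
            });
  std::vector<int> qs, ss, ls;
  int cq = pairs[0].first, cs = pairs[0].second, clen = k;
  for (size_t t = 1; t < pairs.size(); ++t) {
    long d0 = (long)cq - cs, d1 = (long)pairs[t].first - pairs[t].second;
    if (d1 == d0 && pairs[t].first <= cq + clen) {
      clen = pairs[t].first + k - cq;
    } else {
      qs.push_back(cq); ss.push_back(cs); ls.push_back(clen);
      cq = pairs[t].first; cs = pairs[t].second; clen = k;
    }
  }
  qs.push_back(cq); ss.push_back(cs); ls.push_back(clen);
  IntegerMatrix out(qs.size(), 3);
  for (size_t t = 0; t < qs.size(); ++t) {
    out(t, 0) = qs[t]; out(t, 1) = ss[t]; out(t, 2) = ls[t];
  }
  colnames(out) = CharacterVector::create("q_start", "s_start", "len");
  return out;
}

// ---------------------------------------------------------------------------
// Exact palindrome scan: maximal pairs of reverse-complementary arms whose
// spacer is <= max_spacer.  Returns matrix (left_start, arm_len, spacer),
// 0-based; arm_len >= min_len.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix palindrome_scan_cpp(std::string s, int min_len, int max_spacer) {
  const int n = s.size();
  std::vector<int> starts, lens, gaps;
  for (int g = 0; g <= max_spacer; ++g) {
    for (int c = 1; c + g <= n; ++c) { // left arm ends at c (exclusive)
      int l = c - 1, r = c + g;
      int L = 0;
      while (l >= 0 && r < n && enc(s[l]) >= 0 && comp(s[l]) == s[r]) {
        --l; ++r; ++L;
      }
      if (L >= min_len) {
        // only report maximal (extension stopped by mismatch or boundary)
        starts.push_back(c - L); lens.push_back(L); gaps.push_back(g);
      }
    }
  }
  IntegerMatrix out(starts.size(), 3);
  for (size_t t = 0; t < starts.size(); ++t) {
    out(t, 0) = starts[t]; out(t, 1) = lens[t]; out(t, 2) = gaps[t];
  }
  colnames(out) = CharacterVector::create("left_start", "arm_len", "spacer");
  return out;
}

// ---------------------------------------------------------------------------
// Maximal tandem runs of primitive motifs of size 1..max_motif.
// Returns matrix (start, motif_len, run_len), 0-based; run_len >= 2*motif_len.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix ssr_runs_cpp(std::string s, int max_motif) {
  const int n = s.size();
  std::vector<int> st, ml, rl;
  for (int m = 1; m <= max_motif; ++m) {
    for (int i = 0; i + 2 * m <= n; ++i) {
      if (i >= m && s[i] == s[i - m]) continue; // not a run start
      bool okbase = true;
      for (int t = 0; t < m; ++t) if (enc(s[i + t]) < 0) { okbase = false; break; }
      if (!okbase) continue;
      // primitivity of motif s[i..i+m)
      bool prim = true;
      for (int d = 1; d < m; ++d) {
        if (m % d) continue;
        bool per = true;
        for (int t = d; t < m; ++t)
          if (s[i + t] != s[i + t - d]) { per = false; break; }
        if (per) { prim = false; break; }
      }
      if (!prim) continue;
      int j = i + m;
      while (j < n && enc(s[j]) >= 0 && s[j] == s[j - m]) ++j;
      int run = j - i;
      if (run >= 2 * m) { st.push_back(i); ml.push_back(m); rl.push_back(run); }
    }
  }
  IntegerMatrix out(st.size(), 3);
  for (size_t t = 0; t < st.size(); ++t) {
    out(t, 0) = st[t]; out(t, 1) = ml[t]; out(t, 2) = rl[t];
  }
  colnames(out) = CharacterVector::create("start", "motif_len", "run_len");
  return out;
}
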