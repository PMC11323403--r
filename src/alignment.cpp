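#include <Rcpp.h>
using namespace Rcpp;

// Linear-gap global alignment machinery. Scores are doubled internally where
// halves can arise (profile columns average two per-row scores), so all DP
// arithmetic stays in integers. A band > 0 restricts the DP to |i - j| <=
// band (auto-widened to cover the length difference); the result is exact
// whenever the optimal path stays inside the band, which holds for
// near-identical sequences.

static inline int base_score2(char a, char b, int match2, int mismatch2) {
  // N matches nothing; gaps inside a profile column score as mismatch.
  if (a == '-' || b == '-' || a == 'N' || b == 'N') return mismatch2;
  return (a == b) ? match2 : mismatch2;
}

static const int NEG = INT_MIN / 4;

// Banded/full DP core with deterministic tie-breaking (diagonal, then up =
// gap in the column sequence, then left). col_score(i, j) is the doubled
// score of aligning row i with column j (1-based). Returns the traceback
// string over {D, U, L} and the doubled optimal score.
template <typename ColScore>
static std::pair<std::string, int> nw_core(int n, int m, int gap2, int band,
                                           ColScore col_score) {
  if (band > 0) band = std::max(band, std::abs(n - m) + 1);
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);

  for (int j = 0; j <= m; ++j) {
    prev[j] = (band > 0 && j > band) ? NEG : j * gap2;
    tb[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band > 0) { jlo = std::max(1, i - band); jhi = std::min(m, i + band); }
    // only the band fringe needs explicit NEG: the next row reads
    // prev[jlo' - 1 .. jhi' ] which stays within [jlo - 1, jhi + 1]
    if (jlo > 1) cur[jlo - 1] = NEG;
    cur[0] = (band > 0 && i > band) ? NEG : i * gap2;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = jlo; j <= jhi; ++j) {
      int d = prev[j - 1] <= NEG ? NEG : prev[j - 1] + col_score(i, j);
      int u = prev[j] <= NEG ? NEG : prev[j] + gap2;
      int l = cur[j - 1] <= NEG ? NEG : cur[j - 1] + gap2;
      int best = d; unsigned char dir = 0;
      if (u > best) { best = u; dir = 1; }
      if (l > best) { best = l; dir = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = dir;
    }
    if (jhi < m) cur[jhi + 1] = NEG;
    std::swap(prev, cur);
  }
  int score2 = prev[m];

  std::string trace;
  trace.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && dir == 0) { trace.push_back('D'); --i; --j; }
    else if (i > 0 && (dir == 1 || j == 0)) { trace.push_back('U'); --i; }
    else { trace.push_back('L'); --j; }
  }
  std::reverse(trace.begin(), trace.end());
  return {trace, score2};
}

// [[Rcpp::export]]
List nw_align_cpp(std::string s1, std::string s2,
                  int match, int mismatch, int gap, int band = 0) {
  const int n = s1.size(), m = s2.size();
  const int match2 = 2 * match, mismatch2 = 2 * mismatch, gap2 = 2 * gap;

  auto res = nw_core(n, m, gap2, band, [&](int i, int j) {
    return base_score2(s1[i - 1], s2[j - 1], match2, mismatch2);
  });

  std::string a1, a2;
  a1.reserve(res.first.size()); a2.reserve(res.first.size());
  int i = 0, j = 0;
  for (char c : res.first) {
    if (c == 'D') { a1.push_back(s1[i++]); a2.push_back(s2[j++]); }
    else if (c == 'U') { a1.push_back(s1[i++]); a2.push_back('-'); }
    else { a1.push_back('-'); a2.push_back(s2[j++]); }
  }
  return List::create(_["aligned1"] = a1, _["aligned2"] = a2,
                      _["score"] = res.second / 2.0);
}

// Align a sequence to a two-row gapped profile. Column score against an
// outgroup character is the mean of the two per-row match/mismatch scores
// (a gap row char scores as mismatch); gap penalty is linear on both sides.
// [[Rcpp::export]]
List nw_profile_align_cpp(std::string p1, std::string p2, std::string s,
                          int match, int mismatch, int gap, int band = 0) {
  const int n = p1.size(), m = s.size();
  const int match2 = 2 * match, mismatch2 = 2 * mismatch, gap2 = 2 * gap;

  auto res = nw_core(n, m, gap2, band, [&](int i, int j) {
    return (base_score2(p1[i - 1], s[j - 1], match2, mismatch2) +
            base_score2(p2[i - 1], s[j - 1], match2, mismatch2)) / 2;
  });

  std::string o1, o2, o3;
  o1.reserve(res.first.size()); o2.reserve(res.first.size());
  o3.reserve(res.first.size());
  int i = 0, j = 0;
  for (char c : res.first) {
    if (c == 'D') {
      o1.push_back(p1[i]); o2.push_back(p2[i]); ++i; o3.push_back(s[j++]);
    } else if (c == 'U') {
      o1.push_back(p1[i]); o2.push_back(p2[i]); ++i; o3.push_back('-');
    } else { o1.push_back('-'); o2.push_back('-'); o3.push_back(s[j++]); }
  }
  return List::create(_["aligned1"] = o1, _["aligned2"] = o2,
                      _["aligned3"] = o3, _["score"] = res.second / 2.0);
}

// Exact three-sequence sum-of-pairs global alignment (cubic DP). Intended for
// short sequences only (oracle use); returns the optimal SP score.
// Pair scores: char/char as usual, char/gap = gap penalty, gap/gap = 0.
// [[Rcpp::export]]
double nw3_sp_score_cpp(std::string s1, std::string s2, std::string s3,
                        int match, int mismatch, int gap) {
  const int n1 = s1.size(), n2 = s2.size(), n3 = s3.size();
  const int match2 = 2 * match, mismatch2 = 2 * mismatch, gap2 = 2 * gap;
  const long LNEG = LONG_MIN / 4;
  const size_t d2 = (size_t)(n2 + 1) * (n3 + 1);
  std::vector<long> prev(d2), cur(d2);

  auto idx = [&](int j, int k) { return (size_t)j * (n3 + 1) + k; };
  auto pscore = [&](char a, char b) {
    return base_score2(a, b, match2, mismatch2);
  };

  // i = 0 layer
  for (int j = 0; j <= n2; ++j)
    for (int k = 0; k <= n3; ++k) {
      if (j == 0 && k == 0) { prev[idx(j, k)] = 0; continue; }
      long best = LNEG;
      if (j > 0 && k > 0)
        best = std::max(best, prev[idx(j - 1, k - 1)] +
                              pscore(s2[j - 1], s3[k - 1]) + 2 * gap2);
      if (j > 0) best = std::max(best, prev[idx(j - 1, k)] + 2 * gap2);
      if (k > 0) best = std::max(best, prev[idx(j, k - 1)] + 2 * gap2);
      prev[idx(j, k)] = best;
    }

  for (int i = 1; i <= n1; ++i) {
    for (int j = 0; j <= n2; ++j)
      for (int k = 0; k <= n3; ++k) {
        long best = LNEG;
        char c1 = s1[i - 1];
        if (j > 0 && k > 0)
          best = std::max(best, prev[idx(j - 1, k - 1)] +
                                pscore(c1, s2[j - 1]) + pscore(c1, s3[k - 1]) +
                                pscore(s2[j - 1], s3[k - 1]));
        if (j > 0)
          best = std::max(best, prev[idx(j - 1, k)] +
                                pscore(c1, s2[j - 1]) + 2 * gap2);
        if (k > 0)
          best = std::max(best, prev[idx(j, k - 1)] +
                                pscore(c1, s3[k - 1]) + 2 * gap2);
        best = std::max(best, prev[idx(j, k)] + 2 * gap2);
        if (j > 0 && k > 0)
          best = std::max(best, cur[idx(j - 1, k - 1)] +
                                pscore(s2[j - 1], s3[k - 1]) + 2 * gap2);
        if (j > 0) best = std::max(best, cur[idx(j - 1, k)] + 2 * gap2);
        if (k > 0) best = std::max(best, cur[idx(j, k - 1)] + 2 * gap2);
        cur[idx(j, k)] = best;
      }
    std::swap(prev, cur);
  }
  return prev[idx(n2, n3)] / 2.0;
}
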