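#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch global alignment with linear gap scoring and
// deterministic traceback (prefer diagonal, then up = gap in b,
// then left = gap in a).
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b,
              double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix T(n + 1, m + 1); // 0 diag, 1 up, 2 left
  for (int i = 1; i <= n; ++i) { S(i, 0) = i * gap; T(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { S(0, j) = j * gap; T(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sub = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double up = S(i - 1, j) + gap;
      double left = S(i, j - 1) + gap;
      // ties resolved diagonal > up > left
      double best = sub; int dir = 0;
      if (up > best) { best = up; dir = 1; }
      if (left > best) { best = left; dir = 2; }
      S(i, j) = best; T(i, j) = dir;
    }
  }
  std::string aa, bb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int dir = T(i, j);
    if (i > 0 && j > 0 && dir == 0) {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["a"] = aa, _["b"] = bb, _["score"] = S(n, m));
}

// Pairwise mismatch/comparable-column counts for a set of equal-length
// aligned sequences; columns where either sequence has '-' or 'N' are
// excluded.
// [[Rcpp::export(name = ".pi_counts")]]
List pi_counts(std::vector<std::string> seqs) {
  const int k = seqs.size();
  IntegerMatrix matches(k, k), comparable(k, k);
  for (int i = 0; i < k; ++i) {
    for (int j = i + 1; j < k; ++j) {
      const std::string &x = seqs[i], &y = seqs[j];
      int nm = 0, nc = 0;
      const size_t L = std::min(x.size(), y.size());
      for (size_t p = 0; p < L; ++p) {
        char cx = x[p], cy = y[p];
        if (cx == '-' || cy == '-' || cx == 'N' || cy == 'N') continue;
        ++nc;
        if (cx == cy) ++nm;
      }
      matches(i, j) = matches(j, i) = nm;
      comparable(i, j) = comparable(j, i) = nc;
    }
  }
  return List::create(_["matches"] = matches, _["comparable"] = comparable);
}
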