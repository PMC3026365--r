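#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalties.
// Traceback ties are resolved diagonal > up > left, chosen at fill time so
// the result is unique and deterministic. "up" consumes a character of `a`
// (gap in `b`), "left" consumes a character of `b`.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  // pointers: 0 = diag, 1 = up, 2 = left
  std::vector<unsigned char> ptr((n + 1) * (size_t)(m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = j * gap; if (j) ptr[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    ptr[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double sup = prev[j] + gap;
      double sleft = cur[j - 1] + gap;
      double best = sdiag; unsigned char p = 0;
      if (sup > best) { best = sup; p = 1; }
      if (sleft > best) { best = sleft; p = 2; }
      cur[j] = best;
      ptr[(size_t)i * (m + 1) + j] = p;
    }
    std::swap(prev, cur);
  }
  double score = prev[m];
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char p = ptr[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && p == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && (p == 1 || j == 0)) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}
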