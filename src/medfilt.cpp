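#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// reflect index i into [0, n-1] (symmetric half-sample reflection:
// -1 -> 0, n -> n-1), matching pad(mode = "reflect-even")
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix masked_median_filter(NumericMatrix x, LogicalMatrix mask,
                                   int window) {
  const int nr = x.nrow(), nc = x.ncol();
  if (window < 1 || window % 2 == 0)
    stop("window must be a positive odd integer");
  const int h = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)window * window);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) {
        out(i, j) = NA_REAL;
        continue;
      }
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        const int jj = reflect(j + dj, nc);
        for (int di = -h; di <= h; ++di) {
          const int ii = reflect(i + di, nr);
          if (mask(ii, jj)) buf.push_back(x(ii, jj));
        }
      }
      const size_t n = buf.size();
      if (n == 0) {
        out(i, j) = NA_REAL;  // unreachable: the centre pixel is valid
        continue;
      }
      const size_t mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (n % 2 == 0) {
        double lower = *std::max_element(buf.begin(), buf.begin() + mid);
        med = (med + lower) / 2.0;
      }
      out(i, j) = med;
    }
  }
  return out;
}
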