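#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// mirror reflection without repeating the edge sample (0-based)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int p = 2 * (n - 1);
  i = std::abs(i) % p;
  return (i >= n) ? p - i : i;
}

// [[Rcpp::export]]
NumericMatrix disk_median_filter(NumericMatrix img, int radius) {
  int h = img.nrow(), w = img.ncol();
  std::vector<int> dy, dx;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dy.push_back(a); dx.push_back(b); }
  int m = dy.size();
  NumericMatrix out(h, w);
  std::vector<double> buf(m);
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      for (int k = 0; k < m; ++k) {
        int rr = reflect_idx(r + dy[k], h);
        int cc = reflect_idx(c + dx[k], w);
        buf[k] = img(rr, cc);
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      double med = buf[m / 2];
      if (m % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
        med = 0.5 * (lo + med);
      }
      out(r, c) = med;
    }
  }
  return out;
}
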