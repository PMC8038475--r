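#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Quality-guided flood-fill phase unwrapping.
//
// Pixels are admitted in decreasing order of quality starting from the
// highest-quality masked pixel; each new pixel is unwrapped against the
// already-unwrapped neighbour through which it was reached by adding the
// multiple of 2*pi that minimises the jump. Ties in quality are broken by
// linear index (smaller first), making the result deterministic.
//
// wrapped: matrix of wrapped phases; quality: same-shape quality map;
// mask: logical, pixels to unwrap. Returns matrix with NA outside mask.
// [[Rcpp::export(name = ".unwrap_quality_cpp")]]
NumericMatrix unwrap_quality_cpp(NumericMatrix wrapped,
                                 NumericMatrix quality,
                                 LogicalMatrix mask) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  const double TWO_PI = 2.0 * M_PI;
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<char> done(static_cast<size_t>(nr) * nc, 0);

  // priority: higher quality first, then smaller linear index
  typedef std::pair<double, long> Item;  // (quality, -index)
  std::priority_queue<Item> pq;

  long start = -1;
  double best = -1e300;
  for (long i = 0; i < static_cast<long>(nr) * nc; ++i) {
    if (mask[i] && quality[i] > best) { best = quality[i]; start = i; }
  }
  if (start < 0) return out;
  out[start] = wrapped[start];
  done[start] = 1;
  pq.push(Item(quality[start], -start));

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    long idx = -pq.top().second;
    pq.pop();
    int c = static_cast<int>(idx / nr), r = static_cast<int>(idx % nr);
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      long j = static_cast<long>(cc) * nr + rr;
      if (done[j] || !mask[j]) continue;
      double ref = out[idx];
      double w = wrapped[j];
      out[j] = w + TWO_PI * std::round((ref - w) / TWO_PI);
      done[j] = 1;
      pq.push(Item(quality[j], -j));
    }
  }
  return out;
}
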