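#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// LZ-76 exhaustive-history parsing count (Kaspar-Schuster scan).
// The final block is counted whether or not it is novel.
// [[Rcpp::export]]
int lz76_count_cpp(std::string s) {
  const int n = (int)s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// Grid-cell transition symbols for a polyline. Cells are half-open
// [k*cell, (k+1)*cell); points on the top/right boundary belong to the last
// cell. Each segment is subdivided at exact line-grid intersections and
// crossings are emitted in traversal order; at an exact corner hit the
// x-crossing precedes the y-crossing.
// [[Rcpp::export]]
std::string symbolize_cpp(NumericVector xs, NumericVector ys, double cell,
                          int nx, int ny) {
  const int n = xs.size();
  std::string out;
  if (n < 2) return out;
  auto cellix = [cell](double v, int ncell) {
    int k = (int)std::floor(v / cell);
    if (k < 0) k = 0;
    if (k >= ncell) k = ncell - 1;
    return k;
  };
  out.reserve((size_t)n);
  std::vector<std::pair<double, char> > ev;
  for (int i = 0; i + 1 < n; ++i) {
    const double x0 = xs[i], y0 = ys[i], x1 = xs[i + 1], y1 = ys[i + 1];
    const int cx0 = cellix(x0, nx), cx1 = cellix(x1, nx);
    const int cy0 = cellix(y0, ny), cy1 = cellix(y1, ny);
    if (cx0 == cx1 && cy0 == cy1) continue;
    ev.clear();
    if (cx1 > cx0) {
      for (int k = cx0 + 1; k <= cx1; ++k)
        ev.push_back(std::make_pair((k * cell - x0) / (x1 - x0), 'r'));
    } else if (cx1 < cx0) {
      for (int k = cx0; k >= cx1 + 1; --k)
        ev.push_back(std::make_pair((k * cell - x0) / (x1 - x0), 'l'));
    }
    if (cy1 > cy0) {
      for (int k = cy0 + 1; k <= cy1; ++k)
        ev.push_back(std::make_pair((k * cell - y0) / (y1 - y0), 'u'));
    } else if (cy1 < cy0) {
      for (int k = cy0; k >= cy1 + 1; --k)
        ev.push_back(std::make_pair((k * cell - y0) / (y1 - y0), 'd'));
    }
    // x events were inserted first, so a stable sort on the parameter alone
    // keeps them ahead of y events at equal values (corner tie-break).
    std::stable_sort(ev.begin(), ev.end(),
                     [](const std::pair<double, char>& a,
                        const std::pair<double, char>& b) {
                       return a.first < b.first;
                     });
    for (size_t j = 0; j < ev.size(); ++j) out.push_back(ev[j].second);
  }
  return out;
}
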