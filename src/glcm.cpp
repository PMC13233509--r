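#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Moving-window GLCM texture maps.
//
// For every pixel whose window fits inside the raster, a symmetric normalized
// co-occurrence table is built per direction (0, 45, 90, 135 degrees at
// 1-pixel offset) from the valid pixel pairs of the centred window, the eight
// Haralick-style statistics are computed, and the directional values are
// averaged. Directions without valid pairs are excluded from the average;
// pixels with no valid pairs at all (or incomplete windows at the border)
// stay NA. The zero-variance correlation convention is COR = 0.
//
// [[Rcpp::export]]
List cpp_glcm_maps(IntegerMatrix q, int window) {
  const int nr = q.nrow(), nc = q.ncol();
  if (window < 3 || window % 2 == 0)
    stop("window must be odd and >= 3");
  if (nr < window || nc < window)
    stop("raster smaller than the moving window");
  const int h = (window - 1) / 2;
  static const int dr[4] = {0, -1, -1, -1};
  static const int dc[4] = {1, 1, 0, -1};

  NumericMatrix MEA(nr, nc), VAR(nr, nc), HOM(nr, nc), CON(nr, nc),
      DIS(nr, nc), ENT(nr, nc), SEM(nr, nc), COR(nr, nc);
  NumericMatrix* out[8] = {&MEA, &VAR, &HOM, &CON, &DIS, &ENT, &SEM, &COR};
  for (int k = 0; k < 8; ++k)
    std::fill(out[k]->begin(), out[k]->end(), NA_REAL);

  std::vector<long long> keys;
  keys.reserve(4 * window * window);

  for (int r = h; r < nr - h; ++r) {
    for (int c = h; c < nc - h; ++c) {
      double acc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
      int ndir = 0;
      for (int d = 0; d < 4; ++d) {
        double s = 0, ss = 0, sx = 0, con = 0, dis = 0, hom = 0;
        int n2 = 0;
        keys.clear();
        for (int i = r - h; i <= r + h; ++i) {
          for (int j = c - h; j <= c + h; ++j) {
            const int i2 = i + dr[d], j2 = j + dc[d];
            if (i2 < r - h || i2 > r + h || j2 < c - h || j2 > c + h)
              continue;
            const int a = q(i, j), b = q(i2, j2);
            if (a == NA_INTEGER || b == NA_INTEGER) continue;
            n2 += 2;  // symmetric: count (a,b) and (b,a)
            s += (double)a + b;
            ss += (double)a * a + (double)b * b;
            sx += 2.0 * (double)a * b;
            const double dd = (double)a - b;
            con += 2.0 * dd * dd;
            dis += 2.0 * std::fabs(dd);
            hom += 2.0 / (1.0 + dd * dd);
            keys.push_back((long long)a * 1000000LL + b);
            keys.push_back((long long)b * 1000000LL + a);
          }
        }
        if (n2 == 0) continue;
        ++ndir;
        const double mu = s / n2;
        double var = ss / n2 - mu * mu;
        if (var < 0) var = 0;
        const double cov = sx / n2 - mu * mu;
        std::sort(keys.begin(), keys.end());
        double ent = 0, sem = 0;
        size_t k = 0;
        while (k < keys.size()) {
          size_t j = k;
          while (j < keys.size() && keys[j] == keys[k]) ++j;
          const double p = (double)(j - k) / n2;
          ent -= p * std::log(p);
          sem += p * p;
          k = j;
        }
        acc[0] += mu;
        acc[1] += var;
        acc[2] += hom / n2;
        acc[3] += con / n2;
        acc[4] += dis / n2;
        acc[5] += ent;
        acc[6] += sem;
        acc[7] += (var > 1e-12) ? cov / var : 0.0;
      }
      if (ndir > 0)
        for (int k = 0; k < 8; ++k) (*out[k])(r, c) = acc[k] / ndir;
    }
  }
  return List::create(_["Mea"] = MEA, _["Var"] = VAR, _["Hom"] = HOM,
                      _["Con"] = CON, _["Dis"] = DIS, _["Ent"] = ENT,
                      _["Sem"] = SEM, _["Cor"] = COR);
}
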