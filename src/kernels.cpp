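#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask under 4- or 8-connectivity.
// Labels are assigned in column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  static const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int di4[4] = {-1, 1, 0, 0};
  static const int dj4[4] = {0, 0, -1, 1};
  const int ndir = (connectivity == 8) ? 8 : 4;
  const int *di = (connectivity == 8) ? di8 : di4;
  const int *dj = (connectivity == 8) ? dj8 : dj4;
  std::vector<int> qi, qj;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      lab(i, j) = next;
      while (!qi.empty()) {
        const int ci = qi.back(), cj = qj.back();
        qi.pop_back(); qj.pop_back();
        for (int d = 0; d < ndir; ++d) {
          const int ni = ci + di[d], nj = cj + dj[d];
          if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            qi.push_back(ni); qj.push_back(nj);
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Minimum pixel-center-to-pixel-center distance (in pixel units) between
// every pair of labeled regions.  The minimum over full pixel sets is
// attained between 4-boundary pixels, so only those are scanned.
// [[Rcpp::export]]
NumericMatrix min_pair_dist_cpp(IntegerMatrix lab, int k) {
  const int nr = lab.nrow(), nc = lab.ncol();
  std::vector< std::vector<int> > bi(k), bj(k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int l = lab(i, j);
      if (!l) continue;
      bool edge = (i == 0 || i == nr - 1 || j == 0 || j == nc - 1);
      if (!edge)
        edge = lab(i - 1, j) != l || lab(i + 1, j) != l ||
               lab(i, j - 1) != l || lab(i, j + 1) != l;
      if (edge) { bi[l - 1].push_back(i); bj[l - 1].push_back(j); }
    }
  }
  NumericMatrix D(k, k);
  std::fill(D.begin(), D.end(), R_PosInf);
  for (int a = 0; a < k; ++a) {
    D(a, a) = 0.0;
    for (int b = a + 1; b < k; ++b) {
      double best = R_PosInf;
      const std::vector<int> &ai = bi[a], &aj = bj[a];
      const std::vector<int> &ci = bi[b], &cj = bj[b];
      for (size_t p = 0; p < ai.size(); ++p) {
        for (size_t q = 0; q < ci.size(); ++q) {
          const double d1 = ai[p] - ci[q], d2 = aj[p] - cj[q];
          const double d = d1 * d1 + d2 * d2;
          if (d < best) best = d;
        }
      }
      best = std::sqrt(best);
      D(a, b) = best;
      D(b, a) = best;
    }
  }
  return D;
}

// Deposit localization events into a pixel grid.  sigma <= 0 bins each
// event into the pixel containing it; sigma > 0 spreads each event with a
// per-pixel-integrated isotropic Gaussian (truncated at 4 sigma),
// normalized so the full-plane integral equals the event weight.
// Pixel (i, j) covers [x0 + j*px, x0 + (j+1)*px) x [y0 + i*px, y0 + (i+1)*px).
// [[Rcpp::export]]
NumericMatrix render_cpp(NumericVector x, NumericVector y, NumericVector w,
                         int nr, int nc, double px, double x0, double y0,
                         double sigma) {
  NumericMatrix img(nr, nc);
  const int n = x.size();
  if (sigma <= 0) {
    for (int e = 0; e < n; ++e) {
      const int j = (int)std::floor((x[e] - x0) / px);
      const int i = (int)std::floor((y[e] - y0) / px);
      if (i >= 0 && j >= 0 && i < nr && j < nc) img(i, j) += w[e];
    }
    return img;
  }
  const double half = 4.0 * sigma;
  const double s2 = sigma * std::sqrt(2.0);
  for (int e = 0; e < n; ++e) {
    const double ex = x[e], ey = y[e];
    const int j0 = std::max(0, (int)std::floor((ex - half - x0) / px));
    const int j1 = std::min(nc - 1, (int)std::floor((ex + half - x0) / px));
    const int i0 = std::max(0, (int)std::floor((ey - half - y0) / px));
    const int i1 = std::min(nr - 1, (int)std::floor((ey + half - y0) / px));
    if (j0 > j1 || i0 > i1) continue;
    std::vector<double> fx(j1 - j0 + 1), fy(i1 - i0 + 1);
    for (int j = j0; j <= j1; ++j)
      fx[j - j0] = 0.5 * (std::erf((x0 + (j + 1) * px - ex) / s2) -
                          std::erf((x0 + j * px - ex) / s2));
    for (int i = i0; i <= i1; ++i)
      fy[i - i0] = 0.5 * (std::erf((y0 + (i + 1) * px - ey) / s2) -
                          std::erf((y0 + i * px - ey) / s2));
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i)
        img(i, j) += w[e] * fx[j - j0] * fy[i - i0];
  }
  return img;
}
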