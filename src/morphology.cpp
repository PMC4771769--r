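#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Shared worker for grayscale erosion/dilation by a (possibly non-flat)
// structuring function. Erosion: min_s { f(x + s) - b(s) }; dilation (with
// the symmetric elements used here): max_s { f(x + s) + b(s) }. Offsets
// falling outside the image are skipped (padding with +/-Inf). Interior
// pixels, where the whole element fits, use precomputed linear offsets.
static NumericMatrix gray_morph(const NumericMatrix& img,
                                const IntegerVector& dr,
                                const IntegerVector& dc,
                                const NumericVector& h,
                                bool erode) {
  const int nr = img.nrow(), nc = img.ncol(), k = dr.size();
  NumericMatrix out(nr, nc);
  const double* f = img.begin();
  double* o = out.begin();
  const int* pdr = dr.begin();
  const int* pdc = dc.begin();
  const double* ph = h.begin();
  const double sgn = erode ? 1.0 : -1.0; // erode: min(f-h); dilate: -min(-f-h)

  int rmax = 0, cmax = 0;
  std::vector<long> loff(k);
  std::vector<double> hh(k);
  for (int t = 0; t < k; ++t) {
    if (std::abs(pdr[t]) > rmax) rmax = std::abs(pdr[t]);
    if (std::abs(pdc[t]) > cmax) cmax = std::abs(pdc[t]);
    loff[t] = (long)pdr[t] + (long)pdc[t] * nr;
    hh[t] = ph[t];
  }

  for (int j = 0; j < nc; ++j) {
    const bool jin = (j >= cmax && j < nc - cmax);
    for (int i = 0; i < nr; ++i) {
      const long base = (long)i + (long)j * nr;
      double m = R_PosInf;
      if (jin && i >= rmax && i < nr - rmax) {
        for (int t = 0; t < k; ++t) {
          const double v = sgn * f[base + loff[t]] - hh[t];
          if (v < m) m = v;
        }
      } else {
        for (int t = 0; t < k; ++t) {
          const int ii = i + pdr[t], jj = j + pdc[t];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          const double v = sgn * f[(long)ii + (long)jj * nr] - hh[t];
          if (v < m) m = v;
        }
      }
      o[base] = sgn * m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(const NumericMatrix& img,
                             const IntegerVector& dr,
                             const IntegerVector& dc,
                             const NumericVector& h) {
  return gray_morph(img, dr, dc, h, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(const NumericMatrix& img,
                              const IntegerVector& dr,
                              const IntegerVector& dc,
                              const NumericVector& h) {
  return gray_morph(img, dr, dc, h, false);
}

// Connected-component labelling of a logical mask, 4- or 8-connectivity,
// breadth-first, labels assigned in column-major scan order of first contact.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  static const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int t = 0; t < nnb; ++t) {
          int ii = p.first + dr8[t], jj = p.second + dc8[t];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}
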