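#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Zero-normalized cross-correlation surface of a template against every
// placement inside a larger search region (template matching). Returns a
// (sw - tw + 1) x (sh - th + 1) matrix of correlation coefficients in
// [-1, 1]; exactly 1 where the patch equals the template up to affine
// intensity scaling. Featureless patches (zero variance) yield 0.
//
// Patch sums and sums of squares come from summed-area tables; only the
// cross term is a direct O(tw*th) loop per offset.
// [[Rcpp::export]]
NumericMatrix ncc_surface(NumericMatrix tmpl, NumericMatrix search) {
  const int tw = tmpl.nrow(), th = tmpl.ncol();
  const int sw = search.nrow(), sh = search.ncol();
  if (sw < tw || sh < th)
    stop("search region smaller than template");
  const int ow = sw - tw + 1, oh = sh - th + 1;
  const double n = (double)tw * th;

  const double *tp = tmpl.begin();
  const double *sp = search.begin();

  double tsum = 0.0, tsq = 0.0;
  for (int k = 0; k < tw * th; ++k) {
    tsum += tp[k]; tsq += tp[k] * tp[k];
  }
  const double tmean = tsum / n;
  const double tvar = tsq - n * tmean * tmean;

  NumericMatrix out(ow, oh);
  if (tvar <= 1e-12) return out;  // flat template: no signal

  // summed-area tables of search and search^2, (sw+1) x (sh+1)
  const int W = sw + 1;
  std::vector<double> sat(W * (sh + 1), 0.0), sat2(W * (sh + 1), 0.0);
  for (int j = 0; j < sh; ++j) {
    double row = 0.0, row2 = 0.0;
    for (int i = 0; i < sw; ++i) {
      const double v = sp[i + j * sw];
      row += v; row2 += v * v;
      sat[(i + 1) + (j + 1) * W] = sat[(i + 1) + j * W] + row;
      sat2[(i + 1) + (j + 1) * W] = sat2[(i + 1) + j * W] + row2;
    }
  }

  for (int oy = 0; oy < oh; ++oy) {
    for (int ox = 0; ox < ow; ++ox) {
      const double psum = sat[(ox + tw) + (oy + th) * W] -
        sat[ox + (oy + th) * W] - sat[(ox + tw) + oy * W] +
        sat[ox + oy * W];
      const double psq = sat2[(ox + tw) + (oy + th) * W] -
        sat2[ox + (oy + th) * W] - sat2[(ox + tw) + oy * W] +
        sat2[ox + oy * W];
      const double pmean = psum / n;
      const double pvar = psq - n * pmean * pmean;
      if (pvar <= 1e-12) { out(ox, oy) = 0.0; continue; }
      double cross = 0.0;
      for (int j = 0; j < th; ++j) {
        const double *scol = sp + ox + (j + oy) * sw;
        const double *tcol = tp + j * tw;
        for (int i = 0; i < tw; ++i)
          cross += scol[i] * tcol[i];
      }
      out(ox, oy) = (cross - n * tmean * pmean) / std::sqrt(tvar * pvar);
    }
  }
  return out;
}
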