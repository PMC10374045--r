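#include <Rcpp.h>
using namespace Rcpp;

// Sliding-lag spectrographic cross-correlation.
//
// A and B are magnitude spectrograms (frequency bins x time frames) computed
// with identical parameters, so they share the same number of rows. The
// shorter spectrogram slides along the longer in single-frame steps; only
// lags where the shorter fully overlaps the longer are scored. At each lag
// the Pearson correlation of co-occurring cells is computed; a lag with zero
// variance on either side scores 0. The returned similarity is the maximum
// over lags, floored at 0.
// [[Rcpp::export]]
double spcc_max_cor_cpp(NumericMatrix A, NumericMatrix B) {
  if (A.nrow() != B.nrow())
    stop("Spectrograms must share the same frequency axis.");
  NumericMatrix X = (A.ncol() <= B.ncol()) ? A : B;  // shorter
  NumericMatrix Y = (A.ncol() <= B.ncol()) ? B : A;  // longer
  const int nr = X.nrow(), nx = X.ncol(), ny = Y.ncol();
  const int n_lags = ny - nx + 1;
  const double n = static_cast<double>(nr) * nx;

  double sx = 0.0, sxx = 0.0;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = X(i, j);
      sx += v;
      sxx += v * v;
    }
  const double vx = n * sxx - sx * sx;

  // per-column sums of Y for windowed mean/variance bookkeeping
  std::vector<double> cs(ny), css(ny);
  for (int j = 0; j < ny; ++j) {
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < nr; ++i) {
      double v = Y(i, j);
      s += v;
      ss += v * v;
    }
    cs[j] = s;
    css[j] = ss;
  }

  double sy = 0.0, syy = 0.0;
  for (int j = 0; j < nx; ++j) {
    sy += cs[j];
    syy += css[j];
  }

  double best = 0.0;
  for (int lag = 0; lag < n_lags; ++lag) {
    if (lag > 0) {
      sy += cs[lag + nx - 1] - cs[lag - 1];
      syy += css[lag + nx - 1] - css[lag - 1];
    }
    double vy = n * syy - sy * sy;
    if (vx > 0.0 && vy > 0.0) {
      double sxy = 0.0;
      for (int j = 0; j < nx; ++j) {
        const double* xc = &X(0, j);
        const double* yc = &Y(0, j + lag);
        for (int i = 0; i < nr; ++i) sxy += xc[i] * yc[i];
      }
      double r = (n * sxy - sx * sy) / std::sqrt(vx * vy);
      if (r > best) best = r;
    }
  }
  if (best > 1.0) best = 1.0;  // guard against rounding
  return best;
}
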