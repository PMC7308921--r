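#include <Rcpp.h>
using namespace Rcpp;

// Online Kohonen training loop. Column-contiguous layout: X and W hold one
// instance / neuron per column (d rows). `order` gives the 1-based visiting
// order per epoch (epochs rows), precomputed in R so all randomness stays in
// R's seeded RNG. Learning rate and neighborhood radius decay linearly from
// their start to end values over the epochs; the Gaussian neighborhood is
// evaluated from the precomputed squared grid distances gd2 (k2 x k2).
// [[Rcpp::export]]
List som_train_cpp(const NumericMatrix& X, const NumericMatrix& W0,
                   const NumericMatrix& gd2, const IntegerMatrix& order,
                   double alpha_start, double alpha_end,
                   double radius_start, double radius_end) {
  const int d = X.nrow(), n = X.ncol(), k2 = W0.ncol();
  const int epochs = order.nrow();
  NumericMatrix W = clone(W0);
  NumericVector qe(epochs);

  for (int e = 0; e < epochs; ++e) {
    double frac = (epochs == 1) ? 0.0 : (double)e / (epochs - 1);
    double a = alpha_start + frac * (alpha_end - alpha_start);
    double sigma = radius_start + frac * (radius_end - radius_start);
    double denom = 2.0 * sigma * sigma;

    for (int ii = 0; ii < n; ++ii) {
      int i = order(e, ii) - 1;
      const double* x = &X(0, i);
      // competition: best-matching unit by squared Euclidean distance
      int bmu = 0;
      double bestd = R_PosInf;
      for (int m = 0; m < k2; ++m) {
        const double* w = &W(0, m);
        double s = 0.0;
        for (int j = 0; j < d && s < bestd; ++j) {
          double diff = w[j] - x[j];
          s += diff * diff;
        }
        if (s < bestd) { bestd = s; bmu = m; }
      }
      // cooperation + adaptation
      for (int m = 0; m < k2; ++m) {
        double h = a * std::exp(-gd2(bmu, m) / denom);
        if (h < 1e-12) continue;
        double* w = &W(0, m);
        for (int j = 0; j < d; ++j) w[j] += h * (x[j] - w[j]);
      }
    }
    // mean quantization error after the epoch
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* x = &X(0, i);
      double bestd = R_PosInf;
      for (int m = 0; m < k2; ++m) {
        const double* w = &W(0, m);
        double s = 0.0;
        for (int j = 0; j < d && s < bestd; ++j) {
          double diff = w[j] - x[j];
          s += diff * diff;
        }
        if (s < bestd) bestd = s;
      }
      tot += std::sqrt(bestd);
    }
    qe[e] = tot / n;
  }
  return List::create(_["weights"] = W, _["qe"] = qe);
}
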