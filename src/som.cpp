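#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Classic online Kohonen training on a rectangular grid.
// data: samples (genes) x dimensions (cells); prototypes: tiles x dims.
// Uses R's RNG (seeded from the R side) for initialization and the
// per-epoch visiting order, so results are reproducible under set.seed.
// Ties in the best-matching-unit search resolve to the lowest tile index.
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix data, int grid_rows, int grid_cols,
                   int epochs, double alpha0, double alpha1,
                   double sigma0, double sigma1, bool trace) {
  const int n = data.nrow(), d = data.ncol();
  const int ntiles = grid_rows * grid_cols;
  NumericMatrix proto(ntiles, d);

  for (int t = 0; t < ntiles; ++t) {
    int pick = (int)std::floor(unif_rand() * n);
    if (pick >= n) pick = n - 1;
    for (int j = 0; j < d; ++j)
      proto(t, j) = data(pick, j) + 0.01 * norm_rand();
  }

  std::vector<double> gr(ntiles), gc(ntiles);
  for (int t = 0; t < ntiles; ++t) {
    gr[t] = t / grid_cols;
    gc[t] = t % grid_cols;
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector qtrace(trace ? epochs : 0);
  const double denom = epochs > 1 ? (double)(epochs - 1) : 1.0;

  for (int e = 0; e < epochs; ++e) {
    const double frac = (double)e / denom;
    const double alpha = alpha0 + (alpha1 - alpha0) * frac;
    const double sigma = sigma0 + (sigma1 - sigma0) * frac;
    const double s2 = 2.0 * sigma * sigma;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int k = 0; k < n; ++k) {
      const int g = order[k];
      int best = 0;
      double bestd = R_PosInf;
      for (int t = 0; t < ntiles; ++t) {
        double acc = 0.0;
        for (int j = 0; j < d; ++j) {
          const double df = data(g, j) - proto(t, j);
          acc += df * df;
        }
        if (acc < bestd) { bestd = acc; best = t; }
      }
      for (int t = 0; t < ntiles; ++t) {
        const double dr = gr[t] - gr[best], dc = gc[t] - gc[best];
        const double h = std::exp(-(dr * dr + dc * dc) / s2);
        if (h < 1e-4) continue;
        const double ah = alpha * h;
        for (int j = 0; j < d; ++j)
          proto(t, j) += ah * (data(g, j) - proto(t, j));
      }
    }
    if (trace) {
      double tot = 0.0;
      for (int g = 0; g < n; ++g) {
        double bestd = R_PosInf;
        for (int t = 0; t < ntiles; ++t) {
          double acc = 0.0;
          for (int j = 0; j < d; ++j) {
            const double df = data(g, j) - proto(t, j);
            acc += df * df;
          }
          if (acc < bestd) bestd = acc;
        }
        tot += std::sqrt(bestd);
      }
      qtrace[e] = tot;
    }
  }

  IntegerVector assign(n);
  NumericVector qerr(n);
  for (int g = 0; g < n; ++g) {
    int best = 0;
    double bestd = R_PosInf;
    for (int t = 0; t < ntiles; ++t) {
      double acc = 0.0;
      for (int j = 0; j < d; ++j) {
        const double df = data(g, j) - proto(t, j);
        acc += df * df;
      }
      if (acc < bestd) { bestd = acc; best = t; }
    }
    assign[g] = best + 1;
    qerr[g] = std::sqrt(bestd);
  }
  return List::create(_["prototypes"] = proto, _["assignment"] = assign,
                      _["qerror"] = qerr, _["qtrace"] = qtrace);
}
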