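#include <Rcpp.h>
using namespace Rcpp;

// Best-matching unit per row of x against the codebook; ties go to the
// lowest cell index (strict < keeps the first minimum).
// [[Rcpp::export]]
List bmu_cpp(const NumericMatrix& codebook, const NumericMatrix& x) {
  const int m = codebook.nrow(), p = codebook.ncol(), n = x.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bestc = 0;
    for (int c = 0; c < m; ++c) {
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = x(i, j) - codebook(c, j);
        d += diff * diff;
        if (d >= best) break;
      }
      if (d < best) { best = d; bestc = c; }
    }
    idx[i] = bestc + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["cell"] = idx, _["distance"] = dist);
}

static double quantization_err(const NumericMatrix& codebook,
                               const NumericMatrix& x) {
  const int m = codebook.nrow(), p = codebook.ncol(), n = x.nrow();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int c = 0; c < m; ++c) {
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = x(i, j) - codebook(c, j);
        d += diff * diff;
        if (d >= best) break;
      }
      if (d < best) best = d;
    }
    acc += std::sqrt(best);
  }
  return acc / n;
}

// Online Kohonen training on pre-scaled data.
//   data      n x p, finite, already standardized
//   codebook  m x p initial state (overwritten in place on a copy)
//   gd2       m x m squared grid distances between cells
//   order     1-based presentation indices, length per_epoch * max_epochs
// sigma and learning rate decay as value0 / (1 + t / (T/2)) over the total
// planned number of presentations T.  An epoch ends every per_epoch
// presentations; training stops once the full-data quantization error has
// failed to improve on its running best by more than tol for `patience`
// consecutive epochs.
// [[Rcpp::export]]
List som_train_cpp(const NumericMatrix& data, const NumericMatrix& codebook0,
                   const NumericMatrix& gd2, const IntegerVector& order,
                   const int per_epoch, const int max_epochs,
                   const double sigma0, const double lr0,
                   const double tol, const int patience) {
  const int m = codebook0.nrow(), p = codebook0.ncol();
  NumericMatrix codebook = clone(codebook0);
  NumericMatrix best_codebook = clone(codebook0);
  const double T = static_cast<double>(per_epoch) * max_epochs;
  std::vector<double> qe_log;
  double best_qe = R_PosInf;
  int streak = 0, epochs_run = 0;
  bool converged = false;
  long t = 0;

  for (int ep = 0; ep < max_epochs && !converged; ++ep) {
    for (int it = 0; it < per_epoch; ++it, ++t) {
      const int i = order[t] - 1;
      // BMU for this presentation
      double best = R_PosInf;
      int bmu = 0;
      for (int c = 0; c < m; ++c) {
        double d = 0.0;
        for (int j = 0; j < p; ++j) {
          const double diff = data(i, j) - codebook(c, j);
          d += diff * diff;
          if (d >= best) break;
        }
        if (d < best) { best = d; bmu = c; }
      }
      const double decay = 1.0 + t / (T / 2.0);
      const double sig = sigma0 / decay;
      const double lr = lr0 / decay;
      const double denom = 2.0 * sig * sig;
      for (int c = 0; c < m; ++c) {
        const double h = std::exp(-gd2(bmu, c) / denom);
        const double step = lr * h;
        if (step < 1e-12) continue;
        for (int j = 0; j < p; ++j) {
          codebook(c, j) += step * (data(i, j) - codebook(c, j));
        }
      }
    }
    epochs_run = ep + 1;
    const double qe = quantization_err(codebook, data);
    qe_log.push_back(qe);
    if (best_qe - qe > tol) {
      best_qe = qe;
      best_codebook = clone(codebook);
      streak = 0;
    } else {
      if (qe < best_qe) { best_qe = qe; best_codebook = clone(codebook); }
      ++streak;
      if (streak >= patience) converged = true;
    }
  }

  return List::create(
    _["codebook"] = best_codebook,
    _["best_qe"] = best_qe,
    _["qe_log"] = NumericVector(qe_log.begin(), qe_log.end()),
    _["epochs"] = epochs_run,
    _["converged"] = converged);
}
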