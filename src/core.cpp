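// Optimization loops for the two stochastic embedding methods. Kept in
// compiled code for speed; both consume R's RNG so results are fully
// reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Exact-gradient T-SNE descent: minimizes KL(P||Q) with momentum and early
// exaggeration (P scaled by the factor, not renormalized, during the early
// phase). P must be symmetric, zero-diagonal, summing to 1.
// [[Rcpp::export]]
List tsne_gd_cpp(const arma::mat& P, const arma::mat& Y0, int n_iter,
                 double alpha, double exag_factor, int exag_iters,
                 int mom_switch, double mom1, double mom2) {
  const int n = Y0.n_rows;
  arma::mat Y = Y0;
  arma::mat dY(n, Y0.n_cols, arma::fill::zeros);
  arma::vec cost(n_iter, arma::fill::zeros);
  int bad_iter = -1;

  // sum_{ij} P log P over positive entries (for the cost trace)
  double slogp = 0.0;
  for (arma::uword t = 0; t < P.n_elem; ++t)
    if (P(t) > 0) slogp += P(t) * std::log(P(t));

  arma::mat W(n, n), M(n, n);
  for (int it = 0; it < n_iter; ++it) {
    double factor = (it < exag_iters) ? exag_factor : 1.0;

    // W = 1 / (1 + squared distances), zero diagonal
    arma::vec s = arma::sum(arma::square(Y), 1);
    W = -2.0 * (Y * Y.t());
    W.each_col() += s;
    W.each_row() += s.t();
    W.transform([](double v) { return 1.0 / (1.0 + (v > 0 ? v : 0)); });
    W.diag().zeros();
    double sumW = arma::accu(W);

    // KL(fP || Q) = f (slogp + log f) - f sum(P log W) + f log sumW
    double plogw = 0.0;
    for (arma::uword t = 0; t < P.n_elem; ++t)
      if (P(t) > 0) plogw += P(t) * std::log(W(t));
    cost(it) = factor * (slogp + std::log(factor)) - factor * plogw
               + factor * std::log(sumW);

    // gradient: 4 * sum_j (fP - Q)_ij W_ij (y_i - y_j)
    M = factor * (P % W) - arma::square(W) / sumW;
    arma::vec rs = arma::sum(M, 1);
    arma::mat grad = 4.0 * ((Y.each_col() % rs) - M * Y);

    double mom = (it < mom_switch) ? mom1 : mom2;
    dY = mom * dY - alpha * grad;
    Y += dY;
    Y.each_row() -= arma::mean(Y, 0);
    if (!Y.is_finite()) { bad_iter = it + 1; break; }
  }
  return List::create(Named("Y") = Y, Named("cost") = cost,
                      Named("bad_iter") = bad_iter);
}

static inline double clip4(double x) {
  return x > 4.0 ? 4.0 : (x < -4.0 ? -4.0 : x);
}

// Per-edge stochastic gradient descent for the UMAP cross-entropy layout.
// head/tail are 0-based endpoints of the undirected edges; edges are
// sampled once every epochs_per_sample epochs, negatives uniformly.
// [[Rcpp::export]]
List umap_sgd_cpp(const NumericMatrix& Y0, const IntegerVector& head,
                  const IntegerVector& tail,
                  const NumericVector& epochs_per_sample, int n_epochs,
                  double alpha0, double a, double b, int neg_rate) {
  const int n = Y0.nrow(), m = Y0.ncol(), n_edges = head.size();
  NumericMatrix Y = clone(Y0);
  NumericVector next_sample = clone(epochs_per_sample);
  NumericVector eps_neg(n_edges), next_neg(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    eps_neg[e] = epochs_per_sample[e] / neg_rate;
    next_neg[e] = eps_neg[e];
  }
  NumericVector displacement(n_epochs);
  NumericMatrix Yprev(n, m);
  int bad_epoch = -1;

  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    double alpha = alpha0 * (1.0 - (double)(epoch - 1) / n_epochs);
    std::copy(Y.begin(), Y.end(), Yprev.begin());

    for (int e = 0; e < n_edges; ++e) {
      if (next_sample[e] > epoch) continue;
      int i = head[e], j = tail[e];
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        double diff = Y(i, c) - Y(j, c);
        d2 += diff * diff;
      }
      double coeff = 0.0;
      if (d2 > 0.0)
        coeff = (-2.0 * a * b * std::pow(d2, b - 1.0)) /
                (1.0 + a * std::pow(d2, b));
      for (int c = 0; c < m; ++c) {
        double g = clip4(coeff * (Y(i, c) - Y(j, c)));
        Y(i, c) += alpha * g;
        Y(j, c) -= alpha * g;
      }
      next_sample[e] += epochs_per_sample[e];

      int n_neg = (int)((epoch - (next_neg[e] - eps_neg[e])) / eps_neg[e]);
      for (int p = 0; p < n_neg; ++p) {
        int k = (int)(unif_rand() * n);
        if (k == i || k >= n) continue;
        double dn2 = 0.0;
        for (int c = 0; c < m; ++c) {
          double diff = Y(i, c) - Y(k, c);
          dn2 += diff * diff;
        }
        double rc;
        if (dn2 > 0.0)
          rc = (2.0 * b) / ((0.001 + dn2) * (1.0 + a * std::pow(dn2, b)));
        else
          rc = 0.0;
        for (int c = 0; c < m; ++c) {
          double g = (dn2 > 0.0) ? clip4(rc * (Y(i, c) - Y(k, c))) : 4.0;
          Y(i, c) += alpha * g;
        }
      }
      next_neg[e] += n_neg * eps_neg[e];
    }

    double disp = 0.0;
    bool finite = true;
    for (int i = 0; i < n; ++i) {
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        double diff = Y(i, c) - Yprev(i, c);
        d2 += diff * diff;
        if (!std::isfinite(Y(i, c))) finite = false;
      }
      disp += std::sqrt(d2);
    }
    displacement[epoch - 1] = disp / n;
    if (!finite) { bad_epoch = epoch; break; }
  }
  return List::create(Named("Y") = Y, Named("displacement") = displacement,
                      Named("bad_epoch") = bad_epoch);
}
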