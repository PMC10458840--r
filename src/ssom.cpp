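// Supervised self-organizing map: online training on two fused codebook
// layers (feature vectors and one-hot class indicators). The winner for a
// training sample minimizes a weighted sum of per-layer squared Euclidean
// distances, each layer divided by its running mean distance scale so the
// feature and indicator layers are commensurable. Winner and neighbours
// (Gaussian kernel on the grid, radius decaying linearly to 1 across
// passes) move toward the sample in both layers with a learning rate
// decaying linearly over all presentations. All randomness (presentation
// orders, initial codebooks) is drawn in R, so training is deterministic
// given its inputs.
#include <Rcpp.h>
using namespace Rcpp;

static double sqdist(const double *a, const double *b, int p) {
  double s = 0.0;
  for (int j = 0; j < p; ++j) {
    double d = a[j] - b[j];
    s += d * d;
  }
  return s;
}

// [[Rcpp::export(name = ".ssom_train")]]
List ssom_train(NumericMatrix X, NumericMatrix Y,
                NumericMatrix codes_x, NumericMatrix codes_y,
                NumericMatrix grid, IntegerMatrix orders,
                double alpha_start, double alpha_end,
                double radius_start, double class_weight) {
  const int n = X.nrow(), p = X.ncol(), K = Y.ncol();
  const int U = codes_x.nrow();
  const int rlen = orders.nrow();
  if (orders.ncol() != n) stop("orders must be rlen x n");

  // column-major access: work on transposed copies (rows contiguous)
  std::vector<double> xs(n * p), ys(n * K), cx(U * p), cy(U * K);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) xs[i * p + j] = X(i, j);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) ys[i * K + k] = Y(i, k);
  for (int u = 0; u < U; ++u)
    for (int j = 0; j < p; ++j) cx[u * p + j] = codes_x(u, j);
  for (int u = 0; u < U; ++u)
    for (int k = 0; k < K; ++k) cy[u * K + k] = codes_y(u, k);

  // squared grid distances between units
  std::vector<double> gd2(U * U);
  for (int u = 0; u < U; ++u)
    for (int v = 0; v < U; ++v) {
      double dx = grid(u, 0) - grid(v, 0), dy = grid(u, 1) - grid(v, 1);
      gd2[u * U + v] = dx * dx + dy * dy;
    }

  // initial layer scales: mean squared distance of data to initial codebooks
  double scale_x = 0.0, scale_y = 0.0;
  for (int i = 0; i < n; ++i)
    for (int u = 0; u < U; ++u) {
      scale_x += sqdist(&xs[i * p], &cx[u * p], p);
      scale_y += sqdist(&ys[i * K], &cy[u * K], K);
    }
  scale_x /= (double)n * U;
  scale_y /= (double)n * U;
  if (scale_x <= 0) scale_x = 1.0;
  if (scale_y <= 0) scale_y = 1.0;
  const double scale_update = 1e-3;

  const double wx = (1.0 - class_weight), wy = class_weight;
  const R_xlen_t total = (R_xlen_t)rlen * n;
  NumericVector energy(rlen);
  R_xlen_t step = 0;

  std::vector<double> kern(U * U);  // per-pass neighbourhood kernel
  for (int pass = 0; pass < rlen; ++pass) {
    double radius = radius_start +
      (1.0 - radius_start) * (rlen > 1 ? (double)pass / (rlen - 1) : 1.0);
    if (radius < 1.0) radius = 1.0;
    const double denom = 2.0 * radius * radius;
    for (int u = 0; u < U * U; ++u) kern[u] = std::exp(-gd2[u] / denom);
    double e_sum = 0.0;
    for (int t = 0; t < n; ++t, ++step) {
      const double alpha = alpha_start +
        (alpha_end - alpha_start) * ((double)step / (double)(total - 1 > 0 ? total - 1 : 1));
      const int i = orders(pass, t) - 1;  // 1-based from R
      const double *xi = &xs[i * p];
      const double *yi = &ys[i * K];
      int best = 0;
      double best_d = R_PosInf, best_dx = 0.0, best_dy = 0.0;
      for (int u = 0; u < U; ++u) {
        double dx = sqdist(xi, &cx[u * p], p);
        double dy = sqdist(yi, &cy[u * K], K);
        double d = wx * dx / scale_x + wy * dy / scale_y;
        if (d < best_d) { best_d = d; best = u; best_dx = dx; best_dy = dy; }
      }
      e_sum += best_d;
      scale_x = (1.0 - scale_update) * scale_x + scale_update * best_dx;
      scale_y = (1.0 - scale_update) * scale_y + scale_update * best_dy;
      if (scale_x <= 0) scale_x = 1e-12;
      if (scale_y <= 0) scale_y = 1e-12;
      const double *g = &kern[(size_t)best * U];
      for (int u = 0; u < U; ++u) {
        double h = alpha * g[u];
        if (h < 1e-6) continue;
        double *cu = &cx[u * p];
        for (int j = 0; j < p; ++j) cu[j] += h * (xi[j] - cu[j]);
        double *du = &cy[u * K];
        for (int k = 0; k < K; ++k) du[k] += h * (yi[k] - du[k]);
      }
    }
    energy[pass] = e_sum / n;
  }

  NumericMatrix out_x(U, p), out_y(U, K);
  for (int u = 0; u < U; ++u) {
    for (int j = 0; j < p; ++j) out_x(u, j) = cx[u * p + j];
    for (int k = 0; k < K; ++k) out_y(u, k) = cy[u * K + k];
  }
  return List::create(_["codes_x"] = out_x, _["codes_y"] = out_y,
                      _["energy"] = energy,
                      _["scale_x"] = scale_x, _["scale_y"] = scale_y);
}

// winner units by the feature layer only (prediction path)
// [[Rcpp::export(name = ".ssom_map")]]
IntegerVector ssom_map(NumericMatrix X, NumericMatrix codes_x) {
  const int n = X.nrow(), p = X.ncol(), U = codes_x.nrow();
  std::vector<double> cx(U * p);
  for (int u = 0; u < U; ++u)
    for (int j = 0; j < p; ++j) cx[u * p + j] = codes_x(u, j);
  IntegerVector out(n);
  std::vector<double> xi(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xi[j] = X(i, j);
    int best = 0;
    double best_d = R_PosInf;
    for (int u = 0; u < U; ++u) {
      double d = sqdist(xi.data(), &cx[u * p], p);
      if (d < best_d) { best_d = d; best = u; }
    }
    out[i] = best + 1;  // 1-based
  }
  return out;
}
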