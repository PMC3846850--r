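#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Parzen (Gaussian kernel) estimators of mutual information, integrated by
// fixed-grid quadrature over the data range extended by 3 bandwidths.
// All returned values are in the log base supplied by the caller
// (base 2 -> bits). Small negative estimates are clipped to zero.

static const double INV_SQRT_2PI = 0.3989422804014327;

// Silverman rule-of-thumb bandwidth: 0.9 * min(sd, IQR/1.34) * n^(-1/5).
// Returns 0 for degenerate (constant) samples; callers must handle that.
static double silverman_bw(const arma::vec &x) {
  const double n = static_cast<double>(x.n_elem);
  if (x.n_elem < 2) return 0.0;
  double s = arma::stddev(x);
  arma::vec probs = {0.25, 0.75};
  arma::vec q = arma::quantile(x, probs);
  double iqr = q(1) - q(0);
  double spread = s;
  if (iqr > 0.0 && iqr / 1.34 < spread) spread = iqr / 1.34;
  if (spread <= 0.0) spread = s;
  return 0.9 * spread * std::pow(n, -0.2);
}

// Gaussian KDE of sample x evaluated on grid t, bandwidth h.
static arma::vec kde_on_grid(const arma::vec &x, const arma::vec &t, double h) {
  const arma::uword g = t.n_elem, n = x.n_elem;
  arma::vec f(g, arma::fill::zeros);
  const double inv_h = 1.0 / h;
  for (arma::uword i = 0; i < n; ++i) {
    const double xi = x(i);
    for (arma::uword a = 0; a < g; ++a) {
      const double u = (t(a) - xi) * inv_h;
      f(a) += std::exp(-0.5 * u * u);
    }
  }
  f *= INV_SQRT_2PI * inv_h / static_cast<double>(n);
  return f;
}

// MI between a continuous value g and a binary class, with per-class
// bandwidths h0, h1 and empirical class priors.
static double mi_1d_core(const arma::vec &x0, const arma::vec &x1,
                         double h0, double h1, int ngrid, double log_base) {
  const double n0 = static_cast<double>(x0.n_elem);
  const double n1 = static_cast<double>(x1.n_elem);
  const double p0 = n0 / (n0 + n1), p1 = n1 / (n0 + n1);
  const double hmax = std::max(h0, h1);
  double lo = std::min(x0.min(), x1.min()) - 3.0 * hmax;
  double hi = std::max(x0.max(), x1.max()) + 3.0 * hmax;
  arma::vec t = arma::linspace(lo, hi, ngrid);
  const double dt = (hi - lo) / static_cast<double>(ngrid - 1);

  arma::vec f0 = kde_on_grid(x0, t, h0);
  arma::vec f1 = kde_on_grid(x1, t, h1);

  double mi = 0.0;
  for (int a = 0; a < ngrid; ++a) {
    const double p = p0 * f0(a) + p1 * f1(a);
    if (p <= 0.0) continue;
    if (f0(a) > 0.0) mi += p0 * f0(a) * std::log(f0(a) / p);
    if (f1(a) > 0.0) mi += p1 * f1(a) * std::log(f1(a) / p);
  }
  mi *= dt / std::log(log_base);
  return mi > 0.0 ? mi : 0.0;
}

// [[Rcpp::export]]
double cpp_parzen_mi(const arma::vec &g, const arma::ivec &y,
                     double h0, double h1, int ngrid, double log_base) {
  arma::vec x0 = g.elem(arma::find(y == 0));
  arma::vec x1 = g.elem(arma::find(y == 1));
  if (h0 <= 0.0) h0 = silverman_bw(x0);
  if (h1 <= 0.0) h1 = silverman_bw(x1);
  if (h0 <= 0.0 || h1 <= 0.0) {
    // constant within a class: fall back to the pooled-sample bandwidth
    double hp = silverman_bw(g);
    if (hp <= 0.0) return NA_REAL;  // feature constant overall
    if (h0 <= 0.0) h0 = hp;
    if (h1 <= 0.0) h1 = hp;
  }
  return mi_1d_core(x0, x1, h0, h1, ngrid, log_base);
}

// Column-wise MI between each feature of X (samples x features) and the
// binary class y. NA for features that are constant overall.
// [[Rcpp::export]]
arma::vec cpp_parzen_mi_batch(const arma::mat &X, const arma::ivec &y,
                              int ngrid, double log_base) {
  const arma::uvec i0 = arma::find(y == 0), i1 = arma::find(y == 1);
  arma::vec out(X.n_cols);
  for (arma::uword j = 0; j < X.n_cols; ++j) {
    arma::vec x0 = X.submat(i0, arma::uvec{j});
    arma::vec x1 = X.submat(i1, arma::uvec{j});
    double h0 = silverman_bw(x0), h1 = silverman_bw(x1);
    if (h0 <= 0.0 || h1 <= 0.0) {
      double hp = silverman_bw(X.col(j));
      if (hp <= 0.0) { out(j) = NA_REAL; continue; }
      if (h0 <= 0.0) h0 = hp;
      if (h1 <= 0.0) h1 = hp;
    }
    out(j) = mi_1d_core(x0, x1, h0, h1, ngrid, log_base);
  }
  return out;
}

// MI between two continuous variables via a product-kernel 2-D Parzen
// density; marginals are obtained by integrating the joint on the same grid
// so that the estimate is internally consistent (and nonnegative up to
// quadrature error).
// [[Rcpp::export]]
double cpp_parzen_mi_pair(const arma::vec &x, const arma::vec &y,
                          int ngrid, double log_base) {
  const arma::uword n = x.n_elem;
  double hx = silverman_bw(x), hy = silverman_bw(y);
  if (hx <= 0.0 || hy <= 0.0) return NA_REAL;
  arma::vec tx = arma::linspace(x.min() - 3.0 * hx, x.max() + 3.0 * hx, ngrid);
  arma::vec ty = arma::linspace(y.min() - 3.0 * hy, y.max() + 3.0 * hy, ngrid);
  const double dx = tx(1) - tx(0), dy = ty(1) - ty(0);

  // Kx(a, i) = K_hx(tx_a - x_i), joint = Kx Ky^T / n
  arma::mat Kx(ngrid, n), Ky(ngrid, n);
  const double cx = INV_SQRT_2PI / hx, cy = INV_SQRT_2PI / hy;
  for (arma::uword i = 0; i < n; ++i) {
    for (int a = 0; a < ngrid; ++a) {
      double ux = (tx(a) - x(i)) / hx;
      double uy = (ty(a) - y(i)) / hy;
      Kx(a, i) = cx * std::exp(-0.5 * ux * ux);
      Ky(a, i) = cy * std::exp(-0.5 * uy * uy);
    }
  }
  arma::mat joint = (Kx * Ky.t()) / static_cast<double>(n);
  arma::vec px = arma::sum(joint, 1) * dy;
  arma::vec py = arma::sum(joint, 0).t() * dx;

  double mi = 0.0;
  for (int a = 0; a < ngrid; ++a) {
    for (int b = 0; b < ngrid; ++b) {
      const double pj = joint(a, b), pm = px(a) * py(b);
      if (pj > 0.0 && pm > 0.0) mi += pj * std::log(pj / pm);
    }
  }
  mi *= dx * dy / std::log(log_base);
  return mi > 0.0 ? mi : 0.0;
}
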