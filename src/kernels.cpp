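// Small per-sample kernels for the closed-loop simulator: Hudgins
// time-domain features over all channels of one window, and a
// single-sample forward pass through the calibrated network. Both mirror
// their R counterparts (td_features, mrl_forward) exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

// [[Rcpp::export(name = ".td_features_all_cpp")]]
NumericVector td_features_all_cpp(const arma::mat &X, double zc_thr,
                                  double ssc_thr) {
  const int I = X.n_rows, n = X.n_cols;
  NumericVector out(4 * I);
  for (int i = 0; i < I; ++i) {
    double mav = 0, wl = 0;
    int zc = 0, ssc = 0;
    for (int k = 0; k < n; ++k) mav += std::abs(X(i, k));
    mav /= n;
    for (int k = 0; k + 1 < n; ++k) {
      double d = X(i, k + 1) - X(i, k);
      wl += std::abs(d);
      if (X(i, k) * X(i, k + 1) < 0 && std::abs(d) >= zc_thr) ++zc;
    }
    for (int k = 1; k + 1 < n; ++k) {
      double a = X(i, k) - X(i, k - 1);
      double b = X(i, k) - X(i, k + 1);
      if (a * b > 0 && (std::abs(a) >= ssc_thr || std::abs(b) >= ssc_thr)) ++ssc;
    }
    out[4 * i] = mav;
    out[4 * i + 1] = zc;
    out[4 * i + 2] = ssc;
    out[4 * i + 3] = wl;
  }
  return out;
}

// [[Rcpp::export(name = ".mrl_forward_vec_cpp")]]
NumericVector mrl_forward_vec_cpp(List encoder, List decoder,
                                  const arma::vec &e, double slope,
                                  double eps) {
  auto block = [&](const mat &W, const vec &b, const vec &a) {
    vec z = W * a + b;
    for (arma::uword k = 0; k < z.n_elem; ++k)
      if (z(k) < 0) z(k) *= slope;
    double mu = arma::mean(z);
    vec c = z - mu;
    double r = 1.0 / std::sqrt(arma::mean(c % c) + eps);
    return vec(c * r);
  };
  vec a = e;
  for (int l = 0; l < encoder.size(); ++l) {
    List layer = encoder[l];
    a = block(as<mat>(layer["W"]), as<vec>(layer["b"]), a);
  }
  NumericVector out(decoder.size());
  for (int j = 0; j < decoder.size(); ++j) {
    List dj = decoder[j];
    List hidden = dj["hidden"];
    List outl = dj["out"];
    vec aj = block(as<mat>(hidden["W"]), as<vec>(hidden["b"]), a);
    out[j] = arma::dot(as<mat>(outl["W"]).row(0).t(), aj) + as<double>(outl["b"]);
  }
  return out;
}

// [[Rcpp::export(name = ".emg_draw_cpp")]]
NumericMatrix emg_draw_cpp(const arma::mat &gains, double baseline, double mvc,
                           double v_range, int bits, const arma::vec &intent,
                           int n) {
  const int I = gains.n_rows;
  arma::vec dirmag(4);
  dirmag(0) = std::max(-intent(0), 0.0);
  dirmag(1) = std::max(intent(0), 0.0);
  dirmag(2) = std::max(-intent(1), 0.0);
  dirmag(3) = std::max(intent(1), 0.0);
  arma::vec a = baseline + mvc * (gains * dirmag);
  const double delta = 2.0 * v_range / std::pow(2.0, bits);
  const double lo = -std::pow(2.0, bits - 1), hi = std::pow(2.0, bits - 1) - 1;
  NumericVector z = rnorm(I * n); // draws R's session RNG, column-major
  NumericMatrix out(I, n);
  for (int t = 0; t < n; ++t)
    for (int i = 0; i < I; ++i) {
      double q = std::nearbyint(a(i) * z[t * I + i] / delta);
      out(i, t) = std::min(std::max(q, lo), hi) * delta;
    }
  return out;
}

// Full LDA controller step: Hudgins features on the (circular) trailing
// window, z-scoring, linear discriminant argmax (ties to lowest class),
// proportionality scalar and velocity.
// [[Rcpp::export(name = ".lda_vel_cpp")]]
NumericVector lda_vel_cpp(const arma::mat &buf, int pos,
                          const arma::vec &sc_mean, const arma::vec &sc_sd,
                          const arma::mat &A, const arma::vec &c0,
                          const arma::mat &S, const arma::vec &C,
                          const arma::mat &dirs, double px_per_unit) {
  const int I = buf.n_rows, W = buf.n_cols;
  arma::vec f(4 * I);
  // chronological index: oldest sample sits at pos (1-based from R)
  auto at = [&](int i, int k) { return buf(i, (pos + k) % W); };
  for (int i = 0; i < I; ++i) {
    double mav = 0, wl = 0;
    int zc = 0, ssc = 0;
    for (int k = 0; k < W; ++k) mav += std::abs(at(i, k));
    mav /= W;
    for (int k = 0; k + 1 < W; ++k) {
      double x0 = at(i, k), x1 = at(i, k + 1);
      wl += std::abs(x1 - x0);
      if (x0 * x1 < 0) ++zc;
    }
    for (int k = 1; k + 1 < W; ++k) {
      double a = at(i, k) - at(i, k - 1), b = at(i, k) - at(i, k + 1);
      if (a * b > 0) ++ssc;
    }
    f(4 * i) = mav;
    f(4 * i + 1) = zc;
    f(4 * i + 2) = ssc;
    f(4 * i + 3) = wl;
  }
  arma::vec z = (f - sc_mean) / sc_sd;
  arma::vec scores = A.t() * z + c0;
  int m = 0;
  for (arma::uword j = 1; j < scores.n_elem; ++j)
    if (scores(j) > scores(m)) m = j;
  NumericVector v(2);
  if (m == 0) return v;
  double pc = 0;
  for (int i = 0; i < I; ++i) pc += S(i, m) * f(4 * i);
  pc /= C(m);
  pc *= pc;
  v[0] = dirs(0, m) * px_per_unit * pc;
  v[1] = dirs(1, m) * px_per_unit * pc;
  return v;
}

// cumulative sum with plain double accumulation (bit-compatible with the
// one-sample-at-a-time streaming filter, unlike base::cumsum's long double)
// [[Rcpp::export(name = ".cumsum_dbl_cpp")]]
NumericVector cumsum_dbl_cpp(const NumericVector &x) {
  NumericVector out(x.size());
  double acc = 0.0;
  for (int i = 0; i < x.size(); ++i) {
    acc += x[i];
    out[i] = acc;
  }
  return out;
}
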