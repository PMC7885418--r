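// Compiled training engine for the multitask envelope-decoding network.
//
// Mirrors the reference R implementation in R/autodiff.R exactly:
// batched forward pass, forward-mode tangent propagation (full input-output
// Jacobian per sample) and a hand-derived reverse pass giving analytic
// gradients of L = L_i + alpha_c * L_c for every weight and bias.
//
// Tangent layout: n x (B*I) matrices; column (i-1)*B + t holds the tangent
// of the activation at sample t w.r.t. input channel i (0-based internally).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;
using arma::uvec;

namespace {

struct BlockCache {
  mat Aprev, Dprev, S, C, DC;
  rowvec r, svec;
  int n;
};

struct BlockOut {
  mat A, D;
  BlockCache cache;
};

mat rep_cols(const mat &M, const uvec &colsT) { return M.cols(colsT); }

BlockOut block_forward(const mat &W, const vec &b, const mat &A, const mat &D,
                       bool tangent, double slope, double eps,
                       const uvec &colsT) {
  BlockOut out;
  const int n = W.n_rows;
  mat Z = W * A;
  Z.each_col() += b;
  mat S = arma::conv_to<mat>::from(Z > 0) * (1.0 - slope) + slope;
  mat U = Z % S;
  rowvec mu = arma::mean(U, 0);
  mat C = U;
  C.each_row() -= mu;
  rowvec r = 1.0 / arma::sqrt(arma::mean(C % C, 0) + eps);
  out.A = C;
  out.A.each_row() %= r;
  out.cache.Aprev = A;
  out.cache.S = S;
  out.cache.C = C;
  out.cache.r = r;
  out.cache.n = n;
  if (tangent) {
    out.cache.Dprev = D;
    mat DZ = W * D;
    mat DU = DZ % rep_cols(S, colsT);
    mat DC = DU;
    DC.each_row() -= arma::mean(DU, 0);
    mat Crep = rep_cols(C, colsT);
    rowvec svec = arma::sum(Crep % DC, 0);
    rowvec rt = arma::conv_to<rowvec>::from(r.elem(colsT));
    out.D = DC;
    out.D.each_row() %= rt;
    mat tmp = Crep;
    tmp.each_row() %= (arma::pow(rt, 3) % svec / n);
    out.D -= tmp;
    out.cache.DC = DC;
    out.cache.svec = svec;
  }
  return out;
}

struct BlockGrad {
  mat Wbar, Abar, Dbar;
  vec bbar;
};

BlockGrad block_backward(const mat &W, const BlockCache &cc, const mat &Abar_in,
                         const mat &Dbar_in, bool tangent, const uvec &colsT) {
  const int n = cc.n;
  const int B = cc.C.n_cols;
  mat Cbar(n, B, arma::fill::zeros);
  rowvec rbar(B, arma::fill::zeros);
  mat DZbar;
  mat DCbar;
  if (tangent) {
    const int It = colsT.n_elem / B;
    mat Crep = rep_cols(cc.C, colsT);
    rowvec rt = arma::conv_to<rowvec>::from(cc.r.elem(colsT));
    rowvec rt3 = arma::pow(rt, 3);
    rowvec q = arma::sum(Crep % Dbar_in, 0);
    rowvec sbar = -(rt3 / n) % q;
    DCbar = Dbar_in;
    DCbar.each_row() %= rt;
    mat tmp = Crep;
    tmp.each_row() %= sbar;
    DCbar += tmp;
    mat term = Dbar_in;
    term.each_row() %= (-rt3 % cc.svec / n);
    tmp = cc.DC;
    tmp.each_row() %= sbar;
    term += tmp;
    for (int i = 0; i < It; ++i) {
      Cbar += term.cols(i * B, (i + 1) * B - 1);
    }
    rowvec rbar_cols =
        arma::sum(Dbar_in % cc.DC, 0) - (3.0 * arma::pow(rt, 2) % cc.svec / n) % q;
    mat rmat = arma::reshape(rbar_cols.t(), B, It);
    rbar += arma::sum(rmat, 1).t();
    mat DUbar = DCbar;
    DUbar.each_row() -= arma::mean(DCbar, 0);
    DZbar = DUbar % rep_cols(cc.S, colsT);
  }
  Cbar += Abar_in.each_row() % cc.r;
  rbar += arma::sum(Abar_in % cc.C, 0);
  rowvec vbar = -0.5 * arma::pow(cc.r, 3) % rbar;
  mat tmp2 = cc.C;
  tmp2.each_row() %= (2.0 * vbar / n);
  Cbar += tmp2;
  mat Ubar = Cbar;
  Ubar.each_row() -= arma::mean(Cbar, 0);
  mat Zbar = Ubar % cc.S;
  BlockGrad g;
  g.Wbar = Zbar * cc.Aprev.t();
  if (tangent) g.Wbar += DZbar * cc.Dprev.t();
  g.bbar = arma::sum(Zbar, 1);
  g.Abar = W.t() * Zbar;
  if (tangent) g.Dbar = W.t() * DZbar;
  return g;
}

} // namespace

// [[Rcpp::export(name = ".mrl_engine_cpp")]]
List mrl_engine_cpp(List encoder, List decoder, const arma::mat &E,
                    Nullable<NumericMatrix> Y_, double alpha_c, double slope,
                    double eps, bool need_grad, bool need_tangent) {
  const int I = E.n_rows;
  const int B = E.n_cols;
  const int nEnc = encoder.size();
  const int J = decoder.size();

  uvec colsT;
  mat D;
  if (need_tangent) {
    colsT.set_size(B * I);
    for (int i = 0; i < I; ++i)
      for (int t = 0; t < B; ++t) colsT(i * B + t) = t;
    D.zeros(I, B * I);
    for (int i = 0; i < I; ++i)
      D.submat(i, i * B, i, (i + 1) * B - 1).fill(1.0);
  }

  std::vector<BlockCache> encCache(nEnc);
  std::vector<mat> encW(nEnc);
  mat A = E;
  for (int l = 0; l < nEnc; ++l) {
    List layer = encoder[l];
    mat W = as<mat>(layer["W"]);
    vec b = as<vec>(layer["b"]);
    BlockOut st = block_forward(W, b, A, D, need_tangent, slope, eps, colsT);
    A = st.A;
    if (need_tangent) D = st.D;
    encCache[l] = std::move(st.cache);
    encW[l] = std::move(W);
  }
  mat h = A, Dh = D;

  mat Yhat(J, B, arma::fill::zeros);
  mat jrows;
  if (need_tangent) jrows.zeros(J, B * I);
  std::vector<BlockCache> brCache(J);
  std::vector<mat> brA(J), brD(J), brW(J), outW(J);
  for (int j = 0; j < J; ++j) {
    List dj = decoder[j];
    List hidden = dj["hidden"];
    List outl = dj["out"];
    mat Wh = as<mat>(hidden["W"]);
    vec bh = as<vec>(hidden["b"]);
    mat Wo = as<mat>(outl["W"]);
    double bo = as<double>(outl["b"]);
    BlockOut st = block_forward(Wh, bh, h, Dh, need_tangent, slope, eps, colsT);
    Yhat.row(j) = Wo * st.A + bo;
    if (need_tangent) jrows.row(j) = Wo * st.D;
    brCache[j] = std::move(st.cache);
    brA[j] = std::move(st.A);
    if (need_tangent) brD[j] = std::move(st.D);
    brW[j] = std::move(Wh);
    outW[j] = std::move(Wo);
  }

  bool haveY = Y_.isNotNull();
  mat Y;
  double L_i = NA_REAL, L_c = NA_REAL;
  if (haveY) {
    Y = as<mat>(Y_.get());
    L_i = arma::accu(arma::abs(Y - Yhat)) / B;
  }
  if (need_tangent) L_c = arma::accu(jrows % jrows) / (double(B) * I * J);

  List res = List::create(
      Named("L_i") = L_i, Named("L_c") = L_c,
      Named("L") = haveY ? (need_tangent ? L_i + alpha_c * L_c : L_i)
                         : alpha_c * L_c,
      Named("Yhat") = Yhat, Named("code") = h);
  if (need_tangent) res["jrows"] = jrows;
  if (!need_grad) return res;

  mat Ybar(J, B, arma::fill::zeros);
  if (haveY) Ybar = arma::sign(Yhat - Y) / B;
  mat Jbar;
  if (need_tangent) Jbar = (2.0 * alpha_c / (double(B) * I * J)) * jrows;

  List gEnc(nEnc), gDec(J);
  mat hbar(h.n_rows, B, arma::fill::zeros);
  mat Dhbar;
  if (need_tangent) Dhbar.zeros(h.n_rows, B * I);
  for (int j = 0; j < J; ++j) {
    rowvec ybj = Ybar.row(j);
    mat outWbar = ybj * brA[j].t();
    mat Abar = outW[j].t() * ybj;
    mat Dbar;
    if (need_tangent) {
      rowvec jbj = Jbar.row(j);
      outWbar += jbj * brD[j].t();
      Dbar = outW[j].t() * jbj;
    }
    BlockGrad g = block_backward(brW[j], brCache[j], Abar, Dbar, need_tangent,
                                 colsT);
    gDec[j] = List::create(
        Named("hidden") = List::create(Named("W") = g.Wbar, Named("b") = g.bbar),
        Named("out") = List::create(Named("W") = outWbar,
                                    Named("b") = arma::accu(ybj)));
    hbar += g.Abar;
    if (need_tangent) Dhbar += g.Dbar;
  }
  mat Abar = hbar, Dbar = Dhbar;
  for (int l = nEnc - 1; l >= 0; --l) {
    BlockGrad g =
        block_backward(encW[l], encCache[l], Abar, Dbar, need_tangent, colsT);
    gEnc[l] = List::create(Named("W") = g.Wbar, Named("b") = g.bbar);
    Abar = g.Abar;
    if (need_tangent) Dbar = g.Dbar;
  }
  res["grads"] = List::create(Named("encoder") = gEnc, Named("decoder") = gDec);
  return res;
}
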