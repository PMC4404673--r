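// Fast evaluation of the moment map sigma(theta) for the stage-2
// minimum-distance loops.  The model's slot layout (fixed values plus
// free-parameter indices) is packed once into an external pointer; each
// call then only fills matrices and performs small dense algebra.
// Ordering matches momentMap(): mean block (per trait: intercept,
// slopes), variance block (per trait, components within), covariance
// block (per pair in row-wise order, components within).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Slot {
  arma::mat v;
  arma::uvec at;    // 0-based linear indices of free entries
  arma::uvec par;   // 0-based theta indices
};

struct SigmaCtx {
  int t, q, L, C;
  Slot Lam, B, Ge, Gy, nu, alpha;
  std::vector<Slot> Psi, Th;
  arma::uvec ut;    // 0-based upper-triangle indices, row-wise pair order
};

static Slot asSlot(const List& x) {
  Slot s;
  s.v = as<arma::mat>(x["v"]);
  s.at = as<arma::uvec>(x["at"]);
  s.par = as<arma::uvec>(x["par"]);
  return s;
}

static inline void fillSlot(arma::mat& out, const Slot& s,
                            const arma::vec& theta) {
  out = s.v;
  for (arma::uword i = 0; i < s.at.n_elem; ++i)
    out(s.at(i)) = theta(s.par(i));
}

// [[Rcpp::export(name = ".cpp_sigma_pack")]]
SEXP cpp_sigma_pack(const List& ctx) {
  XPtr<SigmaCtx> p(new SigmaCtx(), true);
  p->t = as<int>(ctx["t"]); p->q = as<int>(ctx["q"]);
  p->L = as<int>(ctx["L"]); p->C = as<int>(ctx["C"]);
  p->Lam = asSlot(ctx["Lam"]); p->B = asSlot(ctx["B"]);
  p->Ge = asSlot(ctx["Ge"]); p->Gy = asSlot(ctx["Gy"]);
  p->nu = asSlot(ctx["nu"]); p->alpha = asSlot(ctx["alpha"]);
  List psi = ctx["Psi"], th = ctx["Theta"];
  for (int c = 0; c < p->C; ++c) {
    p->Psi.push_back(asSlot(psi[c]));
    p->Th.push_back(asSlot(th[c]));
  }
  p->ut = as<arma::uvec>(ctx["ut"]);
  return p;
}

// [[Rcpp::export(name = ".cpp_sigma")]]
arma::vec cpp_sigma(SEXP ctxPtr, const arma::vec& theta) {
  XPtr<SigmaCtx> p(ctxPtr);
  const int t = p->t, q = p->q, L = p->L, C = p->C;
  const int npair = t * (t - 1) / 2;
  arma::vec out(t * (1 + q) + t * C + npair * C);

  arma::mat Lam, Bm, Ge, Gy, num, alm;
  fillSlot(num, p->nu, theta);
  fillSlot(Gy, p->Gy, theta);
  arma::vec mu0 = num.col(0);
  arma::mat slopes = Gy;
  arma::mat A;
  if (L) {
    fillSlot(Lam, p->Lam, theta);
    fillSlot(Bm, p->B, theta);
    arma::mat IB = arma::eye(L, L) - Bm;
    arma::mat H;
    if (!arma::inv(H, IB)) stop("(I - B) is singular");
    A = Lam * H;
    fillSlot(alm, p->alpha, theta);
    mu0 += A * alm.col(0);
    if (q) {
      fillSlot(Ge, p->Ge, theta);
      slopes += A * Ge;
    }
  }
  int pos = 0;
  for (int i = 0; i < t; ++i) {
    out(pos++) = mu0(i);
    for (int j = 0; j < q; ++j) out(pos++) = slopes(i, j);
  }
  arma::mat V, P_;
  std::vector<arma::mat> Vs(C);
  for (int c = 0; c < C; ++c) {
    fillSlot(V, p->Th[c], theta);
    if (L) {
      fillSlot(P_, p->Psi[c], theta);
      V += A * P_ * A.t();
    }
    Vs[c] = V;
  }
  for (int i = 0; i < t; ++i)
    for (int c = 0; c < C; ++c) out(pos++) = Vs[c](i, i);
  for (int k = 0; k < npair; ++k)
    for (int c = 0; c < C; ++c) out(pos++) = Vs[c](p->ut(k));
  return out;
}
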