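// Multivariate-normal variance-component likelihood over pedigrees.
//
// Each pedigree contributes y ~ MVN(X beta, Sigma) with
//   Sigma = sum_c kron(R_c, V_c)
// restricted to the observed (non-missing) entries, in individual-major
// stacking (t trait slots per individual).  Optional single-ascertainment
// conditioning subtracts the marginal log density of the proband's
// observed entries.  Scores with respect to beta and the lower-triangle
// elements of every V_c are analytic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093453;
static const double BADLL = -1e10;

struct PedDat {
  arma::vec y;
  arma::mat X;
  std::vector<arma::mat> R;
  arma::uvec idx;   // 0-based rows of the full n*t stacking kept
  arma::uvec pidx;  // 0-based positions (within idx) of proband entries
};

static void unpack(const List& peds, std::vector<PedDat>& out) {
  int N = peds.size();
  out.resize(N);
  for (int k = 0; k < N; ++k) {
    List pk = peds[k];
    out[k].y = as<arma::vec>(pk["y"]);
    out[k].X = as<arma::mat>(pk["X"]);
    List Rl = pk["R"];
    out[k].R.clear();
    for (int c = 0; c < Rl.size(); ++c)
      out[k].R.push_back(as<arma::mat>(Rl[c]));
    out[k].idx = as<arma::uvec>(pk["idx"]) - 1;
    out[k].pidx = as<arma::uvec>(pk["pidx"]) - 1;
  }
}

typedef std::vector<PedDat> PedVec;

// pack once per fit; later calls reuse the external pointer
// [[Rcpp::export(name = ".cpp_pack")]]
SEXP cpp_pack(const List& peds) {
  XPtr<PedVec> p(new PedVec(), true);
  unpack(peds, *p);
  return p;
}

// Sigma restricted to observed entries for one pedigree
static bool buildSigma(const PedDat& pd, const arma::cube& V, arma::mat& S) {
  const int C = V.n_slices;
  const int t = V.n_rows;
  const int nt = pd.R[0].n_rows * t;
  arma::mat full(nt, nt, arma::fill::zeros);
  if (t == 1) {
    for (int c = 0; c < C; ++c) full += V(0, 0, c) * pd.R[c];
  } else {
    for (int c = 0; c < C; ++c) full += arma::kron(pd.R[c], V.slice(c));
  }
  if ((int)pd.idx.n_elem == nt) S = std::move(full);
  else S = full.submat(pd.idx, pd.idx);
  return S.is_finite();
}

static double mvnLogLik(const arma::vec& r, const arma::mat& S) {
  arma::mat L;
  if (!arma::chol(L, S, "lower")) return BADLL;
  arma::vec z = arma::solve(arma::trimatl(L), r);
  double ldet = 2.0 * arma::sum(arma::log(L.diag()));
  return -0.5 * (r.n_elem * LOG2PI + ldet + arma::dot(z, z));
}

// [[Rcpp::export(name = ".cpp_vc_loglik")]]
NumericVector cpp_vc_loglik(const arma::vec& beta, const arma::cube& V,
                            SEXP pedsPtr, bool ascertained,
                            bool perPedigree) {
  XPtr<PedVec> ptr(pedsPtr);
  PedVec& dat = *ptr;
  int N = dat.size();
  NumericVector out(perPedigree ? N : 1);
  double tot = 0.0;
  for (int k = 0; k < N; ++k) {
    arma::mat S;
    double ll;
    if (!buildSigma(dat[k], V, S)) ll = BADLL;
    else {
      arma::vec r = dat[k].y - dat[k].X * beta;
      ll = mvnLogLik(r, S);
      if (ll > BADLL && ascertained && dat[k].pidx.n_elem > 0) {
        arma::mat Sp = S.submat(dat[k].pidx, dat[k].pidx);
        double lp = mvnLogLik(r.elem(dat[k].pidx), Sp);
        ll = (lp <= BADLL) ? BADLL : ll - lp;
      }
    }
    if (perPedigree) out[k] = ll; else tot += ll;
    if (!perPedigree && ll <= BADLL) { out[0] = BADLL; return out; }
  }
  if (!perPedigree) out[0] = tot;
  return out;
}

// scores: one row per pedigree, columns = (beta, vech(V_c) for each c)
// vech order: column-major lower triangle (1,1),(2,1),...,(t,t)
// crossOnly: fill only the off-diagonal (2,1) slots (the free
// parameters of a bivariate cross-covariance fit); other variance
// columns stay zero
// [[Rcpp::export(name = ".cpp_vc_scores")]]
arma::mat cpp_vc_scores(const arma::vec& beta, const arma::cube& V,
                        SEXP pedsPtr, bool ascertained,
                        bool crossOnly = false) {
  XPtr<PedVec> ptr(pedsPtr);
  PedVec& dat = *ptr;
  const int N = dat.size();
  const int t = V.n_rows, C = V.n_slices;
  const int nvech = t * (t + 1) / 2;
  const int P = beta.n_elem + C * nvech;
  arma::mat out(N, P, arma::fill::zeros);

  for (int k = 0; k < N; ++k) {
    const PedDat& pd = dat[k];
    arma::mat S;
    if (!buildSigma(pd, V, S)) stop("non-finite covariance in score evaluation");
    arma::mat Sinv;
    if (!arma::inv_sympd(Sinv, S))
      stop("covariance not positive definite in score evaluation");
    arma::vec r = pd.y - pd.X * beta;
    arma::vec u = Sinv * r;

    bool cond = ascertained && pd.pidx.n_elem > 0;
    arma::mat Spinv;
    arma::vec up;
    if (cond) {
      arma::mat Sp = S.submat(pd.pidx, pd.pidx);
      if (!arma::inv_sympd(Spinv, Sp))
        stop("proband covariance not positive definite");
      up = Spinv * r.elem(pd.pidx);
    }

    // beta block
    arma::vec gb = pd.X.t() * u;
    if (cond) gb -= pd.X.rows(pd.pidx).t() * up;
    for (arma::uword j = 0; j < beta.n_elem; ++j) out(k, j) = gb(j);

    // variance blocks; K is symmetric, so trace(Sinv K) reduces to an
    // elementwise product sum (O(m^2) instead of O(m^3))
    const int nt = pd.R[0].n_rows * t;
    const bool full = ((int)pd.idx.n_elem == nt);
    int col = beta.n_elem;
    for (int c = 0; c < C; ++c) {
      for (int b = 0; b < t; ++b) {
        for (int a = b; a < t; ++a) {
          if (crossOnly && !(a != b)) { ++col; continue; }
          arma::mat K;
          if (t == 1) {
            K = full ? pd.R[c] : pd.R[c].submat(pd.idx, pd.idx);
          } else {
            arma::mat E(t, t, arma::fill::zeros);
            E(a, b) = 1.0; E(b, a) = 1.0;   // symmetric perturbation
            arma::mat Kfull = arma::kron(pd.R[c], E);
            K = full ? std::move(Kfull) : Kfull.submat(pd.idx, pd.idx);
          }
          double g = 0.5 * (arma::dot(u, K * u) - arma::accu(Sinv % K));
          if (cond) {
            arma::mat Kp = K.submat(pd.pidx, pd.pidx);
            g -= 0.5 * (arma::dot(up, Kp * up) - arma::accu(Spinv % Kp));
          }
          out(k, col++) = g;
        }
      }
    }
  }
  return out;
}
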