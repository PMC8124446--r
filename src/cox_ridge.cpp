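// Ridge-penalized Cox partial likelihood (Breslow ties): Newton solver,
// cross-validated likelihood grid, and the leave-one-out outer loop of the
// list-level screen. Rows must be sorted by increasing time; risk sets are
// then suffixes and one backward scan yields loglik, gradient and observed
// information in O(n p^2) (O(n p) without the information). Features are
// accessed through the transposed matrix (p x n) so each subject's profile
// is contiguous.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// backward scan over time-sorted data; eta = X * beta precomputed by the
// caller. level: 0 = loglik only (Xt unused), 1 = +gradient, 2 =
// +information. grad/info must be pre-sized.
double breslow_scan(const arma::mat& Xt, const arma::vec& time,
                    const arma::vec& status, const arma::vec& eta,
                    int level, arma::vec* grad, arma::mat* info) {
  const arma::sword n = eta.n_elem;
  const arma::uword p = level >= 1 ? Xt.n_rows : 0;
  double m = eta.max();
  arma::vec wv = arma::exp(eta - m);

  double s0 = 0.0, ll = 0.0;
  arma::vec s1(p, arma::fill::zeros);
  arma::mat s2;
  if (level >= 1) grad->zeros();
  if (level >= 2) { s2.zeros(p, p); info->zeros(); }
  double* s1p = s1.memptr();

  arma::sword i = n - 1;
  while (i >= 0) {
    arma::sword j = i;
    while (j >= 0 && time(j) == time(i)) {
      double w = wv(j);
      s0 += w;
      if (level >= 1) {
        const double* x = Xt.colptr(j);
        for (arma::uword q = 0; q < p; ++q) s1p[q] += w * x[q];
        if (level >= 2) {
          double* s2p = s2.memptr();
          for (arma::uword c = 0; c < p; ++c) {
            double wx = w * x[c];
            double* col = s2p + c * p;
            for (arma::uword r = 0; r <= c; ++r) col[r] += wx * x[r];
          }
        }
      }
      --j;
    }
    for (arma::sword k = i; k > j; --k) {
      if (status(k) > 0.5) {
        ll += (eta(k) - m) - std::log(s0);
        if (level >= 1) {
          const double* x = Xt.colptr(k);
          double* gp = grad->memptr();
          for (arma::uword q = 0; q < p; ++q) gp[q] += x[q] - s1p[q] / s0;
          if (level >= 2) {
            double* ip = info->memptr();
            const double* s2p = s2.memptr();
            for (arma::uword c = 0; c < p; ++c) {
              double sc = s1p[c] / s0;
              double* icol = ip + c * p;
              const double* scol = s2p + c * p;
              for (arma::uword r = 0; r <= c; ++r) {
                icol[r] += scol[r] / s0 - s1p[r] / s0 * sc;
              }
            }
          }
        }
      }
    }
    i = j;
  }
  if (level >= 2) *info = arma::symmatu(*info);
  return ll;
}

struct FitResult {
  arma::vec beta;
  double ll;
  double pll;
  int iter;
  bool converged;
};

// full Newton with step halving on the penalized objective
FitResult newton_fit(const arma::mat& Xt, const arma::vec& time,
                     const arma::vec& status, double lambda,
                     arma::vec beta, int maxit, double tol) {
  const arma::uword p = Xt.n_rows;
  arma::vec grad(p);
  arma::mat info(p, p);
  arma::vec eta = Xt.t() * beta;
  double ll = breslow_scan(Xt, time, status, eta, 2, &grad, &info);
  double pll = ll - 0.5 * lambda * arma::dot(beta, beta);
  FitResult out{beta, ll, pll, 0, false};
  for (int it = 0; it < maxit; ++it) {
    arma::vec g = grad - lambda * beta;
    arma::mat H = info;
    H.diag() += lambda;
    arma::vec step;
    if (!arma::solve(step, H, g, arma::solve_opts::likely_sympd)) {
      H.diag() += 1e-8 + 1e-8 * arma::trace(H) / p;
      if (!arma::solve(step, H, g)) stop("singular information matrix");
    }
    double alpha = 1.0, ll_new = 0.0, pll_new = -arma::datum::inf;
    arma::vec beta_new, eta_new;
    arma::vec eta_step = Xt.t() * step;
    for (int h = 0; h < 30; ++h) {
      beta_new = beta + alpha * step;
      eta_new = eta + alpha * eta_step;
      ll_new = breslow_scan(Xt, time, status, eta_new, 0, nullptr, nullptr);
      pll_new = ll_new - 0.5 * lambda * arma::dot(beta_new, beta_new);
      if (std::isfinite(pll_new) && pll_new >= pll - 1e-12) break;
      alpha *= 0.5;
    }
    double delta = pll_new - pll;
    beta = beta_new;
    eta = eta_new;
    pll = pll_new;
    ll = breslow_scan(Xt, time, status, eta, 2, &grad, &info);
    out.iter = it + 1;
    if (std::abs(delta) < tol &&
        arma::norm(grad - lambda * beta, "inf") < 1e-6) {
      out.converged = true;
      break;
    }
  }
  out.beta = beta;
  out.ll = ll;
  out.pll = pll;
  return out;
}

// scoring iterations with frozen curvature (Cholesky of info0 + lambda I);
// cheap gradient-only scans, full-Newton fallback when it stalls
FitResult frozen_fit(const arma::mat& Xt, const arma::vec& time,
                     const arma::vec& status, double lambda,
                     const arma::mat& info0, arma::vec beta, int maxit,
                     double tol) {
  const arma::uword p = Xt.n_rows;
  arma::mat H = info0;
  H.diag() += lambda;
  arma::mat L;
  if (!arma::chol(L, H, "lower")) {
    return newton_fit(Xt, time, status, lambda, beta, maxit, tol);
  }
  arma::vec grad(p), grad_new(p);
  arma::vec eta = Xt.t() * beta;
  double ll = breslow_scan(Xt, time, status, eta, 1, &grad, nullptr);
  double pll = ll - 0.5 * lambda * arma::dot(beta, beta);
  for (int it = 0; it < 25; ++it) {
    arma::vec g = grad - lambda * beta;
    arma::vec step = arma::solve(arma::trimatl(L), g);
    step = arma::solve(arma::trimatu(L.t()), step);
    arma::vec eta_step = Xt.t() * step;
    // optimistic full step: one level-1 scan gives both the acceptance
    // check and the next iteration's gradient
    arma::vec beta_new = beta + step;
    arma::vec eta_new = eta + eta_step;
    double ll_new = breslow_scan(Xt, time, status, eta_new, 1, &grad_new,
                                 nullptr);
    double pll_new = ll_new - 0.5 * lambda * arma::dot(beta_new, beta_new);
    if (!(std::isfinite(pll_new) && pll_new >= pll - 1e-12)) {
      double alpha = 0.5;
      for (int h = 0; h < 20; ++h) {
        beta_new = beta + alpha * step;
        eta_new = eta + alpha * eta_step;
        ll_new = breslow_scan(Xt, time, status, eta_new, 0, nullptr,
                              nullptr);
        pll_new = ll_new - 0.5 * lambda * arma::dot(beta_new, beta_new);
        if (std::isfinite(pll_new) && pll_new >= pll - 1e-12) break;
        alpha *= 0.5;
      }
      breslow_scan(Xt, time, status, eta_new, 1, &grad_new, nullptr);
    }
    double delta = pll_new - pll;
    beta = beta_new;
    eta = eta_new;
    pll = pll_new;
    ll = ll_new;
    grad = grad_new;
    if (std::abs(delta) < tol) {
      return FitResult{beta, ll, pll, it + 1, true};
    }
  }
  return newton_fit(Xt, time, status, lambda, beta, maxit, tol);
}

double ll_at(const arma::mat& Xt, const arma::vec& time,
             const arma::vec& status, const arma::vec& beta) {
  arma::vec eta = Xt.t() * beta;
  return breslow_scan(Xt, time, status, eta, 0, nullptr, nullptr);
}

} // namespace

// Breslow partial log likelihood at beta (rows sorted by time ascending).
// [[Rcpp::export]]
double cpp_cox_loglik(const arma::mat& X, const arma::vec& time,
                      const arma::vec& status, const arma::vec& beta) {
  arma::vec eta = X * beta;
  arma::mat Xt; // unused at level 0
  return breslow_scan(Xt, time, status, eta, 0, nullptr, nullptr);
}

// Newton maximization of loglik(beta) - lambda/2 * ||beta||^2.
// [[Rcpp::export]]
List cpp_cox_ridge_newton(const arma::mat& X, const arma::vec& time,
                          const arma::vec& status, double lambda,
                          const arma::vec& beta_init, int maxit = 50,
                          double tol = 1e-9) {
  arma::mat Xt = X.t();
  FitResult fr = newton_fit(Xt, time, status, lambda, beta_init, maxit, tol);
  return List::create(_["beta"] = fr.beta, _["loglik"] = fr.ll,
                      _["penalized_loglik"] = fr.pll, _["iter"] = fr.iter,
                      _["converged"] = fr.converged);
}

// Cross-validated partial likelihood (Verweij-van Houwelingen) over a lambda
// grid: cvl(lambda) = sum_k [ ll_full(beta_{-k}) - ll_train_{-k}(beta_{-k}) ].
// foldid is 1-based; lambdas must be sorted decreasing (warm starts walk the
// path with curvature frozen per fold).
// [[Rcpp::export]]
arma::vec cpp_cox_cvl_grid(const arma::mat& X, const arma::vec& time,
                           const arma::vec& status, const arma::ivec& foldid,
                           const arma::vec& lambdas, int maxit = 50,
                           double tol = 1e-7) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const arma::uword nl = lambdas.n_elem;
  int K = foldid.max();
  arma::vec cvl(nl, arma::fill::zeros);
  arma::mat Xt_all = X.t();
  arma::vec grad(p);
  arma::mat info0(p, p);
  for (int k = 1; k <= K; ++k) {
    arma::uvec tr = arma::find(foldid != k);
    if (tr.n_elem == n || tr.n_elem == 0) continue;
    arma::mat Xt = Xt_all.cols(tr);
    arma::vec ttr = time.elem(tr), str = status.elem(tr);
    arma::vec beta(p, arma::fill::zeros);
    arma::vec eta0(tr.n_elem, arma::fill::zeros);
    breslow_scan(Xt, ttr, str, eta0, 2, &grad, &info0);
    for (arma::uword l = 0; l < nl; ++l) {
      FitResult fr = frozen_fit(Xt, ttr, str, lambdas(l), info0, beta,
                                maxit, tol);
      beta = fr.beta;
      cvl(l) += ll_at(Xt_all, time, status, beta) - fr.ll;
    }
  }
  return cvl;
}

// Full leave-one-out outer loop for the list-level screen: for each left-out
// row, standardize the remaining rows, select lambda by K-fold
// cross-validated partial likelihood (folds fixed over the whole loop), fit
// at the selected lambda, and score the left-out row. Rows must be sorted by
// increasing time. Warm starts and frozen curvature are carried per
// (fold, lambda) across outer iterations.
// [[Rcpp::export]]
List cpp_stage1_loo(const arma::mat& X, const arma::vec& time,
                    const arma::vec& status, const arma::ivec& foldid,
                    const arma::vec& lambdas, int maxit = 50,
                    double tol = 1e-7) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const arma::uword nl = lambdas.n_elem;
  const int K = foldid.max();
  arma::vec risk(n, arma::fill::zeros);
  arma::vec lam_sel(n, arma::fill::zeros);
  arma::vec grad(p);

  arma::cube warm(p, nl, K, arma::fill::zeros);
  arma::mat warm_final(p, nl, arma::fill::zeros);

  // global (all-row) feature transpose; per outer iteration the training
  // block is standardized in place
  arma::mat Xt_all = X.t();

  for (arma::uword i = 0; i < n; ++i) {
    arma::uvec tr(n - 1);
    arma::uword c = 0;
    for (arma::uword r = 0; r < n; ++r) if (r != i) tr(c++) = r;
    arma::mat Xt_tr = Xt_all.cols(tr); // p x (n-1)
    arma::vec mu = arma::mean(Xt_tr, 1);
    arma::vec sd = arma::stddev(Xt_tr, 0, 1);
    sd.elem(arma::find(sd <= 0)).fill(1.0);
    Xt_tr.each_col() -= mu;
    Xt_tr.each_col() /= sd;
    arma::vec ttr = time.elem(tr), str = status.elem(tr);
    arma::ivec ftr = foldid.elem(tr);

    arma::vec cvl(nl, arma::fill::zeros);
    for (int k = 1; k <= K; ++k) {
      arma::uvec in2 = arma::find(ftr != k);
      if (in2.n_elem == tr.n_elem || in2.n_elem == 0) continue;
      arma::mat Xt2 = Xt_tr.cols(in2);
      arma::vec t2 = ttr.elem(in2), s2 = str.elem(in2);
      // curvature frozen per fold at the warm start of the smallest
      // penalty (largest coefficients), where curvature error matters most
      arma::vec bw = warm.slice(k - 1).col(nl - 1);
      arma::vec eta_w = Xt2.t() * bw;
      arma::mat info0(p, p);
      breslow_scan(Xt2, t2, s2, eta_w, 2, &grad, &info0);
      for (arma::uword l = 0; l < nl; ++l) {
        arma::vec beta = warm.slice(k - 1).col(l);
        FitResult fr = frozen_fit(Xt2, t2, s2, lambdas(l), info0, beta,
                                  maxit, tol);
        warm.slice(k - 1).col(l) = fr.beta;
        cvl(l) += ll_at(Xt_tr, ttr, str, fr.beta) - fr.ll;
      }
    }
    // ties on the criterion go to the largest penalty (grid is decreasing)
    arma::uword best = cvl.index_max();
    for (arma::uword l = 0; l < nl; ++l) {
      if (cvl(l) >= cvl(best) - 1e-12) { best = l; break; }
    }
    arma::vec eta_f = Xt_tr.t() * warm_final.col(best);
    arma::mat infoF(p, p);
    breslow_scan(Xt_tr, ttr, str, eta_f, 2, &grad, &infoF);
    FitResult fin = frozen_fit(Xt_tr, ttr, str, lambdas(best), infoF,
                               warm_final.col(best), maxit, tol);
    warm_final.col(best) = fin.beta;
    arma::vec zi = (X.row(i).t() - mu) / sd;
    risk(i) = arma::dot(zi, fin.beta);
    lam_sel(i) = lambdas(best);
  }
  return List::create(_["risk"] = risk, _["lambda"] = lam_sel);
}
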