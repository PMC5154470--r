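// Log-space forward-backward recursion for one subject. This is the inner
// loop of the variational E-step and dominates fit time, hence compiled.
//
// Each log-sum-exp is factored through a shared per-step max:
//   LSE_j(x_j + logA_jk) = m + log( sum_j exp(x_j - m) * expA_jk ),
// with m = max_j x_j, so the K x K inner loop is a plain matrix product
// against the precomputed exp(logA) while remaining exact log-space
// arithmetic (entries more than ~745 nats below the per-step max underflow
// to zero, exactly as in any log-sum-exp).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Expected Gaussian log-densities under each state's Normal-Wishart
// posterior. Y: T x M; means: M x K; rinv: M x (M*K), the horizontally
// stacked inverse Cholesky factors of the scale matrices; consts/dofs:
// per-state additive constants and Wishart dofs.
// [[Rcpp::export(name = ".emission_cpp")]]
arma::mat emission_cpp(const arma::mat &Y, const arma::mat &means,
                       const arma::mat &rinv, const arma::vec &consts,
                       const arma::vec &dofs) {
  const int T = Y.n_rows, M = Y.n_cols, K = means.n_cols;
  arma::mat out(T, K);
  for (int k = 0; k < K; ++k) {
    arma::mat D = Y;
    D.each_row() -= means.col(k).t();
    const arma::mat W = D * rinv.cols(k * M, (k + 1) * M - 1);
    out.col(k) = consts(k) - 0.5 * dofs(k) * arma::sum(W % W, 1);
  }
  return out;
}

// log_pi: K, log_A: K x K, lrho: T x K (expected emission log-densities).
// Returns gamma (T x K), the log normalizer, and either the full pairwise
// marginals xi ((T-1) x K x K, full_xi = true) or only their sum over time
// (K x K, full_xi = false; all the M-step needs).
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(const arma::vec &log_pi, const arma::mat &log_A,
            const arma::mat &lrho, const bool full_xi) {
  const int T = lrho.n_rows, K = lrho.n_cols;
  const arma::mat expA = arma::exp(log_A);      // K x K
  const arma::mat expAt = expA.t();

  arma::mat la(T, K), lb(T, K, arma::fill::zeros);
  la.row(0) = log_pi.t() + lrho.row(0);
  for (int t = 1; t < T; ++t) {
    const double m = la.row(t - 1).max();
    const arma::rowvec v = arma::exp(la.row(t - 1) - m);
    // la[t,k] = lrho[t,k] + m + log(sum_j v_j expA_jk)
    la.row(t) = lrho.row(t) + m + arma::log(v * expA);
  }
  for (int t = T - 2; t >= 0; --t) {
    const arma::rowvec u = lrho.row(t + 1) + lb.row(t + 1);
    const double m = u.max();
    const arma::rowvec w = arma::exp(u - m);
    // lb[t,j] = m + log(sum_k expA_jk w_k)
    lb.row(t) = m + arma::log(w * expAt);
  }
  const double mz = la.row(T - 1).max();
  const double logZ = mz + std::log(arma::accu(arma::exp(la.row(T - 1) - mz)));

  arma::mat gamma = arma::exp(la + lb - logZ);
  gamma.each_col() /= arma::sum(gamma, 1);

  arma::cube xi;
  arma::mat xi_sum(K, K, arma::fill::zeros);
  if (full_xi) xi.zeros(std::max(T - 1, 0), K, K);
  for (int t = 0; t + 1 < T; ++t) {
    const double ma = la.row(t).max();
    const arma::vec a = arma::exp(la.row(t).t() - ma);
    const arma::rowvec u = lrho.row(t + 1) + lb.row(t + 1);
    const double mb = u.max();
    const arma::rowvec b = arma::exp(u - mb);
    // xi_t proportional to diag(a) * expA * diag(b); normalize per t.
    arma::mat x = (a * b) % expA;
    x /= arma::accu(x);
    if (full_xi) xi.row(t) = x;
    xi_sum += x;
  }

  if (full_xi) {
    return List::create(_["gamma"] = gamma, _["xi"] = xi,
                        _["xi_sum"] = xi_sum, _["logZ"] = logZ);
  }
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                      _["logZ"] = logZ);
}
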