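// Compiled kernels for the three-block sampler.
//
// The marginal covariance of the latent vector is
//   Sigma = I_n + h 11' + c Q Q',
// where Q is an orthonormal basis of the span of the selected gene
// columns (X^g (X^g' X^g)^+ X^g' is the orthogonal projector onto that
// span).  With W = [sqrt(h) 1, sqrt(c) Q] and K = I + W'W,
//   log|Sigma| = log|K|,   z' Sigma^{-1} z = z'z - u' K^{-1} u,
// u = W'z.  Because Q'Q = I, K is an arrowhead matrix
//   K = [[1 + h n, b'], [b, (1+c) I_m]],  b = sqrt(h c) Q'1,
// so both quantities cost O(n m) to assemble and O(m) to solve.

#include <RcppArmadillo.h>
using namespace Rcpp;

// orthonormal basis of col(Xsel); singular values <= rtol * s_max dropped
static arma::mat orth_basis(const arma::mat& Xsel, double rtol) {
  arma::mat empty(Xsel.n_rows, 0);
  if (Xsel.n_cols == 0) return empty;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd_econ(U, s, V, Xsel)) Rcpp::stop("SVD failed in basis computation");
  if (s.n_elem == 0 || s(0) <= 0.0) return empty;
  arma::uvec keep = arma::find(s > rtol * s(0));
  return U.cols(keep);
}

// [[Rcpp::export]]
arma::mat cpp_orth_basis(const arma::mat& Xsel, double rtol) {
  return orth_basis(Xsel, rtol);
}

struct SigStats {
  double logdet;
  double quad;
};

static SigStats sigma_stats(const arma::mat& Q, double h, double c,
                            const arma::vec& z, double s1, double zz) {
  const int m = Q.n_cols;
  const int n = Q.n_rows;
  const double d = 1.0 + h * n;
  double aa = 0.0, t_az = 0.0, zq2 = 0.0;
  if (m > 0) {
    arma::vec a = arma::sum(Q, 0).t();   // Q' 1
    arma::vec zq = Q.t() * z;
    aa = arma::dot(a, a);
    t_az = arma::dot(a, zq);
    zq2 = arma::dot(zq, zq);
  }
  const double e = d - h * c * aa / (1.0 + c);
  const double u0 = std::sqrt(h) * s1;
  const double bu1 = std::sqrt(h) * c * t_az;   // b . u1
  const double x0 = (u0 - bu1 / (1.0 + c)) / e;
  const double uKu = u0 * x0 + (c * zq2 - x0 * bu1) / (1.0 + c);
  SigStats out;
  out.logdet = m * std::log1p(c) + std::log(e);
  out.quad = zz - uKu;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sigma_stats(const arma::mat& Q, double h, double c,
                              const arma::vec& z) {
  SigStats s = sigma_stats(Q, h, c, z, arma::accu(z), arma::dot(z, z));
  return NumericVector::create(_["logdet"] = s.logdet, _["quad"] = s.quad);
}

// standard normal truncated to (aa, Inf); inverse-CDF in the body,
// Robert (1995) exponential rejection deep in the tail
static double rtnorm_lower(double aa) {
  if (aa < 6.0) {
    double p = R::pnorm(aa, 0.0, 1.0, 0, 0);       // P(X > aa)
    double u = R::unif_rand();
    double x = R::qnorm(u * p, 0.0, 1.0, 0, 0);    // upper-tail quantile
    if (std::isfinite(x) && x >= aa) return x;
    return aa;   // only reachable through extreme rounding
  }
  double alpha = 0.5 * (aa + std::sqrt(aa * aa + 4.0));
  for (;;) {
    double x = aa + R::exp_rand() / alpha;
    double rho = std::exp(-0.5 * (x - alpha) * (x - alpha));
    if (R::unif_rand() <= rho) return x;
  }
}

// One full sweep of single-site truncated-normal updates for Z.
// Omega is the precision of N(0, Sigma); the conditional of Z_i given
// Z_{-i} is N(Z_i - (Omega Z)_i / Omega_ii, 1 / Omega_ii), truncated to
// (0, Inf) when y_i = 1 and (-Inf, 0] when y_i = 0.
// [[Rcpp::export]]
arma::vec cpp_update_Z(const arma::vec& z0, const arma::mat& Omega,
                       const arma::ivec& y) {
  const int n = z0.n_elem;
  arma::vec z = z0;
  arma::vec oz = Omega * z;
  for (int i = 0; i < n; ++i) {
    const double oii = Omega(i, i);
    if (!(oii > 0.0)) Rcpp::stop("non-positive conditional precision at index %d", i + 1);
    const double mu = z(i) - oz(i) / oii;
    const double sd = 1.0 / std::sqrt(oii);
    double znew;
    if (y(i) == 1) {
      znew = mu + sd * rtnorm_lower(-mu / sd);
    } else {
      znew = mu - sd * rtnorm_lower(mu / sd);
    }
    const double dz = znew - z(i);
    if (dz != 0.0) {
      oz += Omega.col(i) * dz;
      z(i) = znew;
    }
  }
  return z;
}

static arma::uvec to_uvec(const std::vector<arma::uword>& v) {
  arma::uvec out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out(i) = v[i];
  return out;
}

// One full systematic sweep over genes i = 1..p of the inclusion
// indicators.  sel0 holds the 0-based indices currently selected.
// logit_prior[i] = log((1 - pi_i) / pi_i).  Exactly one uniform is
// consumed per gene, in index order.
// [[Rcpp::export]]
List cpp_gamma_sweep(const arma::mat& X, const arma::vec& z,
                     const arma::uvec& sel0, double h, double c,
                     const arma::vec& logit_prior, double rtol) {
  const int p = X.n_cols;
  const double s1 = arma::accu(z);
  const double zz = arma::dot(z, z);
  std::vector<arma::uword> sel(sel0.begin(), sel0.end());
  std::sort(sel.begin(), sel.end());
  arma::mat Q = orth_basis(X.cols(to_uvec(sel)), rtol);
  SigStats cur = sigma_stats(Q, h, c, z, s1, zz);

  for (int i = 0; i < p; ++i) {
    const bool in = std::binary_search(sel.begin(), sel.end(), (arma::uword)i);
    arma::mat Qalt;
    if (!in) {
      // candidate addition: Gram-Schmidt of x_i against Q (twice, for
      // numerical orthogonality)
      arma::vec x = X.col(i);
      const double nx = arma::norm(x);
      arma::vec r = x;
      if (Q.n_cols > 0) {
        r -= Q * (Q.t() * x);
        r -= Q * (Q.t() * r);
      }
      const double nr = arma::norm(r);
      if (nx > 0.0 && nr > rtol * nx) {
        Qalt = arma::join_rows(Q, r / nr);
      } else {
        Qalt = Q;   // column already in the span (or zero): projector unchanged
      }
    } else {
      std::vector<arma::uword> s0;
      for (arma::uword j : sel) if (j != (arma::uword)i) s0.push_back(j);
      Qalt = orth_basis(X.cols(to_uvec(s0)), rtol);
    }
    SigStats alt = sigma_stats(Qalt, h, c, z, s1, zz);
    // rho compares gamma_i = 1 against gamma_i = 0
    const SigStats& one = in ? cur : alt;
    const SigStats& zero = in ? alt : cur;
    const double logrho = 0.5 * (one.logdet - zero.logdet)
                        + 0.5 * (one.quad - zero.quad);
    double lo = logit_prior(i) + logrho;
    double prob;
    if (!std::isfinite(lo)) {
      if (std::isnan(lo)) Rcpp::stop("non-finite inclusion log-odds for gene %d", i + 1);
      prob = (lo > 0.0) ? 0.0 : 1.0;
    } else {
      prob = 1.0 / (1.0 + std::exp(lo));
    }
    const double u = R::unif_rand();
    const bool newval = (u < prob);
    if (newval != in) {
      if (newval) {
        sel.insert(std::lower_bound(sel.begin(), sel.end(), (arma::uword)i),
                   (arma::uword)i);
      } else {
        sel.erase(std::find(sel.begin(), sel.end(), (arma::uword)i));
      }
      Q = Qalt;
      cur = alt;
    }
  }

  IntegerVector selR(sel.size());
  for (size_t k = 0; k < sel.size(); ++k) selR[k] = (int)sel[k] + 1;
  return List::create(_["sel"] = selR,
                      _["logdet"] = cur.logdet,
                      _["quad"] = cur.quad,
                      _["Q"] = Q);
}
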