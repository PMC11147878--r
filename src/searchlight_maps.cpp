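// Fast paths for the two searchlight statistics (leave-one-subject-out
// representational fidelity; partial Spearman RSA). Both reproduce the
// generic R engine exactly; tests assert the equality.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// average-rank transform (ties get the mean rank)
static arma::vec rank_avg(const arma::vec& x) {
  const arma::uword n = x.n_elem;
  arma::uvec ord = arma::sort_index(x);
  arma::vec r(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && x(ord(j + 1)) == x(ord(i))) ++j;
    double avg = 0.5 * (double(i) + double(j)) + 1.0;
    for (arma::uword k = i; k <= j; ++k) r(ord(k)) = avg;
    i = j + 1;
  }
  return r;
}

// lower-triangle (column-major) vector of the correlation-distance RDM of
// the rows of X, after dropping non-finite columns; returns false when
// degenerate (fewer than 2 usable voxels or a zero-variance row)
static bool rdm_vector(const arma::mat& X, arma::vec& out) {
  arma::uvec good(X.n_cols);
  arma::uword ng = 0;
  for (arma::uword c = 0; c < X.n_cols; ++c)
    if (X.col(c).is_finite()) good(ng++) = c;
  if (ng < 2) return false;
  arma::mat Xs = X.cols(good.head(ng));
  const arma::uword S = Xs.n_rows;
  // center and normalize rows
  arma::vec mu = arma::mean(Xs, 1);
  Xs.each_col() -= mu;
  arma::vec nrm = arma::sqrt(arma::sum(arma::square(Xs), 1));
  if (nrm.min() < 1e-12) return false;
  Xs.each_col() /= nrm;
  arma::mat R = Xs * Xs.t();
  arma::uword p = 0;
  for (arma::uword j = 0; j + 1 < S; ++j)
    for (arma::uword i = j + 1; i < S; ++i)
      out(p++) = 1.0 - R(i, j);
  return true;
}

static double pearson(const arma::vec& a, const arma::vec& b) {
  arma::vec ac = a - arma::mean(a);
  arma::vec bc = b - arma::mean(b);
  double na = arma::norm(ac), nb = arma::norm(bc);
  if (na < 1e-14 || nb < 1e-14) return NA_REAL;
  return arma::dot(ac, bc) / (na * nb);
}

// [[Rcpp::export]]
arma::mat cpp_fidelity_map(List betas, List nbrs, bool spearman) {
  const int nsub = betas.size();
  const int ncen = nbrs.size();
  std::vector<arma::mat> B(nsub);
  for (int s = 0; s < nsub; ++s) B[s] = as<arma::mat>(betas[s]);
  const arma::uword S = B[0].n_rows;
  const arma::uword P = S * (S - 1) / 2;
  arma::mat out(nsub, ncen);
  out.fill(NA_REAL);
  arma::mat V(nsub, P);
  arma::vec v(P);
  for (int c = 0; c < ncen; ++c) {
    IntegerVector mem = nbrs[c];
    if (mem.size() < 2) continue;
    arma::uvec cols(mem.size());
    for (int k = 0; k < mem.size(); ++k) cols(k) = mem[k] - 1;
    bool ok = true;
    for (int s = 0; s < nsub && ok; ++s) {
      if (!rdm_vector(B[s].cols(cols), v)) { ok = false; break; }
      V.row(s) = v.t();
    }
    if (!ok) continue;
    arma::rowvec total = arma::sum(V, 0);
    for (int s = 0; s < nsub; ++s) {
      arma::vec others = ((total - V.row(s)) / double(nsub - 1)).t();
      arma::vec self = V.row(s).t();
      if (spearman) { self = rank_avg(self); others = rank_avg(others); }
      out(s, c) = pearson(self, others);
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_rsa_map(List betas, List nbrs, const arma::vec& predResid,
                      const arma::mat& Q) {
  const int nsub = betas.size();
  const int ncen = nbrs.size();
  std::vector<arma::mat> B(nsub);
  for (int s = 0; s < nsub; ++s) B[s] = as<arma::mat>(betas[s]);
  const arma::uword S = B[0].n_rows;
  const arma::uword P = S * (S - 1) / 2;
  const double pnorm_ = arma::norm(predResid);
  arma::mat out(nsub, ncen);
  out.fill(NA_REAL);
  arma::vec v(P);
  for (int c = 0; c < ncen; ++c) {
    IntegerVector mem = nbrs[c];
    if (mem.size() < 2) continue;
    arma::uvec cols(mem.size());
    for (int k = 0; k < mem.size(); ++k) cols(k) = mem[k] - 1;
    for (int s = 0; s < nsub; ++s) {
      if (!rdm_vector(B[s].cols(cols), v)) continue;
      arma::vec r = rank_avg(v);
      arma::vec resid = r - Q * (Q.t() * r);
      double rn = arma::norm(resid);
      // no residual variance: partial correlation 0 by convention
      if (rn < 1e-8 * P || pnorm_ < 1e-8 * P) { out(s, c) = 0.0; continue; }
      out(s, c) = arma::dot(resid, predResid) / (rn * pnorm_);
    }
  }
  return out;
}
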