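// Alternating multiplicative-update loops for the Boltzmann-constrained
// factorization (LSE and generalized-KL objectives) and the free-basis
// NMF baseline.  These mirror the single-step R rules exactly; the R
// test-suite checks one-step equivalence.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-12;

static mat basis(const vec& t, const vec& tau) {
  // w_jr = exp(-t_j / tau_r)
  return exp(-(t * (1.0 / tau.t())));
}

static double lse_obj(const mat& I, const mat& WH) {
  return accu(square(I - WH));
}

static double kl_obj(const mat& I, const mat& WH) {
  mat whf = clamp(WH, EPS, datum::inf);
  mat logterm = zeros(size(I));
  uvec pos = find(I > 0);
  logterm(pos) = I(pos) % log(I(pos) / whf(pos));
  return accu(logterm - I + whf);
}

// [[Rcpp::export]]
Rcpp::List bznmf_fit_cpp(const arma::mat& I, const arma::vec& t,
                         const arma::vec& tau0, const arma::mat& H0,
                         int objective, int max_iter, double rel_tol,
                         double tau_floor, double tau_ceiling) {
  const bool kl = (objective == 1);
  vec tau = clamp(tau0, tau_floor, tau_ceiling);
  mat H = H0;
  const int R = tau.n_elem;

  mat W = basis(t, tau);
  mat WH = W * H;
  double D = kl ? kl_obj(I, WH) : lse_obj(I, WH);

  std::vector<double> trace;
  trace.reserve(std::min(max_iter + 1, 20000));
  trace.push_back(D);

  uvec degen(R, fill::zeros);
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // --- tau update ---
    mat TW = W.each_col() % t;          // t_j * w_jr
    vec num(R), den(R);
    if (kl) {
      mat Q = I / clamp(WH, EPS, datum::inf);
      num = sum(TW % (Q * H.t()), 0).t();
      den = sum(TW, 0).t() % sum(H, 1);
    } else {
      num = sum(TW % (I * H.t()), 0).t();
      den = sum(TW % (WH * H.t()), 0).t();
    }
    for (int r = 0; r < R; ++r) {
      if (den(r) <= EPS || sum(H.row(r)) <= EPS) {
        degen(r) = 1;                   // unused component: freeze tau
      } else {
        degen(r) = 0;
        double tn = tau(r) * num(r) / den(r);
        tau(r) = std::min(std::max(tn, tau_floor), tau_ceiling);
      }
    }
    W = basis(t, tau);
    WH = W * H;

    // --- H update ---
    if (kl) {
      mat Q = I / clamp(WH, EPS, datum::inf);
      mat numH = W.t() * Q;
      vec denH = clamp(sum(W, 0).t(), EPS, datum::inf);
      H = H % (numH.each_col() / denH);
    } else {
      mat numH = W.t() * I;
      mat denH = (W.t() * W) * H;
      H = H % (numH / clamp(denH, EPS, datum::inf));
    }
    WH = W * H;

    double Dnew = kl ? kl_obj(I, WH) : lse_obj(I, WH);
    trace.push_back(Dnew);
    if (!std::isfinite(Dnew)) { D = Dnew; break; }
    double rel = std::fabs(D - Dnew) / std::max(D, EPS);
    D = Dnew;
    if (rel < rel_tol) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("tau") = tau,
      Rcpp::Named("H") = H,
      Rcpp::Named("objective") = D,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("degenerate") = Rcpp::LogicalVector(degen.begin(),
                                                      degen.end()));
}

// [[Rcpp::export]]
Rcpp::List nmf_lse_fit_cpp(const arma::mat& I, const arma::mat& W0,
                           const arma::mat& H0, int max_iter,
                           double rel_tol) {
  mat W = W0, H = H0;
  mat WH = W * H;
  double D = lse_obj(I, WH);
  std::vector<double> trace;
  trace.push_back(D);
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    H = H % ((W.t() * I) / clamp((W.t() * W) * H, EPS, datum::inf));
    W = W % ((I * H.t()) / clamp(W * (H * H.t()), EPS, datum::inf));
    WH = W * H;
    double Dnew = lse_obj(I, WH);
    trace.push_back(Dnew);
    if (!std::isfinite(Dnew)) { D = Dnew; break; }
    double rel = std::fabs(D - Dnew) / std::max(D, EPS);
    D = Dnew;
    if (rel < rel_tol) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("W") = W,
      Rcpp::Named("H") = H,
      Rcpp::Named("objective") = D,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged);
}

// Coefficient-only refit at fixed tau (used by the cross-validation
// baseline on held-out sequences).
// [[Rcpp::export]]
Rcpp::List fit_coeffs_cpp(const arma::mat& I, const arma::vec& t,
                          const arma::vec& tau, const arma::mat& H0,
                          int objective, int max_iter, double rel_tol) {
  const bool kl = (objective == 1);
  mat W = basis(t, tau);
  mat H = H0;
  mat WH = W * H;
  double D = kl ? kl_obj(I, WH) : lse_obj(I, WH);
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    if (kl) {
      mat Q = I / clamp(WH, EPS, datum::inf);
      vec denH = clamp(sum(W, 0).t(), EPS, datum::inf);
      mat numH = W.t() * Q;
      H = H % (numH.each_col() / denH);
    } else {
      H = H % ((W.t() * I) / clamp((W.t() * W) * H, EPS, datum::inf));
    }
    WH = W * H;
    double Dnew = kl ? kl_obj(I, WH) : lse_obj(I, WH);
    if (!std::isfinite(Dnew)) { D = Dnew; break; }
    double rel = std::fabs(D - Dnew) / std::max(D, EPS);
    D = Dnew;
    if (rel < rel_tol) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;
  return Rcpp::List::create(Rcpp::Named("H") = H,
                            Rcpp::Named("objective") = D,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("converged") = converged);
}
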