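// Cox proportional-hazards engine: Newton-Raphson maximization of the
// Breslow or Efron partial likelihood, a batched univariate screen over
// voxel columns, and the full nested leave-one-out loop (screen ->
// threshold -> composite indices -> covariate-adjusted refit -> score).
//
// Conventions shared by all entry points:
//   * covariate columns are centered by the caller (the partial likelihood
//     is shift-invariant, centering only guards exp() overflow);
//   * ties handled per `ties`: 0 = Breslow, 1 = Efron;
//   * |beta| exceeding `cap` marks a monotone likelihood (separation) and
//     the fit is flagged non-converged rather than crashing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One sweep over the risk sets at the current beta: log partial likelihood,
// score vector and observed information. `ord` holds subject indices in
// descending time order so risk-set sums accumulate incrementally.
static void cox_pass(const arma::mat& X, const arma::vec& time,
                     const arma::ivec& event, const arma::uvec& ord,
                     const arma::vec& beta, int ties,
                     double& ll, arma::vec& U, arma::mat& H) {
  const arma::uword n = ord.n_elem, p = X.n_cols;
  arma::vec eta = X * beta;
  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);
  ll = 0.0;
  U.zeros(p);
  H.zeros(p, p);

  arma::uword i = 0;
  while (i < n) {
    const double t = time(ord(i));
    arma::uword j = i;
    int d = 0;
    double s0d = 0.0, etad = 0.0;
    arma::vec s1d(p, arma::fill::zeros), xd(p, arma::fill::zeros);
    arma::mat s2d(p, p, arma::fill::zeros);
    // add the whole tie block to the risk set before its deaths are scored
    while (j < n && time(ord(j)) == t) {
      const arma::uword k = ord(j);
      const double w = std::exp(eta(k));
      const arma::rowvec xr = X.row(k);
      S0 += w;
      S1 += w * xr.t();
      S2 += w * (xr.t() * xr);
      if (event(k)) {
        ++d;
        etad += eta(k);
        xd += xr.t();
        s0d += w;
        s1d += w * xr.t();
        s2d += w * (xr.t() * xr);
      }
      ++j;
    }
    if (d > 0) {
      if (ties == 0) {  // Breslow
        ll += etad - d * std::log(S0);
        const arma::vec m = S1 / S0;
        U += xd - d * m;
        H += d * (S2 / S0 - m * m.t());
      } else {  // Efron
        ll += etad;
        U += xd;
        for (int l = 0; l < d; ++l) {
          const double f = static_cast<double>(l) / d;
          const double den = S0 - f * s0d;
          const arma::vec V1 = S1 - f * s1d;
          const arma::mat V2 = S2 - f * s2d;
          const arma::vec m = V1 / den;
          ll -= std::log(den);
          U -= m;
          H += V2 / den - m * m.t();
        }
      }
    }
    i = j;
  }
}

// Newton-Raphson from beta = 0 with step-halving on likelihood decrease.
// Returns convergence flag; fills beta, the final information matrix, the
// maximized and null log partial likelihoods, the score/information at 0,
// the iteration count and a separation flag.
static bool cox_nr(const arma::mat& X, const arma::vec& time,
                   const arma::ivec& event, const arma::uvec& ord, int ties,
                   double tol, int maxit, double cap,
                   arma::vec& beta, arma::mat& Hfin, double& ll, double& ll0,
                   arma::vec& U0, arma::mat& I0, int& iter, bool& capped) {
  const arma::uword p = X.n_cols;
  beta.zeros(p);
  arma::vec U(p);
  arma::mat H(p, p);
  cox_pass(X, time, event, ord, beta, ties, ll, U, H);
  ll0 = ll;
  U0 = U;
  I0 = H;
  capped = false;
  bool conv = false;
  for (iter = 0; iter < maxit; ++iter) {
    if (arma::norm(U, 2) < tol) { conv = true; break; }
    arma::vec step;
    if (!arma::solve(step, H, U, arma::solve_opts::no_approx)) break;
    double ll_new;
    arma::vec beta_new, U_new(p);
    arma::mat H_new(p, p);
    int halvings = 0;
    for (;;) {
      beta_new = beta + step;
      cox_pass(X, time, event, ord, beta_new, ties, ll_new, U_new, H_new);
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) break;
      step *= 0.5;
      if (++halvings > 30) break;
    }
    beta = beta_new;
    ll = ll_new;
    U = U_new;
    H = H_new;
    if (arma::abs(beta).max() > cap) { capped = true; break; }
  }
  if (!conv && !capped && arma::norm(U, 2) < tol) conv = true;
  // monotone likelihood: the information collapses as |beta| drifts toward
  // infinity even though the gradient norm can fall below tol first
  if (conv) {
    for (arma::uword j = 0; j < p; ++j) {
      if (H(j, j) < 1e-6 * I0(j, j)) { capped = true; conv = false; break; }
    }
  }
  Hfin = H;
  return conv;
}

static arma::uvec desc_order(const arma::vec& time) {
  return arma::sort_index(time, "descend");
}

// [[Rcpp::export]]
List cpp_cox_fit(const arma::mat& X, const arma::vec& time,
                 const arma::ivec& event, int ties, double tol, int maxit,
                 double cap) {
  arma::uvec ord = desc_order(time);
  arma::vec beta, U0;
  arma::mat H, I0;
  double ll, ll0;
  int iter;
  bool capped;
  bool conv = cox_nr(X, time, event, ord, ties, tol, maxit, cap,
                     beta, H, ll, ll0, U0, I0, iter, capped);
  arma::vec se(X.n_cols);
  se.fill(NA_REAL);
  if (conv) {
    arma::mat Hinv;
    if (arma::inv(Hinv, H)) se = arma::sqrt(Hinv.diag());
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["loglik"] = ll,
                      _["loglik_null"] = ll0, _["converged"] = conv,
                      _["capped"] = capped, _["iter"] = iter,
                      _["score0"] = U0, _["info0"] = I0);
}

// ---- univariate screening ------------------------------------------------

// Scalar specialization of cox_pass for a single centered covariate.
// Tie blocks are precomputed as [starts[b], starts[b+1]) over `ord`.
static void uni_pass(const double* x, const arma::ivec& event,
                     const arma::uvec& ord, const std::vector<int>& starts,
                     double beta, double& ll, double& U, double& I) {
  double S0 = 0, S1 = 0, S2 = 0;
  ll = 0; U = 0; I = 0;
  const int nb = static_cast<int>(starts.size()) - 1;
  for (int b = 0; b < nb; ++b) {
    int d = 0;
    double s0d = 0, s1d = 0, s2d = 0, xd = 0, etad = 0;
    for (int j = starts[b]; j < starts[b + 1]; ++j) {
      const arma::uword k = ord(j);
      const double xk = x[k];
      const double e = beta * xk;
      const double w = std::exp(e);
      S0 += w;
      S1 += w * xk;
      S2 += w * xk * xk;
      if (event(k)) {
        ++d;
        xd += xk;
        etad += e;
        s0d += w;
        s1d += w * xk;
        s2d += w * xk * xk;
      }
    }
    if (d > 0) {
      ll += etad;
      U += xd;
      for (int l = 0; l < d; ++l) {
        // f = 0 for every l reproduces Breslow; Efron downweights the deaths
        const double f = s0d > 0 && d > 0 ? static_cast<double>(l) / d : 0.0;
        const double den = S0 - f * s0d;
        const double V1 = S1 - f * s1d;
        const double V2 = S2 - f * s2d;
        const double m = V1 / den;
        ll -= std::log(den);
        U -= m;
        I += V2 / den - m * m;
      }
    }
  }
}

static void tie_blocks(const arma::vec& time, const arma::uvec& ord,
                       std::vector<int>& starts) {
  starts.clear();
  const int n = static_cast<int>(ord.n_elem);
  int i = 0;
  while (i < n) {
    starts.push_back(i);
    const double t = time(ord(i));
    while (i < n && time(ord(i)) == t) ++i;
  }
  starts.push_back(n);
}

// Breslow variant of uni_pass (f == 0); kept separate so the screening hot
// loop pays no per-death branching.
static void uni_pass_breslow(const double* x, const arma::ivec& event,
                             const arma::uvec& ord,
                             const std::vector<int>& starts, double beta,
                             double& ll, double& U, double& I) {
  double S0 = 0, S1 = 0, S2 = 0;
  ll = 0; U = 0; I = 0;
  const int nb = static_cast<int>(starts.size()) - 1;
  for (int b = 0; b < nb; ++b) {
    int d = 0;
    double xd = 0, etad = 0;
    for (int j = starts[b]; j < starts[b + 1]; ++j) {
      const arma::uword k = ord(j);
      const double xk = x[k];
      const double e = beta * xk;
      const double w = std::exp(e);
      S0 += w;
      S1 += w * xk;
      S2 += w * xk * xk;
      if (event(k)) { ++d; xd += xk; etad += e; }
    }
    if (d > 0) {
      const double m = S1 / S0;
      ll += etad - d * std::log(S0);
      U += xd - d * m;
      I += d * (S2 / S0 - m * m);
    }
  }
}

struct UniFit {
  double beta, se, ll, ll0;
  int status;  // 0 ok, 1 capped/separated, 2 not converged, 3 degenerate
};

static UniFit uni_cox(const double* xfull, const arma::vec& time,
                      const arma::ivec& event, const arma::uvec& ord,
                      const std::vector<int>& starts, int ties, double tol,
                      int maxit, double cap, std::vector<double>& xc) {
  const int n = static_cast<int>(ord.n_elem);
  // center over the subjects actually in `ord` (training set)
  double mean = 0;
  for (int j = 0; j < n; ++j) mean += xfull[ord(j)];
  mean /= n;
  double ss = 0;
  for (int j = 0; j < n; ++j) {
    const arma::uword k = ord(j);
    xc[k] = xfull[k] - mean;
    ss += xc[k] * xc[k];
  }
  UniFit out{0.0, NA_REAL, NA_REAL, NA_REAL, 0};
  if (ss / n < 1e-24) { out.status = 3; return out; }
  double beta = 0, ll, U, I;
  auto pass = [&](double b, double& l, double& u, double& i2) {
    if (ties == 0)
      uni_pass_breslow(xc.data(), event, ord, starts, b, l, u, i2);
    else
      uni_pass(xc.data(), event, ord, starts, b, l, u, i2);
  };
  pass(beta, ll, U, I);
  out.ll0 = ll;
  const double info_at_zero = I;
  bool conv = false, capped = false;
  for (int iter = 0; iter < maxit; ++iter) {
    if (std::fabs(U) < tol) { conv = true; break; }
    double step = U / I;
    double ll_new, U_new, I_new, beta_new;
    int h = 0;
    for (;;) {
      beta_new = beta + step;
      pass(beta_new, ll_new, U_new, I_new);
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) break;
      step *= 0.5;
      if (++h > 30) break;
    }
    beta = beta_new; ll = ll_new; U = U_new; I = I_new;
    if (std::fabs(beta) > cap) { capped = true; break; }
  }
  out.beta = beta;
  out.ll = ll;
  // information collapse relative to beta = 0 marks a monotone likelihood
  if (!capped && conv && I < 1e-6 * info_at_zero) capped = true;
  if (capped) {
    out.status = 1;
  } else if (!conv && std::fabs(U) >= tol) {
    out.status = 2;
  } else {
    out.se = I > 0 ? 1.0 / std::sqrt(I) : NA_REAL;
    if (!std::isfinite(out.se)) out.status = 2;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cox_screen(const arma::mat& Z, const arma::vec& time,
                    const arma::ivec& event, int ties, double tol, int maxit,
                    double cap) {
  const arma::uword n = Z.n_rows, V = Z.n_cols;
  arma::uvec ord = desc_order(time);
  std::vector<int> starts;
  tie_blocks(time, ord, starts);
  NumericVector beta(V), se(V), ll(V), ll0(V);
  IntegerVector status(V);
  std::vector<double> xc(n);
  for (arma::uword v = 0; v < V; ++v) {
    UniFit f = uni_cox(Z.colptr(v), time, event, ord, starts, ties, tol,
                       maxit, cap, xc);
    beta[v] = f.beta;
    se[v] = f.se;
    ll[v] = f.ll;
    ll0[v] = f.ll0;
    status[v] = f.status;
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["loglik"] = ll,
                      _["loglik_null"] = ll0, _["status"] = status);
}

// ---- nested leave-one-out loop -------------------------------------------

// For each held-out subject: univariate screen on the remaining n-1, build
// protective (beta<0) / risk (beta>0) masks at two-sided Wald p < alpha,
// sum the held-out subject's connectivity over each mask, refit the final
// Cox model (indexP, indexR, covariates) on the training set and score the
// held-out subject by its linear predictor relative to training means.
// [[Rcpp::export]]
List cpp_loocv(const arma::mat& Z, const arma::mat& C, const arma::vec& time,
               const arma::ivec& event, double alpha, int ties, double tol,
               int maxit, double cap, bool return_masks) {
  const arma::uword n = Z.n_rows, V = Z.n_cols, q = C.n_cols;
  const arma::uword pfull = 2 + q;
  NumericVector scores(n), idxP(n), idxR(n);
  IntegerVector nprot(n), nrisk(n), cov_only(n), fit_ok(n);
  NumericMatrix fold_beta(pfull, n);
  std::fill(fold_beta.begin(), fold_beta.end(), NA_REAL);
  LogicalMatrix prot_mask(return_masks ? V : 0, return_masks ? n : 0);
  LogicalMatrix risk_mask(return_masks ? V : 0, return_masks ? n : 0);

  std::vector<int> starts;
  std::vector<double> xc(n);
  arma::uvec ord(n - 1);
  arma::uvec global_ord = desc_order(time);

  for (arma::uword i = 0; i < n; ++i) {
    // training order: global descending order with subject i removed
    arma::uword m = 0;
    int ev = 0;
    for (arma::uword j = 0; j < n; ++j) {
      const arma::uword k = global_ord(j);
      if (k == i) continue;
      ord(m++) = k;
      if (event(k)) ++ev;
    }
    if (ev < 2) stop("fold %d: training set has fewer than 2 events",
                     static_cast<int>(i) + 1);
    tie_blocks(time, ord, starts);

    std::vector<arma::uword> prot, risk;
    for (arma::uword v = 0; v < V; ++v) {
      UniFit f = uni_cox(Z.colptr(v), time, event, ord, starts, ties, tol,
                         maxit, cap, xc);
      if (f.status != 0 || !(f.se > 0)) continue;
      const double z = f.beta / f.se;
      const double p = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
      if (p < alpha) {
        if (f.beta < 0) prot.push_back(v);
        else if (f.beta > 0) risk.push_back(v);
      }
    }
    nprot[i] = static_cast<int>(prot.size());
    nrisk[i] = static_cast<int>(risk.size());
    if (return_masks) {
      for (arma::uword v : prot) prot_mask(v, i) = true;
      for (arma::uword v : risk) risk_mask(v, i) = true;
    }

    // composite indices: raw sums of Fisher-z values over each mask
    arma::vec ip(n, arma::fill::zeros), ir(n, arma::fill::zeros);
    for (arma::uword v : prot) ip += Z.col(v);
    for (arma::uword v : risk) ir += Z.col(v);
    idxP[i] = ip(i);
    idxR[i] = ir(i);

    // assemble the final design over usable columns
    arma::mat D(n, pfull);
    std::vector<int> colid;  // 0=indexP, 1=indexR, 2..=covariates
    arma::uword pc = 0;
    if (!prot.empty()) { D.col(pc++) = ip; colid.push_back(0); }
    if (!risk.empty()) { D.col(pc++) = ir; colid.push_back(1); }
    for (arma::uword c = 0; c < q; ++c) {
      D.col(pc++) = C.col(c);
      colid.push_back(2 + static_cast<int>(c));
    }
    cov_only[i] = prot.empty() && risk.empty();

    // training rows, drop zero-variance columns, center by training means
    arma::uvec tr(n - 1);
    m = 0;
    for (arma::uword j = 0; j < n; ++j) if (j != i) tr(m++) = j;
    arma::mat Dtr = D.submat(tr, arma::regspace<arma::uvec>(0, pc - 1));
    arma::rowvec mu = arma::mean(Dtr, 0);
    Dtr.each_row() -= mu;
    arma::uvec keep = arma::find(arma::sum(arma::square(Dtr), 0).t() /
                                 (n - 1) > 1e-20);
    if (keep.n_elem == 0) {
      scores[i] = 0.0;
      fit_ok[i] = 0;
      continue;
    }
    Dtr = Dtr.cols(keep);

    arma::uvec tord(n - 1);
    // training rows are in subject order; re-derive descending time order
    {
      arma::vec ttr(n - 1);
      for (arma::uword j = 0; j < n - 1; ++j) ttr(j) = time(tr(j));
      tord = arma::sort_index(ttr, "descend");
    }
    arma::ivec etr(n - 1);
    for (arma::uword j = 0; j < n - 1; ++j) etr(j) = event(tr(j));
    arma::vec ttr(n - 1);
    for (arma::uword j = 0; j < n - 1; ++j) ttr(j) = time(tr(j));

    arma::vec beta, U0;
    arma::mat H, I0;
    double ll, ll0;
    int iter;
    bool capped;
    bool conv = cox_nr(Dtr, ttr, etr, tord, ties, tol, maxit, cap,
                       beta, H, ll, ll0, U0, I0, iter, capped);
    fit_ok[i] = conv ? 1 : 0;
    double sc = 0.0;
    for (arma::uword c = 0; c < keep.n_elem; ++c) {
      const arma::uword col = keep(c);
      sc += (D(i, col) - mu(col)) * beta(c);
      fold_beta(colid[col], i) = beta(c);
    }
    scores[i] = sc;
  }

  List out = List::create(_["scores"] = scores, _["index_p"] = idxP,
                          _["index_r"] = idxR, _["n_protective"] = nprot,
                          _["n_risk"] = nrisk, _["cov_only"] = cov_only,
                          _["fit_ok"] = fit_ok, _["fold_beta"] = fold_beta);
  if (return_masks) {
    out["prot_mask"] = prot_mask;
    out["risk_mask"] = risk_mask;
  }
  return out;
}
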