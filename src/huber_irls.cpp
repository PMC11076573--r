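#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Case-weighted median over entries with positive weight (cumulative-weight
// definition, midpoint at an exact 0.5 boundary) — matches the R helper.
static double weighted_median(const vec& x, const vec& w) {
  uvec keep = find(w > 0);
  if (keep.n_elem == 0) return datum::nan;
  vec xs = x(keep), ws = w(keep);
  uvec ord = sort_index(xs);
  double tot = accu(ws), c = 0.0;
  for (uword k = 0; k < ord.n_elem; ++k) {
    c += ws(ord(k));
    double frac = c / tot;
    if (frac >= 0.5) {
      if (std::abs(frac - 0.5) < 1e-12 && k + 1 < ord.n_elem) {
        vec xsort = sort(xs);
        return 0.5 * (xsort(k) + xsort(k + 1));
      }
      vec xsort = sort(xs);
      return xsort(k);
    }
  }
  return max(xs);
}

static vec wls_solve(const mat& X, const vec& y, const vec& w, bool& ok) {
  mat Xs = X.each_col() % sqrt(w);         // syrk-friendly normal equations
  mat A = Xs.t() * Xs;
  vec b = X.t() * (w % y);
  vec beta;
  ok = solve(beta, A, b, solve_opts::no_approx + solve_opts::likely_sympd);
  if (ok && !beta.is_finite()) ok = false;
  return beta;
}

// [[Rcpp::export(name = ".huber_irls_cpp")]]
Rcpp::List huber_irls_cpp(const arma::vec& y, const arma::mat& X,
                          const arma::vec& cw, double tuning, int max_iter,
                          double tol, bool sandwich) {
  const uword n = y.n_elem, p = X.n_cols;
  uvec active = find(cw > 0);
  double n_eff = active.n_elem;

  bool ok = true;
  vec beta = wls_solve(X, y, cw, ok);
  if (!ok) Rcpp::stop("design matrix is rank deficient on the weighted support");
  vec rob_w = ones<vec>(n);
  double scale = datum::nan;
  bool converged = false;
  int iter = 0;
  vec r = y - X * beta;

  if (!std::isfinite(tuning)) {
    converged = true;
    scale = weighted_median(abs(r), cw) / 0.6745;
  } else {
    double yscale = weighted_median(abs(y), cw);
    if (yscale < 1e-12) yscale = 1e-12;
    for (iter = 1; iter <= max_iter; ++iter) {
      r = y - X * beta;
      scale = weighted_median(abs(r), cw) / 0.6745;
      if (!std::isfinite(scale) || scale < 1e-12 * yscale) {
        rob_w.ones();
        converged = true;
        break;
      }
      vec u = abs(r) / scale;
      rob_w = clamp(tuning / u, 0.0, 1.0);
      rob_w.elem(find(u <= tuning)).ones();
      vec beta_new = wls_solve(X, y, cw % rob_w, ok);
      if (!ok) Rcpp::stop("rank deficiency during IRLS");
      double step = abs(beta_new - beta).max();
      double ref = std::max(1.0, abs(beta).max());
      beta = beta_new;
      if (step <= tol * ref) { converged = true; break; }
    }
    if (iter > max_iter) iter = max_iter;
  }

  vec w_tot = cw % rob_w;
  r = y - X * beta;
  double wrss = accu(w_tot % square(r));
  double df = n_eff - p;
  vec se(p, fill::zeros);
  if (sandwich) {
    vec psi_p;
    if (std::isfinite(tuning) && std::isfinite(scale) && scale > 0)
      psi_p = conv_to<vec>::from(abs(r / scale) <= tuning);
    else
      psi_p = ones<vec>(n);
    vec psi = rob_w % r;
    mat A = X.t() * (X.each_col() % (cw % psi_p));
    mat B = X.t() * (X.each_col() % square(cw % psi));
    mat Ai;
    if (!inv_sympd(Ai, symmatu(A))) Ai = pinv(symmatu(A));
    mat V = Ai * B * Ai * (n_eff / df);
    se = sqrt(clamp(V.diag(), 0.0, datum::inf));
  } else {
    mat A = X.t() * (X.each_col() % w_tot);
    mat Ai;
    if (!inv_sympd(Ai, symmatu(A))) Ai = pinv(symmatu(A));
    se = sqrt(clamp(Ai.diag() * (wrss / df), 0.0, datum::inf));
  }
  // AIC from the case-weighted RSS of the robust fit's residuals: the
  // robustness weights (and the Huber scale behind them) are re-estimated per
  // model, so a robustness-weighted RSS is not comparable across models,
  // while this loss is. The multiplier is the effective sample size
  // (sum w)^2 / sum(w^2): under variable matching weights the expected
  // chance RSS-gain of a junk parameter is sigma^2 * sum(w^2)/sum(w), and
  // ESS * log(RSS) prices that at 1 per parameter, exactly as n * log(RSS)
  // does for unit weights.
  double rss_aic = accu(cw % square(r));
  double sum_w = accu(cw), sum_w2 = accu(square(cw));
  double ess = sum_w * sum_w / sum_w2;
  double aic = ess * std::log(rss_aic / ess) + 2.0 * (p + 1);

  return Rcpp::List::create(
    Rcpp::Named("coefficients") = beta,
    Rcpp::Named("se") = se,
    Rcpp::Named("scale") = scale,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("residuals") = r,
    Rcpp::Named("rob_weights") = rob_w,
    Rcpp::Named("total_weights") = w_tot,
    Rcpp::Named("wrss") = wrss,
    Rcpp::Named("df") = df,
    Rcpp::Named("n_eff") = n_eff,
    Rcpp::Named("aic") = aic);
}
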