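#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Row-wise Poisson log-linear regressions with a fixed offset.
//
// For each row i of Y solves
//   max_g  sum_j [ y_ij * (o_ij + h_j . g) - exp(o_ij + h_j . g) ]
// (no intercept beyond the offset) by damped Newton iterations. This is the
// score equation H' (y - mu) = 0 with mu = exp(o + H g), i.e. exactly what
// glm(y ~ 0 + H, family = poisson, offset = o) solves, batched over rows.
//
// Y: n x m counts; O: n x m offsets (log of the fixed multiplicative part);
// H: m x K covariates; G0: n x K warm start. Linear predictors are clamped
// to [-30, 30] and Newton steps to max-norm 4 for numerical safety.
// [[Rcpp::export]]
Rcpp::List batch_poisson_irls(const arma::mat& Y, const arma::mat& O,
                              const arma::mat& H, const arma::mat& G0,
                              int maxit = 25, double tol = 1e-9) {
  const uword n = Y.n_rows;
  const uword K = H.n_cols;
  mat G = G0;
  uvec conv(n, fill::zeros);

  for (uword i = 0; i < n; ++i) {
    vec y = Y.row(i).t();
    vec o = O.row(i).t();
    vec g = G.row(i).t();
    bool ok = false;
    for (int it = 0; it < maxit; ++it) {
      vec eta = clamp(o + H * g, -30.0, 30.0);
      vec mu = exp(eta);
      vec score = H.t() * (y - mu);
      mat info = H.t() * (H.each_col() % mu);
      info.diag() += 1e-10;  // guard against singular weights
      vec step;
      if (!solve(step, info, score, solve_opts::no_approx) ||
          !step.is_finite()) {
        break;
      }
      double sm = norm(step, "inf");
      if (sm > 4.0) step *= 4.0 / sm;  // damp large steps
      g += step;
      if (sm < tol * (1.0 + norm(g, "inf"))) { ok = true; break; }
    }
    if (!g.is_finite()) { g.zeros(); ok = false; }
    if (!ok) {
      // accept if the score equations are satisfied to relative tolerance
      vec eta = clamp(o + H * g, -30.0, 30.0);
      vec score = H.t() * (y - exp(eta));
      ok = norm(score, "inf") < 1e-6 * (1.0 + accu(y));
      if (!ok) g.zeros();
    }
    G.row(i) = g.t();
    conv(i) = ok ? 1 : 0;
  }
  return Rcpp::List::create(Rcpp::Named("G") = G,
                            Rcpp::Named("converged") = conv);
}

// Scan statistic U for a window sum (0 log 0 := 0 limit).
static inline double ustat(double ys, double ls) {
  return ys == 0.0 ? ls : ys * std::log(ys / ls) - (ys - ls);
}

// Best split of the stretch lo..hi by the mBIC change it would produce;
// the compiled core of the segmentation recursion (see best_window in R/).
// cy, cl are length n+1 cumulative sums with cy[i] = sum of elements 1..i.
// a, b are the neighbouring change points in the tau convention; n the
// chromosome length in exons. Returns (s, t, U, delta) or s = -1 when the
// stretch admits no valid split. Ties break toward the smallest s, then
// the smallest t (guaranteed by the ascending scan with strict >).
// [[Rcpp::export]]
Rcpp::NumericVector best_window_cpp(const arma::vec& cy, const arma::vec& cl,
                                    int lo, int hi, int a, int b, int n) {
  const double logn = std::log((double) n);
  const double cur = 0.5 * std::log((double) (b - a));
  const double u0 = ustat(cy[hi] - cy[lo - 1], cl[hi] - cl[lo - 1]);
  double best = -std::numeric_limits<double>::infinity();
  int bs = -1, bt = -1; double bu = 0.0;
  for (int s = lo; s <= hi; ++s) {
    const double uL = (s > lo) ? ustat(cy[s - 1] - cy[lo - 1],
                                       cl[s - 1] - cl[lo - 1]) : 0.0;
    const double g1 = (double) (s - 1 - a);   // spacing of cp s-1
    if (s > lo && g1 <= 0.0) continue;        // change point at 1: invalid
    for (int t = s; t <= hi; ++t) {
      if (s == lo && t == hi) continue;       // the full stretch
      double pen, uR;
      if (s == lo) {                          // cuts {t}
        const double gA = (double) (t - a), gB = (double) (b - t);
        if (gA <= 0.0) continue;
        pen = -0.5 * (std::log(gA) + std::log(gB)) + cur - logn;
      } else if (t == hi) {                   // cuts {s-1}
        const double gB = (double) (b - s + 1);
        pen = -0.5 * (std::log(g1) + std::log(gB)) + cur - logn;
      } else {                                // cuts {s-1, t}
        const double g2 = (double) (t - s + 1), g3 = (double) (b - t);
        pen = -0.5 * (std::log(g1) + std::log(g2) + std::log(g3)) +
          cur - 2.0 * logn;
      }
      uR = (t < hi) ? ustat(cy[hi] - cy[t], cl[hi] - cl[t]) : 0.0;
      const double u = ustat(cy[t] - cy[s - 1], cl[t] - cl[s - 1]);
      const double delta = u + uL + uR - u0 + pen;
      if (delta > best) { best = delta; bs = s; bt = t; bu = u; }
    }
  }
  return Rcpp::NumericVector::create(bs, bt, bu, best);
}
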