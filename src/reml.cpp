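// Restricted log-likelihood (and analytic gradient) for the intercept-only
// multi-level meta-regression
//
//   r_i = theta + u_{g1(i)} + w_{g2(i)} + e_i,
//   u ~ N(0, tau2_1), w ~ N(0, tau2_2), e_i ~ N(0, v_i) with v_i known.
//
// Marginal covariance V = D + Z G Z' with D = diag(v), Z the group
// indicator columns of both factors and G = diag(tau2_1 I_q1, tau2_2 I_q2).
// All quantities use the Woodbury identity
//   V^-1 = D^-1 - D^-1 Z G^1/2 M^-1 G^1/2 Z' D^-1,
//   M = I + G^1/2 Z' D^-1 Z G^1/2,
//   log|V| = log|M| + sum log v_i,
// which stays well defined at tau2 = 0 and costs O(k q^2).
//
// REML criterion (to minimize):
//   nll = 0.5 * [ log|V| + log(1' V^-1 1) + res' V^-1 res ],
// with theta-hat the GLS mean and res = r - theta-hat. The gradient
// w.r.t. tau2_j uses dV/dtau2_j = Zj Zj' and
//   d nll / d tau2_j = 0.5 * [ tr(P Aj) - q' Aj q ],  q = P r = V^-1 res,
//   tr(P Aj) = tr(V^-1 Aj) - (V^-1 1)' Aj (V^-1 1) / (1' V^-1 1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// dense path: explicit V and inv_sympd; cheaper than Woodbury for small k
static Rcpp::List reml_nll_dense(const vec &r, const vec &v,
                                 const ivec &g1, const ivec &g2,
                                 double tau1, double tau2, bool has2,
                                 bool want_grad) {
  const uword k = r.n_elem;
  mat V(k, k, fill::zeros);
  V.diag() = v;
  for (uword i = 0; i < k; ++i)
    for (uword j = 0; j <= i; ++j) {
      double add = 0.0;
      if (g1[i] == g1[j]) add += tau1;
      if (has2 && g2[i] == g2[j]) add += tau2;
      if (add != 0.0) {
        V(i, j) += add;
        if (i != j) V(j, i) += add;
      }
    }
  mat Vi;
  double ldet, sign;
  if (!inv_sympd(Vi, V) || (log_det(ldet, sign, V), sign <= 0.0))
    return Rcpp::List::create(Rcpp::Named("nll") = R_PosInf,
                              Rcpp::Named("ok") = false);
  vec ones_k(k, fill::ones);
  vec Vi1 = Vi * ones_k;
  double s11 = dot(ones_k, Vi1);
  double theta = dot(r, Vi1) / s11;
  vec res = r - theta;
  vec Vires = Vi * res;
  double nll = 0.5 * (ldet + std::log(s11) + dot(res, Vires));
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("nll") = nll, Rcpp::Named("theta") = theta,
      Rcpp::Named("se") = std::sqrt(1.0 / s11), Rcpp::Named("ok") = true);
  if (want_grad) {
    vec grad(has2 ? 2 : 1);
    for (int comp = 0; comp < (has2 ? 2 : 1); ++comp) {
      const ivec &g = (comp == 0) ? g1 : g2;
      int ng = g.max() + 1;
      double trViA = 0.0;
      for (uword i = 0; i < k; ++i)
        for (uword j = 0; j < k; ++j)
          if (g[i] == g[j]) trViA += Vi(i, j);
      vec gs1(ng, fill::zeros), gsq(ng, fill::zeros);
      for (uword i = 0; i < k; ++i) {
        gs1[g[i]] += Vi1[i];
        gsq[g[i]] += Vires[i];
      }
      grad[comp] = 0.5 * ((trViA - dot(gs1, gs1) / s11) - dot(gsq, gsq));
    }
    out["grad"] = grad;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List reml_nll_cpp(const arma::vec &r, const arma::vec &v,
                        const arma::ivec &g1, const arma::ivec &g2,
                        double tau1, double tau2, bool has2,
                        bool want_grad) {
  const uword k = r.n_elem;
  if (k <= 60)
    return reml_nll_dense(r, v, g1, g2, tau1, tau2, has2, want_grad);
  const uword q1 = g1.max() + 1;
  const uword q2 = has2 ? (g2.max() + 1) : 0;
  const uword q = q1 + q2;

  mat Z(k, q, fill::zeros);
  for (uword i = 0; i < k; ++i) {
    Z(i, g1[i]) = 1.0;
    if (has2) Z(i, q1 + g2[i]) = 1.0;
  }
  vec ghalf(q);
  ghalf.head(q1).fill(std::sqrt(tau1));
  if (has2) ghalf.tail(q2).fill(std::sqrt(tau2));

  vec vinv = 1.0 / v;
  mat W = Z.each_col() % vinv;              // D^-1 Z, k x q
  mat M = Z.t() * W;                        // Z' D^-1 Z
  M.each_col() %= ghalf;
  M.each_row() %= ghalf.t();
  M.diag() += 1.0;
  mat Mchol;
  if (!chol(Mchol, M)) {
    return Rcpp::List::create(Rcpp::Named("nll") = R_PosInf,
                              Rcpp::Named("ok") = false);
  }
  double logdetM = 2.0 * accu(log(Mchol.diag()));
  double logdetV = logdetM + accu(log(v));

  // Vi_apply(y) = D^-1 y - W Ghalf M^-1 Ghalf Z'(D^-1 y)
  auto vi_apply = [&](const vec &y) -> vec {
    vec dy = y % vinv;
    vec t = Z.t() * dy;
    t %= ghalf;
    vec s = solve(trimatl(Mchol.t()), t);
    s = solve(trimatu(Mchol), s);
    s %= ghalf;
    return dy - W * s;
  };

  vec ones_k(k, fill::ones);
  vec Vi1 = vi_apply(ones_k);
  double s11 = dot(ones_k, Vi1);            // 1' V^-1 1
  double s1r = dot(r, Vi1);                 // 1' V^-1 r
  double theta = s1r / s11;
  vec res = r - theta;
  vec Vires = vi_apply(res);
  double quad = dot(res, Vires);
  double nll = 0.5 * (logdetV + std::log(s11) + quad);

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("nll") = nll, Rcpp::Named("theta") = theta,
      Rcpp::Named("se") = std::sqrt(1.0 / s11), Rcpp::Named("ok") = true);

  if (want_grad) {
    // T = Z' V^-1 Z (q x q): diagonal blocks give tr(V^-1 Aj)
    mat ViZ(k, q);
    for (uword c = 0; c < q; ++c) ViZ.col(c) = vi_apply(Z.col(c));
    mat T = Z.t() * ViZ;
    vec a1 = Z.t() * Vi1;                   // group sums of V^-1 1
    vec aq = Z.t() * Vires;                 // group sums of P r
    vec grad(has2 ? 2 : 1);
    double tr1 = trace(T.submat(0, 0, q1 - 1, q1 - 1));
    double b1 = dot(a1.head(q1), a1.head(q1));
    double c1 = dot(aq.head(q1), aq.head(q1));
    grad[0] = 0.5 * ((tr1 - b1 / s11) - c1);
    if (has2) {
      double tr2 = trace(T.submat(q1, q1, q - 1, q - 1));
      double b2 = dot(a1.tail(q2), a1.tail(q2));
      double c2 = dot(aq.tail(q2), aq.tail(q2));
      grad[1] = 0.5 * ((tr2 - b2 / s11) - c2);
    }
    out["grad"] = grad;
  }
  return out;
}
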