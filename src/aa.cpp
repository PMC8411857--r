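// Archetypal-analysis engine: Lawson-Hanson NNLS on precomputed Gram
// matrices, simplex-constrained least squares via the penalty-row device,
// and the alternating minimization loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// min ||A x - b||^2 s.t. x >= 0, expressed through the normal equations:
// G = A'A, h = A'b (Lawson & Hanson active-set algorithm).
static vec nnls_gram(const mat& G, const vec& h, const double tol) {
  const uword m = G.n_rows;
  vec x(m, fill::zeros);
  std::vector<bool> passive(m, false);
  vec w = h;  // h - G x with x = 0
  const uword maxit = 3 * m + 30;

  for (uword outer = 0; outer < maxit; ++outer) {
    // pick the most violated dual among the active set
    sword j = -1;
    double wmax = tol;
    for (uword i = 0; i < m; ++i) {
      if (!passive[i] && w(i) > wmax) { wmax = w(i); j = (sword)i; }
    }
    if (j < 0) break;
    passive[(uword)j] = true;

    for (uword inner = 0; inner < maxit; ++inner) {
      uvec P(m);
      uword np = 0;
      for (uword i = 0; i < m; ++i) if (passive[i]) P(np++) = i;
      P.resize(np);

      mat Gp = G.submat(P, P);
      vec z;
      bool ok = solve(z, Gp, h(P), solve_opts::likely_sympd);
      if (!ok) z = pinv(Gp) * h(P);

      if (z.min() > 0) {
        x.zeros();
        x(P) = z;
        break;
      }
      // step back to the feasibility boundary
      double step = datum::inf;
      for (uword i = 0; i < np; ++i) {
        if (z(i) <= 0) {
          double xi = x(P(i));
          double a = xi / (xi - z(i));
          if (a < step) step = a;
        }
      }
      if (!std::isfinite(step)) step = 0.0;
      for (uword i = 0; i < np; ++i) {
        double xi = x(P(i));
        x(P(i)) = xi + step * (z(i) - xi);
      }
      bool removed = false;
      for (uword i = 0; i < np; ++i) {
        if (x(P(i)) <= 1e-14) {
          passive[P(i)] = false; x(P(i)) = 0.0; removed = true;
        }
      }
      if (!removed) {  // numerical stalemate: accept the feasible iterate
        break;
      }
    }
    w = h - G * x;
  }
  return x;
}

// Simplex-constrained coefficients from precomputed Gram pieces:
// G = D D' + M^2, H rows = y_i D' + M^2.  Each row of the result solves
// min ||coef_i D - y_i||^2 with coef_i >= 0 summing to 1 (penalty row of
// weight M appended to the design), then is renormalized to sum exactly to
// one (the penalty leaves a violation of order 1/M^2).
static mat simplex_coef_gram(const mat& G, const mat& H, const double tol) {
  const uword q = H.n_rows, m = G.n_rows;
  mat coef(q, m, fill::zeros);
  for (uword i = 0; i < q; ++i) {
    vec x = nnls_gram(G, H.row(i).t(), tol);
    double s = accu(x);
    if (s > 0) x /= s;
    coef.row(i) = x.t();
  }
  return coef;
}

// Express each row of Y as a simplex-constrained combination of the rows of D.
// [[Rcpp::export]]
arma::mat simplex_coef_cpp(const arma::mat& D, const arma::mat& Y, double M) {
  const double m2 = M * M;
  mat G = D * D.t() + m2;
  mat H = Y * D.t() + m2;
  const double tol = 1e-10 * G.diag().max();
  return simplex_coef_gram(G, H, tol);
}

// One archetypal-analysis fit from a fixed initialization (row indices of X
// seeding the archetypes). Alternates the weight step (alpha), the
// unconstrained archetype update, and the convex-hull projection step (beta).
// [[Rcpp::export]]
Rcpp::List aa_fit_cpp(const arma::mat& X, int k, arma::uvec init_idx,
                      int max_iter, double tol, double M) {
  const double m2 = M * M;
  mat Z = X.rows(init_idx);            // k x p
  const mat GX = X * X.t() + m2;       // beta-step Gram, fixed across iters
  const double tolX = 1e-10 * GX.diag().max();
  mat alpha, beta;
  mat bestZ, bestAlpha, bestBeta;
  double bestRss = datum::inf;
  std::vector<double> history;
  bool converged = false;
  int iters = 0;
  double rssPrev = datum::inf;

  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;
    mat GZ = Z * Z.t() + m2;
    alpha = simplex_coef_gram(GZ, X * Z.t() + m2, 1e-10 * GZ.diag().max());
    mat AtA = alpha.t() * alpha;
    AtA.diag() += 1e-10;                                 // ridge guard
    mat Ztilde = solve(AtA, alpha.t() * X);              // k x p
    beta = simplex_coef_gram(GX, Ztilde * X.t() + m2, tolX);
    Z = beta * X;
    double rss = accu(square(X - alpha * Z));
    history.push_back(rss);
    if (rss < bestRss) {
      bestRss = rss; bestZ = Z; bestAlpha = alpha; bestBeta = beta;
    }
    if (std::isfinite(rssPrev) &&
        std::abs(rssPrev - rss) <= tol * std::max(1.0, rssPrev)) {
      converged = true;
      break;
    }
    rssPrev = rss;
  }
  // Exact block-coordinate polish on the true objective: alternate the exact
  // alpha step with exact per-archetype beta updates (each a simplex-
  // constrained QP in beta_j), which is monotone and sharpens the classical
  // scheme's fixed point to the constrained optimum on well-posed instances.
  const mat GX0 = X * X.t();
  mat Zp = bestZ;
  mat alphap, betap = bestBeta;
  double rssPrevP = bestRss;
  for (int it = 0; it < 50; ++it) {
    mat GZ = Zp * Zp.t() + m2;
    alphap = simplex_coef_gram(GZ, X * Zp.t() + m2, 1e-10 * GZ.diag().max());
    mat R = X - alphap * Zp;
    for (int j = 0; j < k; ++j) {
      vec aj = alphap.col(j);
      double cj = dot(aj, aj);
      if (cj < 1e-12) continue;
      mat Rj = R + aj * Zp.row(j);
      mat Gj = cj * GX0 + m2;
      vec hj = X * (Rj.t() * aj) + m2;
      vec bj = nnls_gram(Gj, hj, 1e-10 * Gj.diag().max());
      double s = accu(bj);
      if (s <= 0) continue;
      bj /= s;
      rowvec zj = bj.t() * X;
      Zp.row(j) = zj;
      betap.row(j) = bj.t();
      R = Rj - aj * zj;
    }
    double rss = accu(square(R));
    if (rss < bestRss) {
      bestRss = rss; bestZ = Zp; bestAlpha = alphap; bestBeta = betap;
    }
    if (std::abs(rssPrevP - rss) <= tol * std::max(1.0, rssPrevP)) break;
    rssPrevP = rss;
  }

  // weights consistent with the best (returned) archetypes
  {
    mat GZ = bestZ * bestZ.t() + m2;
    bestAlpha = simplex_coef_gram(GZ, X * bestZ.t() + m2,
                                  1e-10 * GZ.diag().max());
  }
  bestRss = accu(square(X - bestAlpha * bestZ));

  return Rcpp::List::create(
    Rcpp::Named("Z") = bestZ,
    Rcpp::Named("alpha") = bestAlpha,
    Rcpp::Named("beta") = bestBeta,
    Rcpp::Named("rss") = bestRss,
    Rcpp::Named("history") = history,
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("converged") = converged);
}
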