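#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Sparse group LASSO proximal map applied in-place:
// soft-threshold each coordinate by t*lam1, then shrink each group's
// Euclidean norm by t*lam2 (block soft threshold).
static void sgl_prox(arma::vec &a, const arma::uvec &grp, int k,
                     const arma::vec &gw, double t1, double t2) {
  // elementwise soft threshold
  for (arma::uword j = 0; j < a.n_elem; ++j) {
    double v = a[j];
    if (v > t1) a[j] = v - t1;
    else if (v < -t1) a[j] = v + t1;
    else a[j] = 0.0;
  }
  if (t2 <= 0.0) return;
  // groupwise shrink (group g's norm thresholded by t2 * gw[g])
  std::vector<double> nrm(k, 0.0);
  for (arma::uword j = 0; j < a.n_elem; ++j)
    nrm[grp[j]] += a[j] * a[j];
  for (int g = 0; g < k; ++g) nrm[g] = std::sqrt(nrm[g]);
  for (arma::uword j = 0; j < a.n_elem; ++j) {
    double ng = nrm[grp[j]];
    double tg = t2 * gw[grp[j]];
    if (ng <= tg) a[j] = 0.0;
    else a[j] *= (1.0 - tg / ng);
  }
}

static double sgl_objective(const arma::vec &a, const arma::mat &XtX,
                            const arma::vec &Xty, double yty,
                            const arma::uvec &grp, int k,
                            const arma::vec &gw,
                            double lam1, double lam2) {
  // ||y - X a||^2 (no 1/2 factor) + lam1 ||a||_1 + lam2 sum_g w_g ||a_g||_2
  double quad = yty - 2.0 * arma::dot(a, Xty) + arma::dot(a, XtX * a);
  double l1 = arma::norm(a, 1);
  double gp = 0.0;
  if (lam2 > 0.0) {
    std::vector<double> nrm(k, 0.0);
    for (arma::uword j = 0; j < a.n_elem; ++j) nrm[grp[j]] += a[j] * a[j];
    for (int g = 0; g < k; ++g) gp += gw[g] * std::sqrt(nrm[g]);
  }
  return quad + lam1 * l1 + lam2 * gp;
}

//' @noRd
// [[Rcpp::export(name = ".sgl_fista")]]
List sgl_fista(const arma::mat &XtX, const arma::vec &Xty, double yty,
               const arma::ivec &groups, int ngroups,
               const arma::vec &group_weights,
               double lambda1, double lambda2,
               double lipschitz, double tol, int max_iter,
               const arma::vec &alpha0) {
  const arma::uword p = Xty.n_elem;
  arma::uvec grp(p);
  for (arma::uword j = 0; j < p; ++j) grp[j] = (arma::uword)groups[j];

  // smooth part f(a) = ||y - X a||^2 has gradient 2(XtX a - Xty),
  // Lipschitz constant 2*lambda_max(XtX) supplied by the caller.
  const double step = 1.0 / lipschitz;
  arma::vec a = alpha0, z = alpha0;
  double tt = 1.0;
  double obj = sgl_objective(a, XtX, Xty, yty, grp, ngroups, group_weights,
                             lambda1, lambda2);
  bool converged = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    arma::vec grad = 2.0 * (XtX * z - Xty);
    arma::vec a_new = z - step * grad;
    sgl_prox(a_new, grp, ngroups, group_weights,
             step * lambda1, step * lambda2);
    double obj_new = sgl_objective(a_new, XtX, Xty, yty, grp, ngroups,
                                   group_weights, lambda1, lambda2);
    if (obj_new > obj) {
      // monotone variant: reject the step, restart momentum from a
      z = a; tt = 1.0;
      continue;
    }
    double tt_new = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tt * tt));
    z = a_new + ((tt - 1.0) / tt_new) * (a_new - a);
    a = a_new; tt = tt_new;
    double rel = std::fabs(obj - obj_new) / std::max(1.0, std::fabs(obj));
    obj = obj_new;
    if (rel < tol) { converged = true; ++it; break; }
  }
  return List::create(_["alpha"] = a, _["objective"] = obj,
                      _["iterations"] = it, _["converged"] = converged);
}

//' @noRd
// [[Rcpp::export(name = ".pam_swap")]]
List pam_swap(const arma::mat &D, arma::ivec medoids, int max_iter) {
  // Greedy PAM: repeatedly apply the best cost-improving (medoid, point)
  // swap until none improves or max_iter sweeps. Medoids are 0-based here.
  const int n = D.n_rows;
  const int k = medoids.n_elem;
  std::vector<bool> is_med(n, false);
  for (int j = 0; j < k; ++j) is_med[medoids[j]] = true;

  auto total_cost = [&](const arma::ivec &med) {
    double c = 0.0;
    for (int i = 0; i < n; ++i) {
      double best = std::numeric_limits<double>::infinity();
      for (int j = 0; j < k; ++j) best = std::min(best, D(i, med[j]));
      c += best;
    }
    return c;
  };

  double cost = total_cost(medoids);
  for (int sweep = 0; sweep < max_iter; ++sweep) {
    double best_delta = -1e-12;
    int best_j = -1, best_h = -1;
    for (int j = 0; j < k; ++j) {
      arma::ivec cand = medoids;
      for (int h = 0; h < n; ++h) {
        if (is_med[h]) continue;
        cand[j] = h;
        double c = total_cost(cand);
        double delta = c - cost;
        if (delta < best_delta) { best_delta = delta; best_j = j; best_h = h; }
      }
      cand[j] = medoids[j];
    }
    if (best_j < 0) break;
    is_med[medoids[best_j]] = false;
    medoids[best_j] = best_h;
    is_med[best_h] = true;
    cost += best_delta;
  }

  // final assignment: nearest medoid, ties to the lowest medoid index;
  // a medoid always belongs to its own group
  std::vector<int> med_of(n, -1);
  for (int j = 0; j < k; ++j) med_of[medoids[j]] = j;
  arma::ivec assign(n);
  for (int i = 0; i < n; ++i) {
    if (med_of[i] >= 0) { assign[i] = med_of[i]; continue; }
    double best = std::numeric_limits<double>::infinity();
    int bj = 0;
    for (int j = 0; j < k; ++j) {
      if (D(i, medoids[j]) < best) { best = D(i, medoids[j]); bj = j; }
    }
    assign[i] = bj;
  }
  return List::create(_["medoids"] = medoids, _["assignments"] = assign,
                      _["cost"] = total_cost(medoids));
}
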