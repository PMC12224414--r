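#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Nonincreasing PAVA, as in pava.cpp, on an arma vector.
static vec pava_nonincr(const vec &z) {
  int m = z.n_elem;
  std::vector<double> mean(m), wt(m);
  std::vector<int> last(m);
  int nb = 0;
  for (int i = 0; i < m; ++i) {
    mean[nb] = z[i];
    wt[nb] = 1.0;
    last[nb] = i;
    ++nb;
    while (nb > 1 && mean[nb - 2] < mean[nb - 1]) {
      double w = wt[nb - 2] + wt[nb - 1];
      mean[nb - 2] = (wt[nb - 2] * mean[nb - 2] + wt[nb - 1] * mean[nb - 1]) / w;
      wt[nb - 2] = w;
      last[nb - 2] = last[nb - 1];
      --nb;
    }
  }
  vec out(m);
  int i = 0;
  for (int b = 0; b < nb; ++b)
    for (; i <= last[b]; ++i) out[i] = mean[b];
  return out;
}

// grOWL prox: ordered-weighted-L1 prox on the row norms, rows rescaled.
static mat prox_growl_cpp(const mat &V, const vec &tw) {
  vec v = sqrt(sum(square(V), 1));
  uvec ord = sort_index(v, "descend");
  vec z = v(ord) - tw;
  vec x = pava_nonincr(z);
  x.clamp(0.0, datum::inf);
  vec nrm(v.n_elem);
  nrm(ord) = x;
  mat out(V.n_rows, V.n_cols, fill::zeros);
  for (uword i = 0; i < V.n_rows; ++i) {
    if (nrm[i] > 0 && v[i] > 0) out.row(i) = V.row(i) * (nrm[i] / v[i]);
  }
  return out;
}

static mat prox_lasso_cpp(const mat &V, double t) {
  return sign(V) % clamp(abs(V) - t, 0.0, datum::inf);
}

static double penalty(const mat &B, int family, double alpha, const vec &w) {
  if (alpha == 0.0) return 0.0;
  if (family == 1) return alpha * accu(abs(B));
  vec rho = sort(sqrt(sum(square(B), 1)), "descend");
  return alpha * dot(w, rho);
}

// FISTA with fixed step 1/L, monotone (objective) adaptive restart,
// zero initialization; stops on relative objective change < tol.
// family: 0 = grOWL, 1 = lasso.
// [[Rcpp::export]]
Rcpp::List fista_solve(const arma::mat &X, const arma::mat &U,
                       const arma::vec &weights, double alpha, int family,
                       double step, int max_iter, double tol,
                       bool keep_objective) {
  const int n = X.n_rows, m = X.n_cols, r = U.n_cols;
  mat beta(m, r, fill::zeros), y(m, r, fill::zeros);
  mat XtU = X.t() * U / n;
  vec tw = step * alpha * weights;
  double t_k = 1.0;
  auto objective = [&](const mat &B) {
    return accu(square(U - X * B)) / (2.0 * n) + penalty(B, family, alpha, weights);
  };
  auto prox = [&](const mat &V) {
    return family == 1 ? prox_lasso_cpp(V, step * alpha) : prox_growl_cpp(V, tw);
  };
  double obj = objective(beta);
  std::vector<double> trace;
  if (keep_objective) trace.push_back(obj);
  bool converged = false;
  int iter = 0, restarts = 0;
  double rel_change = datum::inf;
  for (iter = 1; iter <= max_iter; ++iter) {
    mat grad = X.t() * (X * y) / n - XtU;
    mat beta_new = prox(y - step * grad);
    double obj_new = objective(beta_new);
    if (obj_new > obj) {
      ++restarts;
      t_k = 1.0;
      y = beta;
      grad = X.t() * (X * y) / n - XtU;
      beta_new = prox(y - step * grad);
      obj_new = objective(beta_new);
    }
    double t_new = (1.0 + std::sqrt(1.0 + 4.0 * t_k * t_k)) / 2.0;
    y = beta_new + ((t_k - 1.0) / t_new) * (beta_new - beta);
    rel_change = std::abs(obj - obj_new) /
      std::max(std::abs(obj), datum::eps);
    beta = beta_new;
    t_k = t_new;
    obj = obj_new;
    if (keep_objective) trace.push_back(obj);
    if (rel_change < tol) {
      converged = true;
      break;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("iterations") = std::min(iter, max_iter),
    Rcpp::Named("restarts") = restarts,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("rel_change") = rel_change,
    Rcpp::Named("objective_trace") = trace);
}
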