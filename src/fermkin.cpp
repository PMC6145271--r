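// Compiled core: right-hand side of the six-state fermentation model,
// orthogonal collocation on finite elements (Gauss implicit Runge-Kutta
// form with simplified Newton), and the Gaussian log-likelihood used by
// the Metropolis-within-Gibbs sampler.
//
// Parameter vector layout (length 20), fixed across the package:
//   0..11  k1..k12
//   12     cor_bio    13 cor_NPN    14 cor_X
//   15     y1_max     16 y4_max     17 y5_max
//   18     frac_bio = N_bio*AW_N/MW_bio   19 frac_npn = N_NPN*AW_N/MW_NPN

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int NS = 6; // number of state variables

static inline void rhs_core(double t, const double* y, const vec& p, double* dy) {
  const double lag = 1.0 - std::exp(-p[2] * t);
  const double mu  = lag * p[0] * y[1] / (p[1] + y[1]);
  const double dy1 = mu * y[0] * (1.0 - y[0] / p[15]) - p[11] * y[0];
  const double a   = p[12] * p[18];
  const double b   = p[13] * p[19];
  const double dy2 = -(a * dy1 + b * p[4] * y[1] + p[14] * y[1]) / (1.0 - b * p[3]);
  dy[0] = dy1;
  dy[1] = dy2;
  dy[2] = -p[3] * dy2 + p[4] * y[1];
  dy[3] =  p[5] * dy1 + p[6] * (1.0 - y[3] / p[16]);
  dy[4] =  p[7] * dy1 + p[8] * (1.0 - y[4] / p[17]);
  dy[5] = -p[9] * dy1 - p[10] * (1.0 - y[3] / p[16]);
}

// Finite-difference Jacobian of the rhs at (t, y).
static void fd_jacobian(double t, const vec& y, const vec& p, mat& J) {
  vec f0(NS), f1(NS), yy = y;
  rhs_core(t, y.memptr(), p, f0.memptr());
  for (int j = 0; j < NS; ++j) {
    const double eps = 1e-7 * (1.0 + std::fabs(y[j]));
    yy[j] = y[j] + eps;
    rhs_core(t, yy.memptr(), p, f1.memptr());
    J.col(j) = (f1 - f0) / eps;
    yy[j] = y[j];
  }
}

// Advance the collocation solution over all elements; fill dense output at
// t_out (sorted, within [t_ends.front(), t_ends.back()]). Returns false on
// Newton failure. Stage information is stored when stage_* are non-null.
static bool colloc_run(const vec& y0, const vec& p, const vec& t_ends,
                       const vec& cn, const mat& A, const vec& bw,
                       const mat& Vinv, const vec& t_out,
                       double tol, int max_iter,
                       mat& out,
                       vec* stage_time, mat* stage_y, mat* stage_f,
                       mat* elem_y0) {
  const int s = (int) cn.n_elem;
  const int n_el = (int) t_ends.n_elem - 1;
  const int n_out = (int) t_out.n_elem;
  const int n = NS * s;
  vec y_cur = y0;
  mat J(NS, NS), M(n, n), L, U, P;
  mat Y(NS, s), F(NS, s);
  vec f0(NS), resid(n), delta(n);
  vec theta_pow(s), w(s);
  int idx = 0;
  // the iteration matrix I - h*(A (x) J) is refactored lazily: it is kept
  // across elements (uniform grid, slowly varying Jacobian) until Newton
  // convergence degrades
  bool have_fact = false;

  for (int m = 0; m < n_el; ++m) {
    const double tm = t_ends[m];
    const double h  = t_ends[m + 1] - tm;
    rhs_core(tm, y_cur.memptr(), p, f0.memptr());
    if (!f0.is_finite()) return false;
    for (int j = 0; j < s; ++j) Y.col(j) = y_cur + (cn[j] * h) * f0;

    const double tol_abs = tol * (1.0 + norm(y_cur, "inf"));
    bool converged = false;
    int refresh_left = 2;
    double nr_prev = datum::inf;
    for (int it = 0; it < 2 * max_iter; ++it) {
      for (int j = 0; j < s; ++j)
        rhs_core(tm + cn[j] * h, Y.colptr(j), p, F.colptr(j));
      double nr = 0.0;
      for (int j = 0; j < s; ++j) {
        for (int i = 0; i < NS; ++i) {
          double acc = 0.0;
          for (int k = 0; k < s; ++k) acc += A(j, k) * F(i, k);
          const double r = Y(i, j) - y_cur[i] - h * acc;
          resid[j * NS + i] = r;
          const double ar = std::fabs(r);
          if (ar > nr) nr = ar;
        }
      }
      if (!std::isfinite(nr)) return false;
      if (nr < tol_abs) { converged = true; break; }
      const bool stalling = (it >= 2 && nr > 0.25 * nr_prev);
      nr_prev = nr;
      if (!have_fact || it == 0 || (stalling && refresh_left > 0)) {
        fd_jacobian(tm + 0.5 * h, y_cur, p, J);
        for (int j = 0; j < s; ++j)
          for (int k = 0; k < s; ++k) {
            mat blk = -(h * A(j, k)) * J;
            if (j == k) blk.diag() += 1.0;
            M.submat(j * NS, k * NS, (j + 1) * NS - 1, (k + 1) * NS - 1) = blk;
          }
        if (!lu(L, U, P, M)) return false;
        have_fact = true;
        if (stalling) --refresh_left;
      }
      delta = solve(trimatu(U), solve(trimatl(L), P * resid));
      if (!delta.is_finite()) return false;
      for (int j = 0; j < s; ++j)
        Y.col(j) -= delta.subvec(j * NS, (j + 1) * NS - 1);
      if (it == 2 * max_iter - 1) return false;
    }
    if (!converged) return false;

    // dense output inside this element via the collocation polynomial:
    // y(tm + theta*h) = y_cur + h * sum_k w_k(theta) F_k, where the weights
    // solve sum_k w_k c_k^(q-1) = theta^q / q, q = 1..s.
    while (idx < n_out && t_out[idx] <= t_ends[m + 1] + 1e-12 * (1.0 + std::fabs(t_ends[m + 1]))) {
      const double theta = (t_out[idx] - tm) / h;
      double tp = theta;
      for (int q = 0; q < s; ++q) { theta_pow[q] = tp / (q + 1.0); tp *= theta; }
      w = Vinv * theta_pow;
      out.row(idx) = (y_cur + h * (F * w)).t();
      ++idx;
    }

    if (stage_time) {
      elem_y0->row(m) = y_cur.t();
      for (int j = 0; j < s; ++j) {
        (*stage_time)[m * s + j] = tm + cn[j] * h;
        stage_y->row(m * s + j) = Y.col(j).t();
        stage_f->row(m * s + j) = F.col(j).t();
      }
    }
    y_cur += h * (F * bw);
  }
  return idx == n_out;
}

// [[Rcpp::export]]
Rcpp::NumericVector rhs_cpp(double t, Rcpp::NumericVector y, Rcpp::NumericVector p) {
  vec pp(p.begin(), p.size());
  Rcpp::NumericVector dy(NS);
  rhs_core(t, y.begin(), pp, dy.begin());
  return dy;
}

// [[Rcpp::export]]
Rcpp::List colloc_simulate_cpp(Rcpp::NumericVector y0, Rcpp::NumericVector p,
                               Rcpp::NumericVector t_ends, Rcpp::NumericVector c_nodes,
                               Rcpp::NumericMatrix A, Rcpp::NumericVector b,
                               Rcpp::NumericMatrix Vinv, Rcpp::NumericVector t_out,
                               double tol, int max_iter, bool want_stages) {
  vec y0v(y0.begin(), y0.size());
  vec pv(p.begin(), p.size());
  vec te(t_ends.begin(), t_ends.size());
  vec cn(c_nodes.begin(), c_nodes.size());
  mat Am(A.begin(), A.nrow(), A.ncol());
  vec bv(b.begin(), b.size());
  mat Vi(Vinv.begin(), Vinv.nrow(), Vinv.ncol());
  vec to(t_out.begin(), t_out.size());

  const int s = (int) cn.n_elem, n_el = (int) te.n_elem - 1;
  mat out(to.n_elem, NS);
  vec st_time(want_stages ? n_el * s : 0);
  mat st_y(want_stages ? n_el * s : 0, NS), st_f(want_stages ? n_el * s : 0, NS);
  mat el_y0(want_stages ? n_el : 0, NS);

  bool ok = colloc_run(y0v, pv, te, cn, Am, bv, Vi, to, tol, max_iter, out,
                       want_stages ? &st_time : nullptr,
                       want_stages ? &st_y : nullptr,
                       want_stages ? &st_f : nullptr,
                       want_stages ? &el_y0 : nullptr);
  return Rcpp::List::create(
    Rcpp::Named("states") = out,
    Rcpp::Named("converged") = ok,
    Rcpp::Named("stage_time") = st_time,
    Rcpp::Named("stage_y") = st_y,
    Rcpp::Named("stage_f") = st_f,
    Rcpp::Named("elem_y0") = el_y0);
}

// Gaussian log-likelihood of observations against the collocation solution.
// obs_row: 0-based index into t_out; obs_col: 0-based state index.
// Returns -Inf when the solver fails (draw rejected by the sampler).
// [[Rcpp::export]]
double colloc_loglik_cpp(Rcpp::NumericVector y0, Rcpp::NumericVector p,
                         Rcpp::NumericVector t_ends, Rcpp::NumericVector c_nodes,
                         Rcpp::NumericMatrix A, Rcpp::NumericVector b,
                         Rcpp::NumericMatrix Vinv, Rcpp::NumericVector t_out,
                         Rcpp::IntegerVector obs_row, Rcpp::IntegerVector obs_col,
                         Rcpp::NumericVector obs_val, Rcpp::NumericVector obs_sd,
                         double tol, int max_iter) {
  vec y0v(y0.begin(), y0.size());
  vec pv(p.begin(), p.size());
  vec te(t_ends.begin(), t_ends.size());
  vec cn(c_nodes.begin(), c_nodes.size());
  mat Am(A.begin(), A.nrow(), A.ncol());
  vec bv(b.begin(), b.size());
  mat Vi(Vinv.begin(), Vinv.nrow(), Vinv.ncol());
  vec to(t_out.begin(), t_out.size());

  mat out(to.n_elem, NS);
  bool ok = colloc_run(y0v, pv, te, cn, Am, bv, Vi, to, tol, max_iter, out,
                       nullptr, nullptr, nullptr, nullptr);
  if (!ok) return R_NegInf;

  double ll = 0.0;
  const int n = obs_row.size();
  for (int i = 0; i < n; ++i) {
    const double pred = out(obs_row[i], obs_col[i]);
    const double z = (obs_val[i] - pred) / obs_sd[i];
    ll += -0.5 * z * z - std::log(obs_sd[i]);
  }
  if (!std::isfinite(ll)) return R_NegInf;
  return ll;
}
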