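#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>
using namespace Rcpp;

// SMO for the epsilon-SVR dual:
//   max  sum_i y_i b_i - eps * sum_i |b_i| - 1/2 b' K b,   b_i = a_i - a*_i
//   s.t. sum_i b_i = 0,  a_i, a*_i in [0, C]
// worked on the split variables (a, a*). Each step pairs one feasible move
// that raises sum(b) with one that lowers it and solves the two-variable
// subproblem exactly. The raising move is the maximal KKT violator; its
// partner is chosen by second-order gain (violation^2 / curvature). Clearly
// non-violating bound points are periodically shrunk out of the working set
// and the full problem is re-checked (and re-activated) before convergence is
// declared, so the returned solution satisfies the KKT conditions on every
// point. The KKT stopping test is the maximal-violating-pair gap; u = K b is
// kept incrementally over the active set.
//
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double eps,
               double tol, int max_iter,
               Nullable<NumericVector> a_init = R_NilValue,
               Nullable<NumericVector> as_init = R_NilValue) {
  const int n = y.size();
  if (K.nrow() != n || K.ncol() != n)
    stop("kernel matrix dimensions do not match the target vector");
  std::vector<double> a(n, 0.0), as(n, 0.0), u(n, 0.0);

  if (a_init.isNotNull() && as_init.isNotNull()) {
    NumericVector a0(a_init), as0(as_init);
    if (a0.size() == n && as0.size() == n) {
      // clip the warm start into the (possibly smaller) box, then restore the
      // equality constraint by bleeding the drift out of interior variables
      for (int i = 0; i < n; ++i) {
        a[i] = std::min(std::max(a0[i], 0.0), C);
        as[i] = std::min(std::max(as0[i], 0.0), C);
      }
      double drift = std::accumulate(a.begin(), a.end(), 0.0) -
                     std::accumulate(as.begin(), as.end(), 0.0);
      for (int i = 0; i < n && std::fabs(drift) > 1e-12; ++i) {
        double *v = drift > 0 ? &a[i] : &as[i];
        const double take = std::min(std::fabs(drift), *v);
        *v -= take;
        drift += drift > 0 ? -take : take;
      }
      for (int i = 0; i < n; ++i) {
        const double bi = a[i] - as[i];
        if (bi != 0.0)
          for (int k = 0; k < n; ++k) u[k] += bi * K(k, i);
      }
    }
  }

  const double* Kp = &K(0, 0);  // column-major; column c starts at Kp + c*n
  std::vector<double> Kd(n);
  for (int i = 0; i < n; ++i) Kd[i] = Kp[(size_t)i * n + i];

  std::vector<int> active(n);
  std::iota(active.begin(), active.end(), 0);
  const int shrink_every = std::max(100, std::min(n, 1000));
  int shrink_counter = shrink_every;

  auto reconstruct_u = [&]() {
    std::fill(u.begin(), u.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double bj = a[j] - as[j];
      if (bj != 0.0) {
        const double* col = Kp + (size_t)j * n;
        for (int k = 0; k < n; ++k) u[k] += bj * col[k];
      }
    }
  };

  int iter = 0;
  double gap = R_PosInf;
  const double neg_inf = -std::numeric_limits<double>::infinity();
  const double tau = 1e-12;

  for (iter = 0; iter < max_iter; ++iter) {
    // gradients: d/da_i = y_i - eps - u_i, d/da*_i = -y_i - eps + u_i
    double best_plus = neg_inf, best_minus = neg_inf;
    int ip = -1, im = -1, tp = 0, tm = 0;  // type 0: alpha move, 1: alpha* move
    for (int idx = (int)active.size() - 1; idx >= 0; --idx) {
      const int i = active[idx];
      const double Ga = y[i] - eps - u[i];
      const double Gs = -y[i] - eps + u[i];
      // raise sum(b): increase a_i, or decrease a*_i
      if (a[i] < C && Ga > best_plus) { best_plus = Ga; ip = i; tp = 0; }
      if (as[i] > 0.0 && -Gs > best_plus) { best_plus = -Gs; ip = i; tp = 1; }
      // lower sum(b): increase a*_i, or decrease a_i
      if (as[i] < C && Gs > best_minus) { best_minus = Gs; im = i; tm = 1; }
      if (a[i] > 0.0 && -Ga > best_minus) { best_minus = -Ga; im = i; tm = 0; }
    }
    gap = best_plus + best_minus;

    if (!(gap > tol)) {
      if ((int)active.size() == n) break;  // optimal on the full problem
      // re-activate everything and re-check before declaring convergence
      reconstruct_u();
      active.resize(n);
      std::iota(active.begin(), active.end(), 0);
      shrink_counter = shrink_every;
      continue;
    }

    if (--shrink_counter == 0) {
      shrink_counter = shrink_every;
      // drop bound points that cannot pair with the current best movers
      std::vector<int> keep;
      keep.reserve(active.size());
      for (int idx = 0; idx < (int)active.size(); ++idx) {
        const int i = active[idx];
        if (i == ip || i == im) { keep.push_back(i); continue; }
        const double Ga = y[i] - eps - u[i];
        const double Gs = -y[i] - eps + u[i];
        double g_up = neg_inf, g_dn = neg_inf;
        if (a[i] < C) g_up = std::max(g_up, Ga);
        if (as[i] > 0.0) g_up = std::max(g_up, -Gs);
        if (as[i] < C) g_dn = std::max(g_dn, Gs);
        if (a[i] > 0.0) g_dn = std::max(g_dn, -Ga);
        const bool interior = (a[i] > 0.0 && a[i] < C) ||
                              (as[i] > 0.0 && as[i] < C);
        if (interior || g_up > -best_minus || g_dn > -best_plus) {
          keep.push_back(i);
        }
      }
      if (keep.size() >= 2) active.swap(keep);
    }

    // second-order choice of the lowering move, given the raiser ip
    const double Kii = Kd[ip];
    const double* col_ip = Kp + (size_t)ip * n;  // K(., ip) = K(ip, .) by symmetry
    double best_gain = neg_inf;
    for (int idx = (int)active.size() - 1; idx >= 0; --idx) {
      const int j = active[idx];
      const double Ga = y[j] - eps - u[j];
      const double Gs = -y[j] - eps + u[j];
      double eta = Kii + Kd[j] - 2.0 * col_ip[j];
      if (j == ip || eta < tau) eta = tau;
      if (as[j] < C) {
        const double viol = best_plus + Gs;
        if (viol > 0) {
          const double gain = viol * viol / eta;
          if (gain > best_gain) { best_gain = gain; im = j; tm = 1; }
        }
      }
      if (a[j] > 0.0) {
        const double viol = best_plus - Ga;
        if (viol > 0) {
          const double gain = viol * viol / eta;
          if (gain > best_gain) { best_gain = gain; im = j; tm = 0; }
        }
      }
    }

    const int i = ip, j = im;
    const double gain_minus = (tm == 1) ? (-y[j] - eps + u[j])
                                        : -(y[j] - eps - u[j]);
    const double step_gap = best_plus + gain_minus;
    const double lim_plus = (tp == 0) ? (C - a[i]) : as[i];
    const double lim_minus = (tm == 1) ? (C - as[j]) : a[j];
    double dmax = std::min(lim_plus, lim_minus);
    if (dmax <= 0.0) break;  // numerically stuck; report gap as-is

    double d;
    if (i == j) {
      // same-index pair leaves b unchanged: objective is linear in the step
      d = dmax;
    } else {
      const double eta = Kd[i] + Kd[j] - 2.0 * Kp[(size_t)i * n + j];
      d = (eta > 1e-14) ? std::min(step_gap / eta, dmax) : dmax;
    }

    if (tp == 0) a[i] += d; else as[i] -= d;
    if (tm == 1) as[j] += d; else a[j] -= d;
    a[i] = std::min(std::max(a[i], 0.0), C);
    as[i] = std::min(std::max(as[i], 0.0), C);
    a[j] = std::min(std::max(a[j], 0.0), C);
    as[j] = std::min(std::max(as[j], 0.0), C);
    if (i != j) {
      const double* col_i = Kp + (size_t)i * n;
      const double* col_j = Kp + (size_t)j * n;
      for (int idx = (int)active.size() - 1; idx >= 0; --idx) {
        const int k = active[idx];
        u[k] += d * (col_i[k] - col_j[k]);
      }
    }
  }

  if ((int)active.size() != n) reconstruct_u();

  // bias from free support vectors' KKT equalities, averaged; otherwise the
  // midpoint of the interval of biases consistent with the bound variables
  const double tolb = 1e-8 * C;
  double b_sum = 0.0;
  int n_free = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] > tolb && a[i] < C - tolb) { b_sum += y[i] - u[i] - eps; ++n_free; }
    if (as[i] > tolb && as[i] < C - tolb) { b_sum += y[i] - u[i] + eps; ++n_free; }
  }
  double b;
  if (n_free > 0) {
    b = b_sum / n_free;
  } else {
    double blo = neg_inf, bhi = std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
      if (a[i] <= tolb && as[i] <= tolb) {
        blo = std::max(blo, y[i] - u[i] - eps);
        bhi = std::min(bhi, y[i] - u[i] + eps);
      }
      if (a[i] >= C - tolb) bhi = std::min(bhi, y[i] - u[i] - eps);
      if (as[i] >= C - tolb) blo = std::max(blo, y[i] - u[i] + eps);
    }
    if (!std::isfinite(blo)) blo = std::isfinite(bhi) ? bhi : 0.0;
    if (!std::isfinite(bhi)) bhi = blo;
    b = 0.5 * (blo + bhi);
  }

  NumericVector beta(n), alpha(n), alphastar(n), uu(n);
  for (int i = 0; i < n; ++i) {
    alpha[i] = a[i];
    alphastar[i] = as[i];
    beta[i] = a[i] - as[i];
    uu[i] = u[i];
  }
  return List::create(
    _["beta"] = beta, _["alpha"] = alpha, _["alphastar"] = alphastar,
    _["b"] = b, _["u"] = uu, _["iterations"] = iter, _["gap"] = gap,
    _["converged"] = !(gap > tol), _["n_free"] = n_free);
}
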