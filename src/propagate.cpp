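// Core state propagator for voltage-clamp Markov-model simulation.
//
// The model is linear in the states, dx/dt = A(V(t)) x, and protocols are
// piecewise constant/linear in V.  On constant-voltage steps the solution is
// the matrix exponential, computed once per inter-observation interval and
// reused along the segment.  On ramps a 4th-order Magnus integrator (two
// Gauss nodes per step) is used; it is unconditionally stable, so stiff
// parameter proposals during optimisation cannot blow up the state.
//
// The hot path is templated on the (small) state count so all matrices live
// on the stack; models with more than MAXN states fall back to dynamic
// matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int MAXN = 8;

template <typename MatT>
static void rate_matrix_t(MatT &A, int n, const int *from, const int *to,
                          const int *kind, const double *a, const double *b,
                          int ntr, double V) {
  A.zeros();
  for (int i = 0; i < ntr; ++i) {
    double k;
    switch (kind[i]) {
    case 0: k = a[i]; break;                  // constant
    case 1: k = a[i] * std::exp(b[i] * V); break;   // exp_increasing
    default: k = a[i] * std::exp(-b[i] * V); break; // exp_decreasing
    }
    if (!std::isfinite(k))
      Rcpp::stop("non-finite transition rate at V = %f", V);
    A(to[i], from[i]) += k;
    A(from[i], from[i]) -= k;
  }
}

// scaling-and-squaring Taylor exponential; matrices here are tiny (<= 8x8)
// with moderate norms, where this beats a general-purpose Pade routine
template <typename MatT>
static MatT expm_small(const MatT &M) {
  double nrm = norm(M, "inf");
  if (!std::isfinite(nrm)) Rcpp::stop("non-finite rate matrix");
  int s = 0;
  if (nrm > 0.5) s = (int)std::ceil(std::log2(nrm / 0.5));
  MatT A = M / std::ldexp(1.0, s);
  MatT E = A;
  E.diag() += 1.0;
  MatT T = A;
  for (int k = 2; k <= 18; ++k) {
    T = (T * A) / k;
    E += T;
    if (norm(T, "inf") < 1e-17) break;
  }
  for (int i = 0; i < s; ++i) E = E * E;
  return E;
}

template <int N>
struct kernel {
  typedef typename mat::fixed<N, N> M;
  typedef typename vec::fixed<N> V;

  static void run(const ivec &from, const ivec &to, const ivec &kind,
                  const vec &a, const vec &b, const vec &x_init,
                  const Rcpp::NumericVector &seg_start,
                  const Rcpp::NumericVector &seg_end,
                  const Rcpp::NumericVector &seg_v0,
                  const Rcpp::NumericVector &seg_v1, const vec &tobs,
                  double ramp_substep, mat &out) {
    const int ntr = from.n_elem;
    const int *fr = from.memptr();
    const int *t_ = to.memptr();
    const int *kd = kind.memptr();
    const double *ap = a.memptr();
    const double *bp = b.memptr();
    const uword n_obs = tobs.n_elem;
    const double eps = 1e-9;

    V x;
    for (int i = 0; i < N; ++i) x[i] = x_init[i];
    M A, E, A1, A2, Om;

    uword iobs = 0;
    double t_cur = seg_start[0];
    while (iobs < n_obs && tobs[iobs] <= t_cur + eps) out.col(iobs++) = x;

    for (int s = 0; s < seg_start.size(); ++s) {
      const double t1 = seg_end[s];
      const bool is_ramp = std::abs(seg_v1[s] - seg_v0[s]) > 0;
      if (!is_ramp) {
        rate_matrix_t(A, N, fr, t_, kd, ap, bp, ntr, seg_v0[s]);
        double dt_cached = -1.0;
        while (iobs < n_obs && tobs[iobs] < t1 - eps) {
          double dt = tobs[iobs] - t_cur;
          if (dt > eps) {
            if (std::abs(dt - dt_cached) > eps) {
              E = expm_small<M>(A * dt);
              dt_cached = dt;
            }
            x = E * x;
            t_cur = tobs[iobs];
          }
          out.col(iobs++) = x;
        }
        if (t1 - t_cur > eps) x = expm_small<M>(A * (t1 - t_cur)) * x;
        t_cur = t1;
      } else {
        const double t0 = seg_start[s];
        const double slope = (seg_v1[s] - seg_v0[s]) / (t1 - t0);
        const double c1 = 0.5 - std::sqrt(3.0) / 6.0;
        const double c2 = 0.5 + std::sqrt(3.0) / 6.0;
        while (t_cur < t1 - eps) {
          double t_target = t1;
          bool at_obs = false;
          if (iobs < n_obs && tobs[iobs] < t1 - eps) {
            t_target = tobs[iobs];
            at_obs = true;
          }
          double span = t_target - t_cur;
          if (span > eps) {
            int m = (int)std::ceil(span / ramp_substep - 1e-12);
            if (m < 1) m = 1;
            double h = span / m;
            for (int j = 0; j < m; ++j) {
              double t = t_cur + j * h;
              rate_matrix_t(A1, N, fr, t_, kd, ap, bp, ntr,
                            seg_v0[s] + slope * (t + c1 * h - t0));
              rate_matrix_t(A2, N, fr, t_, kd, ap, bp, ntr,
                            seg_v0[s] + slope * (t + c2 * h - t0));
              Om = (h / 2.0) * (A1 + A2) +
                   (h * h * std::sqrt(3.0) / 12.0) * (A2 * A1 - A1 * A2);
              x = expm_small<M>(Om) * x;
            }
          }
          t_cur = t_target;
          if (at_obs) out.col(iobs++) = x;
          else break;
        }
        t_cur = t1;
      }
    }
    while (iobs < n_obs) out.col(iobs++) = x;
  }
};

// dynamic-size fallback, same algorithm
static void run_dyn(int n, const ivec &from, const ivec &to, const ivec &kind,
                    const vec &a, const vec &b, const vec &x_init,
                    const Rcpp::NumericVector &seg_start,
                    const Rcpp::NumericVector &seg_end,
                    const Rcpp::NumericVector &seg_v0,
                    const Rcpp::NumericVector &seg_v1, const vec &tobs,
                    double ramp_substep, mat &out) {
  const int ntr = from.n_elem;
  const uword n_obs = tobs.n_elem;
  const double eps = 1e-9;
  vec x = x_init;
  mat A(n, n), E, A1(n, n), A2(n, n), Om;

  uword iobs = 0;
  double t_cur = seg_start[0];
  while (iobs < n_obs && tobs[iobs] <= t_cur + eps) out.col(iobs++) = x;

  for (int s = 0; s < seg_start.size(); ++s) {
    const double t1 = seg_end[s];
    const bool is_ramp = std::abs(seg_v1[s] - seg_v0[s]) > 0;
    if (!is_ramp) {
      rate_matrix_t(A, n, from.memptr(), to.memptr(), kind.memptr(),
                    a.memptr(), b.memptr(), ntr, seg_v0[s]);
      double dt_cached = -1.0;
      while (iobs < n_obs && tobs[iobs] < t1 - eps) {
        double dt = tobs[iobs] - t_cur;
        if (dt > eps) {
          if (std::abs(dt - dt_cached) > eps) {
            E = expm_small<mat>(A * dt);
            dt_cached = dt;
          }
          x = E * x;
          t_cur = tobs[iobs];
        }
        out.col(iobs++) = x;
      }
      if (t1 - t_cur > eps) x = expm_small<mat>(A * (t1 - t_cur)) * x;
      t_cur = t1;
    } else {
      const double t0 = seg_start[s];
      const double slope = (seg_v1[s] - seg_v0[s]) / (t1 - t0);
      const double c1 = 0.5 - std::sqrt(3.0) / 6.0;
      const double c2 = 0.5 + std::sqrt(3.0) / 6.0;
      while (t_cur < t1 - eps) {
        double t_target = t1;
        bool at_obs = false;
        if (iobs < n_obs && tobs[iobs] < t1 - eps) {
          t_target = tobs[iobs];
          at_obs = true;
        }
        double span = t_target - t_cur;
        if (span > eps) {
          int m = (int)std::ceil(span / ramp_substep - 1e-12);
          if (m < 1) m = 1;
          double h = span / m;
          for (int j = 0; j < m; ++j) {
            double t = t_cur + j * h;
            rate_matrix_t(A1, n, from.memptr(), to.memptr(), kind.memptr(),
                          a.memptr(), b.memptr(), ntr,
                          seg_v0[s] + slope * (t + c1 * h - t0));
            rate_matrix_t(A2, n, from.memptr(), to.memptr(), kind.memptr(),
                          a.memptr(), b.memptr(), ntr,
                          seg_v0[s] + slope * (t + c2 * h - t0));
            Om = (h / 2.0) * (A1 + A2) +
                 (h * h * std::sqrt(3.0) / 12.0) * (A2 * A1 - A1 * A2);
            x = expm_small<mat>(Om) * x;
          }
        }
        t_cur = t_target;
        if (at_obs) out.col(iobs++) = x;
        else break;
      }
      t_cur = t1;
    }
  }
  while (iobs < n_obs) out.col(iobs++) = x;
}

// [[Rcpp::export(name = ".propagate_cpp")]]
Rcpp::NumericMatrix propagate_cpp(int n_states,
                                  Rcpp::IntegerVector trans_from,
                                  Rcpp::IntegerVector trans_to,
                                  Rcpp::IntegerVector trans_kind,
                                  Rcpp::NumericVector trans_a,
                                  Rcpp::NumericVector trans_b,
                                  Rcpp::NumericVector x_init,
                                  Rcpp::NumericVector seg_start,
                                  Rcpp::NumericVector seg_end,
                                  Rcpp::NumericVector seg_v0,
                                  Rcpp::NumericVector seg_v1,
                                  Rcpp::NumericVector obs_times,
                                  double ramp_substep) {
  ivec from = Rcpp::as<ivec>(trans_from);
  ivec to = Rcpp::as<ivec>(trans_to);
  ivec kind = Rcpp::as<ivec>(trans_kind);
  vec a = Rcpp::as<vec>(trans_a);
  vec b = Rcpp::as<vec>(trans_b);
  vec x0 = Rcpp::as<vec>(x_init);
  vec tobs = Rcpp::as<vec>(obs_times);
  mat out(n_states, tobs.n_elem);

  switch (n_states) {
  case 1: kernel<1>::run(from, to, kind, a, b, x0, seg_start, seg_end,
                         seg_v0, seg_v1, tobs, ramp_substep, out); break;
  case 2: kernel<2>::run(from, to, kind, a, b, x0, seg_start, seg_end,
                         seg_v0, seg_v1, tobs, ramp_substep, out); break;
  case 3: kernel<3>::run(from, to, kind, a, b, x0, seg_start, seg_end,
                         seg_v0, seg_v1, tobs, ramp_substep, out); break;
  case 4: kernel<4>::run(from, to, kind, a, b, x0, seg_start, seg_end,
                         seg_v0, seg_v1, tobs, ramp_substep, out); break;
  case 5: kernel<5>::run(from, to, kind, a, b, x0, seg_start, seg_end,
                         seg_v0, seg_v1, tobs, ramp_substep, out); break;
  case 6: kernel<6>::run(from, to, kind, a, b, x0, seg_start, seg_end,
                         seg_v0, seg_v1, tobs, ramp_substep, out); break;
  default:
    run_dyn(n_states, from, to, kind, a, b, x0, seg_start, seg_end,
            seg_v0, seg_v1, tobs, ramp_substep, out);
  }
  return Rcpp::wrap(out.t());
}
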