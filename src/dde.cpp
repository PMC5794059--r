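// Method-of-steps integration of delay differential equations with a single
// constant delay.  Fixed-step classical RK4; delayed states come from cubic
// Hermite interpolation of the stored solution (or from the initial history
// for arguments before t = 0).  A ring buffer holds the last ceil(tau/h)+2
// grid points so memory stays bounded for long colony runs; the returned
// trajectory is thinned to `save_every` steps with derivatives retained for
// dense evaluation on the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// uniform-grid ring buffer of (y, f) pairs indexed by step number
struct Ring {
  int dim, cap;
  long lo;  // smallest step index currently stored
  long hi;  // largest
  bool empty;
  std::vector<double> y, f;

  Ring(int dim_, int cap_) : dim(dim_), cap(cap_), lo(0), hi(-1), empty(true),
                             y((size_t)cap_ * dim_), f((size_t)cap_ * dim_) {}

  double* yslot(long n) { return &y[(size_t)(((n % cap) + cap) % cap) * dim]; }
  double* fslot(long n) { return &f[(size_t)(((n % cap) + cap) % cap) * dim]; }

  void push(long n, const double* yv, const double* fv) {
    std::copy(yv, yv + dim, yslot(n));
    std::copy(fv, fv + dim, fslot(n));
    if (empty) { lo = n; empty = false; }
    hi = std::max(hi, n);
    if (hi - lo + 1 > cap) lo = hi - cap + 1;
  }

  // cubic Hermite interpolation at s = (n_lo + theta) * h, theta in [0,1]
  void interp(double s, double h, double* out) {
    double u = s / h;
    long j = (long)std::floor(u + 1e-12);
    if (j >= hi) j = hi - 1;
    if (j < lo) j = lo;
    double theta = u - (double)j;
    if (theta < 0) theta = 0;
    if (theta > 1) theta = 1;
    const double* y0 = yslot(j);
    const double* f0 = fslot(j);
    const double* y1 = yslot(j + 1);
    const double* f1 = fslot(j + 1);
    double t2 = theta * theta, t3 = t2 * theta;
    double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + theta;
    double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
    for (int i = 0; i < dim; ++i)
      out[i] = h00 * y0[i] + h * h10 * f0[i] + h01 * y1[i] + h * h11 * f1[i];
  }
};

inline int light_at(double t, const std::vector<double>& st,
                    const std::vector<int>& sc) {
  int cond = sc.empty() ? 0 : sc[0];
  for (size_t i = 0; i < st.size(); ++i) {
    if (st[i] <= t + 1e-12) cond = sc[i]; else break;
  }
  return cond;
}

// oscillator parameter order shared with R/params.R (see osc_par_order)
enum { P_CA, P_CI, P_DELTA, P_ALPHA, P_K1, P_TAU, P_GA, P_GI, P_GH,
       P_F, P_G, P_K, P_B, P_D, P_D0, P_DMEM, P_MU, P_D1, P_GTC, P_NOSC };
// channel parameter order (see chan_par_order)
enum { C_ATC, C_KTC, C_NTC, C_K, C_N1, C_GR, C_ACT, C_NCHAN };

struct ColonySystem {
  int n;                       // cells
  std::vector<int> model;      // 0 danino, 1 hotfm
  const double* op;
  const double* green;
  const double* uv;
  std::vector<double> sched_t;
  std::vector<int> sched_c;
  double inv_dx2, D1c;

  // y: n*6 state (A, I, Hi, He, R, TC per cell); ylag: full delayed state
  void rhs(double t, const double* y, const double* ylag, double* dy) const {
    const double CA = op[P_CA], CI = op[P_CI], delta = op[P_DELTA],
                 alpha = op[P_ALPHA], k1 = op[P_K1], gA = op[P_GA],
                 gI = op[P_GI], gH = op[P_GH], f = op[P_F], g = op[P_G],
                 k = op[P_K], b = op[P_B], d = op[P_D], d0 = op[P_D0],
                 Dm = op[P_DMEM], mu = op[P_MU], gTC = op[P_GTC];
    const double pref = 1.0 - std::pow(d / d0, 4.0);
    const double dfac = d / (1.0 - d);
    const int cond = light_at(t, sched_t, sched_c);

    for (int i = 0; i < n; ++i) {
      const double* yi = y + 6 * i;
      double* di = dy + 6 * i;
      const double A = yi[0], I = yi[1], Hi = yi[2], He = yi[3],
                   R = yi[4], TC = yi[5];
      const double Htau = ylag[6 * i + 2];
      const double P = delta + alpha * Htau * Htau / (1.0 + k1 * Htau * Htau);

      const int il = (i == 0) ? n - 1 : i - 1;
      const int ir = (i == n - 1) ? 0 : i + 1;
      const double lap = (n > 1)
        ? (y[6 * il + 3] - 2.0 * He + y[6 * ir + 3]) * inv_dx2 : 0.0;

      di[1] = CI * pref * P - gI * I / (1.0 + f * (A + I));
      di[2] = b * I / (1.0 + k * I) - gH * A * Hi / (1.0 + g * A)
              + Dm * (He - Hi);
      di[3] = -dfac * Dm * (He - Hi) - mu * He + D1c * lap;

      if (model[i] == 0) {
        di[0] = CA * pref * P - gA * A / (1.0 + f * (A + I));
        di[4] = 0.0;
        di[5] = 0.0;
      } else {
        const double* ch = green;
        double gate = 0.0;
        if (cond == (int)green[C_ACT]) { ch = green; gate = 1.0; }
        else if (cond == (int)uv[C_ACT]) { ch = uv; gate = 1.0; }
        const double Kr = ch[C_K], n1 = ch[C_N1];
        const double Kn = std::pow(Kr, n1);
        const double repf = Kn / (std::pow(R, n1) + Kn);
        const double TCn = std::pow(TC, ch[C_NTC]);
        const double act = (TCn > 0.0)
          ? ch[C_ATC] * TCn / (TCn + std::pow(ch[C_KTC], ch[C_NTC])) : 0.0;
        di[0] = CA * pref * P * repf - gA * A / (1.0 + f * (A + I));
        di[5] = CA * pref * P * repf - gTC * TC / (1.0 + f * (TC + I));
        di[4] = gate * pref * act - ch[C_GR] * R / (1.0 + f * R);
      }
    }
  }
};

}  // namespace

// Shared stepping loop for both entry points.  `Rhs` is a callable
// rhs(t, y, ylag, dy); `clamp` enables the nonnegativity projection used for
// concentration models.  `hist_y`/`hist_f` sample the initial history (and
// its derivative) on the uniform grid -m*h, ..., -h, 0; row m is the state
// at t = 0.
template <typename Rhs>
static List run_dde(Rhs rhs, int dim, const NumericMatrix& hist_y,
                    const NumericMatrix& hist_f,
                    double tau, double h, double t_final,
                    long save_every, bool clamp, double clamp_rel_tol) {
  const long N = (long)std::lround(t_final / h);
  if (N < 1) stop("t_final must allow at least one step");
  const long m = (long)std::ceil(tau / h - 1e-9);
  if (m < 1) stop("step must not exceed the delay tau");
  if (hist_y.nrow() != m + 1 || hist_y.ncol() != dim ||
      hist_f.nrow() != m + 1 || hist_f.ncol() != dim)
    stop("history must be sampled on %d grid points", (int)(m + 1));

  Ring ring(dim, (int)(m + 3));
  std::vector<double> y(dim), f0(dim), ylag(dim), ytmp(dim),
      k1(dim), k2(dim), k3(dim), k4(dim);
  std::vector<double> runmax(dim, 0.0);

  // delayed lookups before t = 0 interpolate the sampled history only;
  // the solution's derivative generally jumps at t = 0, so Hermite data
  // must never straddle it
  auto hist_interp = [&](double s, double* out) {
    double u = s / h + (double)m;  // position on history rows 0..m
    long j = (long)std::floor(u + 1e-12);
    if (j < 0) j = 0;
    if (j >= m) j = m - 1;
    double theta = u - (double)j;
    if (theta < 0) theta = 0;
    if (theta > 1) theta = 1;
    double t2 = theta * theta, t3 = t2 * theta;
    double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + theta;
    double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
    for (int i = 0; i < dim; ++i)
      out[i] = h00 * hist_y(j, i) + h * h10 * hist_f(j, i) +
               h01 * hist_y(j + 1, i) + h * h11 * hist_f(j + 1, i);
  };

  for (int i = 0; i < dim; ++i) y[i] = hist_y(m, i);
  hist_interp(-tau, ylag.data());
  rhs(0.0, y.data(), ylag.data(), f0.data());
  ring.push(0, y.data(), f0.data());
  if (clamp)
    for (int i = 0; i < dim; ++i) runmax[i] = std::max(0.0, y[i]);

  long n_out = N / save_every + 1 + (N % save_every ? 1 : 0);
  NumericVector out_t(n_out);
  NumericMatrix out_y(n_out, dim), out_f(n_out, dim);
  long row = 0;
  auto save = [&](long nn, const std::vector<double>& yv,
                  const std::vector<double>& fv) {
    out_t[row] = nn * h;
    for (int i = 0; i < dim; ++i) { out_y(row, i) = yv[i]; out_f(row, i) = fv[i]; }
    ++row;
  };
  save(0, y, f0);

  long n_clamped = 0;
  double worst = 0.0;

  for (long nn = 0; nn < N; ++nn) {
    const double t = nn * h;
    auto lag = [&](double s) {
      double sd = s - tau;
      if (sd < 0.0) hist_interp(sd, ylag.data());
      else ring.interp(sd, h, ylag.data());
    };

    // k1 is the stored derivative at the accepted point
    std::copy(ring.fslot(nn), ring.fslot(nn) + dim, k1.data());

    lag(t + h / 2);
    for (int i = 0; i < dim; ++i) ytmp[i] = y[i] + 0.5 * h * k1[i];
    rhs(t + h / 2, ytmp.data(), ylag.data(), k2.data());
    for (int i = 0; i < dim; ++i) ytmp[i] = y[i] + 0.5 * h * k2[i];
    rhs(t + h / 2, ytmp.data(), ylag.data(), k3.data());
    lag(t + h);
    for (int i = 0; i < dim; ++i) ytmp[i] = y[i] + h * k3[i];
    rhs(t + h, ytmp.data(), ylag.data(), k4.data());

    for (int i = 0; i < dim; ++i) {
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(y[i]))
        stop("non-finite state at t = %g (component %d); the system may be "
             "unstable at this step size", t + h, i + 1);
    }
    if (clamp) {
      for (int i = 0; i < dim; ++i) {
        if (y[i] < 0.0) {
          double thr = clamp_rel_tol * std::max(runmax[i], 1.0);
          if (-y[i] > thr) { ++n_clamped; worst = std::max(worst, -y[i]); }
          y[i] = 0.0;
        }
        if (y[i] > runmax[i]) runmax[i] = y[i];
      }
    }

    // derivative at the new accepted point (k1 of the next step)
    lag(t + h);  // ylag already holds lag(t+h); recompute defensively
    rhs(t + h, y.data(), ylag.data(), f0.data());
    ring.push(nn + 1, y.data(), f0.data());

    if ((nn + 1) % save_every == 0 || nn + 1 == N) save(nn + 1, y, f0);
    if (nn % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["time"] = out_t[Range(0, row - 1)],
                      _["state"] = out_y(Range(0, row - 1), _),
                      _["deriv"] = out_f(Range(0, row - 1), _),
                      _["n_clamped"] = (double)n_clamped,
                      _["worst_undershoot"] = worst);
}

//' @noRd
// [[Rcpp::export(name = ".dde_integrate_r")]]
List dde_integrate_r(Function rhs, NumericMatrix hist_y, NumericMatrix hist_f,
                     double tau, double h, double t_final, int save_every) {
  int dim = hist_y.ncol();
  auto call_rhs = [&](double t, const double* yv, const double* ylag,
                      double* dy) {
    NumericVector yy(yv, yv + dim), ll(ylag, ylag + dim);
    NumericVector res = rhs(t, yy, ll);
    if (res.size() != dim) stop("rhs returned wrong length");
    std::copy(res.begin(), res.end(), dy);
  };
  return run_dde(call_rhs, dim, hist_y, hist_f, tau, h, t_final, save_every,
                 false, 0.0);
}

//' @noRd
// [[Rcpp::export(name = ".colony_integrate_cpp")]]
List colony_integrate_cpp(NumericMatrix y0, IntegerVector model,
                          NumericVector op, NumericVector green,
                          NumericVector uv, NumericVector sched_t,
                          IntegerVector sched_c, double h, double t_final,
                          double dx, int save_every, double clamp_rel_tol) {
  const int n = y0.nrow();
  if (y0.ncol() != 6) stop("state matrix must have 6 species columns");
  if (op.size() != P_NOSC) stop("bad oscillator parameter vector");
  if (green.size() != C_NCHAN || uv.size() != C_NCHAN)
    stop("bad channel parameter vector");

  ColonySystem sys;
  sys.n = n;
  sys.model.assign(model.begin(), model.end());
  sys.op = REAL(op);
  sys.green = REAL(green);
  sys.uv = REAL(uv);
  sys.sched_t.assign(sched_t.begin(), sched_t.end());
  sys.sched_c.assign(sched_c.begin(), sched_c.end());
  sys.inv_dx2 = 1.0 / (dx * dx);
  sys.D1c = op[P_D1];

  // constant history equal to the initial state
  const long m = (long)std::ceil(op[P_TAU] / h - 1e-9);
  NumericMatrix hist_y(m + 1, n * 6), hist_f(m + 1, n * 6);
  for (long r = 0; r <= m; ++r)
    for (int i = 0; i < n; ++i)
      for (int s = 0; s < 6; ++s) hist_y(r, 6 * i + s) = y0(i, s);

  auto rhs = [&](double t, const double* yv, const double* ylag, double* dy) {
    sys.rhs(t, yv, ylag, dy);
  };
  return run_dde(rhs, n * 6, hist_y, hist_f, op[P_TAU], h, t_final, save_every,
                 true, clamp_rel_tol);
}

//' @noRd
// [[Rcpp::export(name = ".colony_rhs_cpp")]]
NumericVector colony_rhs_cpp(double t, NumericVector y, NumericVector ylag,
                             IntegerVector model, NumericVector op,
                             NumericVector green, NumericVector uv,
                             NumericVector sched_t, IntegerVector sched_c,
                             double dx) {
  const int n = model.size();
  if (y.size() != 6 * n || ylag.size() != 6 * n) stop("bad state length");
  ColonySystem sys;
  sys.n = n;
  sys.model.assign(model.begin(), model.end());
  sys.op = REAL(op);
  sys.green = REAL(green);
  sys.uv = REAL(uv);
  sys.sched_t.assign(sched_t.begin(), sched_t.end());
  sys.sched_c.assign(sched_c.begin(), sched_c.end());
  sys.inv_dx2 = 1.0 / (dx * dx);
  sys.D1c = op[P_D1];
  NumericVector dy(6 * n);
  sys.rhs(t, REAL(y), REAL(ylag), REAL(dy));
  return dy;
}
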