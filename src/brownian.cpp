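#include <Rcpp.h>
using namespace Rcpp;

// Overdamped (Brownian / Euler-Maruyama) integrator on a 2D periodic box.
//
// Pair potential between species a and b with centre distance r:
//   soft core   U_rep = k_rep * (1 - r/r0)^2            for r < r0
//   attraction  U_att = -eps * exp(-(r - r0)^2 / (2 s^2))  truncated at r0 + 3 s
// Forces are the analytic derivatives; kT = 1 so the mobility is D itself.
// Uses R's RNG so runs are reproducible from set.seed().

static inline double wrap_d(double d, double L) {
  d -= L * std::floor(d / L);
  if (d > L / 2.0) d -= L;
  return d;
}

// [[Rcpp::export(name = ".bd_simulate")]]
List bd_simulate(NumericVector x0, NumericVector y0, NumericVector th0,
                 IntegerVector sp, NumericVector D, NumericVector Dr,
                 NumericMatrix eps, NumericMatrix sigma, NumericMatrix r0,
                 double k_rep, NumericVector L,
                 double dt, int n_steps, int stride) {
  const int np = x0.size();
  const int nf = n_steps / stride + 1;
  const double Lx = L[0], Ly = L[1];

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> th(th0.begin(), th0.end());
  std::vector<double> fx(np), fy(np);
  std::vector<double> sdt(np), rdt(np), mob(np);
  for (int i = 0; i < np; ++i) {
    sdt[i] = std::sqrt(2.0 * D[i] * dt);
    rdt[i] = std::sqrt(2.0 * Dr[i] * dt);
    mob[i] = D[i] * dt;           // kT = 1
  }

  const int ns = eps.nrow();
  // squared interaction cutoffs per species pair
  NumericMatrix cut2(ns, ns);
  bool any_pair = false;
  for (int a = 0; a < ns; ++a)
    for (int b = 0; b < ns; ++b) {
      double rc = r0(a, b);
      if (eps(a, b) > 0.0) rc = std::max(rc, r0(a, b) + 3.0 * sigma(a, b));
      if (k_rep <= 0.0 && eps(a, b) <= 0.0) rc = 0.0;
      cut2(a, b) = rc * rc;
      if (rc > 0.0) any_pair = true;
    }

  NumericMatrix X(np, nf), Y(np, nf), TH(np, nf);
  int frame = 0;
  for (int i = 0; i < np; ++i) {
    X(i, 0) = x[i]; Y(i, 0) = y[i]; TH(i, 0) = th[i];
  }
  frame = 1;

  for (int step = 1; step <= n_steps; ++step) {
    if (any_pair) {
      std::fill(fx.begin(), fx.end(), 0.0);
      std::fill(fy.begin(), fy.end(), 0.0);
      for (int i = 0; i < np - 1; ++i) {
        const int si = sp[i];
        for (int j = i + 1; j < np; ++j) {
          const int sj = sp[j];
          const double c2 = cut2(si, sj);
          if (c2 <= 0.0) continue;
          double dx = wrap_d(x[j] - x[i], Lx);
          if (dx * dx > c2) continue;
          double dy = wrap_d(y[j] - y[i], Ly);
          double r2 = dx * dx + dy * dy;
          if (r2 > c2 || r2 < 1e-12) continue;
          double r = std::sqrt(r2);
          double f = 0.0;
          const double rr0 = r0(si, sj);
          if (k_rep > 0.0 && r < rr0)
            f += 2.0 * k_rep * (1.0 - r / rr0) / rr0;
          const double e = eps(si, sj);
          if (e > 0.0) {
            const double s = sigma(si, sj);
            const double u = r - rr0;
            if (u < 3.0 * s)
              f += -e * u / (s * s) * std::exp(-u * u / (2.0 * s * s));
          }
          const double fxp = f * dx / r, fyp = f * dy / r;
          fx[j] += fxp; fy[j] += fyp;
          fx[i] -= fxp; fy[i] -= fyp;
        }
      }
      for (int i = 0; i < np; ++i) {
        x[i] += mob[i] * fx[i] + sdt[i] * norm_rand();
        y[i] += mob[i] * fy[i] + sdt[i] * norm_rand();
        if (rdt[i] > 0.0) th[i] += rdt[i] * norm_rand();
      }
    } else {
      for (int i = 0; i < np; ++i) {
        x[i] += sdt[i] * norm_rand();
        y[i] += sdt[i] * norm_rand();
        if (rdt[i] > 0.0) th[i] += rdt[i] * norm_rand();
      }
    }
    for (int i = 0; i < np; ++i) {
      x[i] -= Lx * std::floor(x[i] / Lx);
      y[i] -= Ly * std::floor(y[i] / Ly);
    }
    if (step % stride == 0) {
      for (int i = 0; i < np; ++i) {
        X(i, frame) = x[i]; Y(i, frame) = y[i]; TH(i, frame) = th[i];
      }
      ++frame;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["theta"] = TH);
}
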