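// Mass-action kinetics backends: a 4(3) Rosenbrock (Kaps-Rentrop, Shampine
// parameter set) stiff integrator with analytic Jacobian, and an exact
// Gillespie direct-method SSA using R's RNG stream.
//
// Conventions: y is in nM, t in seconds, rate constants already converted
// to nM/s units (bimolecular: nM^-1 s^-1). Reactions have <= 2 reactants,
// encoded in `ri` (2 x nr, 0-based species index, -1 = absent). `S` is the
// ns x nr net stoichiometry matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void mass_action_rates(const arma::vec& y, const arma::imat& ri,
                              const arma::vec& k, arma::vec& v) {
  const int nr = k.n_elem;
  for (int r = 0; r < nr; ++r) {
    double rate = k[r];
    int a = ri(0, r), b = ri(1, r);
    if (a >= 0) rate *= y[a];
    if (b >= 0) rate *= y[b];
    v[r] = rate;
  }
}

static void mass_action_jac(const arma::vec& y, const arma::imat& ri,
                            const arma::vec& k, const arma::mat& S,
                            arma::mat& J) {
  J.zeros();
  const int nr = k.n_elem;
  for (int r = 0; r < nr; ++r) {
    int a = ri(0, r), b = ri(1, r);
    if (a < 0) continue;
    if (b < 0) {
      // v = k*y[a]; dv/dy[a] = k
      J.col(a) += k[r] * S.col(r);
    } else {
      J.col(a) += k[r] * y[b] * S.col(r);
      J.col(b) += k[r] * y[a] * S.col(r);
    }
  }
}

// Shampine's parameter set for the Kaps-Rentrop 4(3) Rosenbrock method.
static const double GAM = 0.5;
static const double A21 = 2.0, A31 = 48.0 / 25.0, A32 = 6.0 / 25.0;
static const double C21 = -8.0, C31 = 372.0 / 25.0, C32 = 12.0 / 5.0;
static const double C41 = -112.0 / 125.0, C42 = -54.0 / 125.0,
                    C43 = -2.0 / 5.0;
static const double B1 = 19.0 / 9.0, B2 = 0.5, B3 = 25.0 / 108.0,
                    B4 = 125.0 / 108.0;
static const double E1 = 17.0 / 54.0, E2 = 7.0 / 36.0, E3 = 0.0,
                    E4 = 125.0 / 108.0;

// [[Rcpp::export]]
arma::mat cpp_rosenbrock(const arma::mat& S, const arma::imat& ri,
                         const arma::vec& k, const arma::vec& y0,
                         double t0, const arma::vec& times,
                         double rtol, double atol,
                         int max_steps = 2000000) {
  const int ns = y0.n_elem, nr = k.n_elem, nt = times.n_elem;
  arma::mat out(nt, ns, arma::fill::zeros);
  arma::vec y = y0, v(nr), f(ns), f2(ns), f3(ns);
  arma::mat J(ns, ns), A(ns, ns);
  arma::vec g1(ns), g2(ns), g3(ns), g4(ns), y2(ns), y3(ns), err(ns), ynew(ns);

  double t = t0;
  int iout = 0;
  while (iout < nt && times[iout] <= t0 + 1e-300) {
    out.row(iout++) = y.t();
  }
  if (iout >= nt) return out;

  double h = std::min(1e-4, (times[nt - 1] - t0) / 100.0);
  if (h <= 0) h = 1e-6;
  int steps = 0;

  auto deriv = [&](const arma::vec& yy, arma::vec& ff) {
    mass_action_rates(yy, ri, k, v);
    ff = S * v;
  };

  while (iout < nt) {
    if (++steps > max_steps)
      stop("Rosenbrock integrator exceeded max_steps at t = %f s", t);
    double t_target = times[iout];
    if (t + h > t_target) h = t_target - t;
    bool accepted = false;
    while (!accepted) {
      deriv(y, f);
      mass_action_jac(y, ri, k, S, J);
      A = arma::eye(ns, ns) / (GAM * h) - J;
      arma::mat Ainv;
      bool ok = true;
      arma::mat g1m;
      // stage solves via LU (solve); fall back to smaller h on failure
      if (!arma::solve(g1, A, f, arma::solve_opts::fast)) ok = false;
      if (ok) {
        y2 = y + A21 * g1;
        deriv(y2, f2);
        if (!arma::solve(g2, A, f2 + C21 * g1 / h, arma::solve_opts::fast))
          ok = false;
      }
      if (ok) {
        y3 = y + A31 * g1 + A32 * g2;
        deriv(y3, f3);
        if (!arma::solve(g3, A, f3 + (C31 * g1 + C32 * g2) / h,
                         arma::solve_opts::fast))
          ok = false;
      }
      if (ok) {
        if (!arma::solve(g4, A, f3 + (C41 * g1 + C42 * g2 + C43 * g3) / h,
                         arma::solve_opts::fast))
          ok = false;
      }
      double errnorm = 0.0;
      if (ok) {
        ynew = y + B1 * g1 + B2 * g2 + B3 * g3 + B4 * g4;
        err = E1 * g1 + E2 * g2 + E3 * g3 + E4 * g4;
        for (int i = 0; i < ns; ++i) {
          double sc = atol + rtol * std::max(std::abs(y[i]), std::abs(ynew[i]));
          double e = std::abs(err[i]) / sc;
          if (e > errnorm) errnorm = e;
        }
        if (!ynew.is_finite()) ok = false;
      }
      if (ok && errnorm <= 1.0) {
        accepted = true;
        t += h;
        y = ynew;
        // clamp solver-scale negative excursions
        for (int i = 0; i < ns; ++i)
          if (y[i] < 0 && y[i] > -10.0 * atol) y[i] = 0.0;
        double fac = 0.9 * std::pow(std::max(errnorm, 1e-12), -0.25);
        h *= std::min(5.0, std::max(0.2, fac));
      } else {
        double fac = ok ? 0.9 * std::pow(errnorm, -1.0 / 3.0) : 0.1;
        h *= std::min(0.5, std::max(0.1, fac));
        if (h < 1e-14 * std::max(1.0, std::abs(t)))
          stop("Rosenbrock step size underflow at t = %f s", t);
      }
      if (++steps > max_steps)
        stop("Rosenbrock integrator exceeded max_steps at t = %f s", t);
    }
    while (iout < nt && t >= times[iout] - 1e-9 * std::max(1.0, times[iout])) {
      out.row(iout++) = y.t();
    }
    if (h <= 0 || !std::isfinite(h)) h = 1e-6;
  }
  return out;
}

// Exact SSA (direct method). `c` are stochastic rate constants per reaction
// (s^-1 units acting on copy numbers), `n0` initial copy numbers. Samples
// the state at `times` (piecewise-constant between events). Uses unif_rand
// so results are reproducible under set.seed().
// [[Rcpp::export]]
arma::mat cpp_ssa(const arma::mat& S, const arma::imat& ri,
                  const arma::vec& c, const arma::vec& n0,
                  double t0, const arma::vec& times,
                  double max_events = 5e7) {
  const int ns = n0.n_elem, nr = c.n_elem, nt = times.n_elem;
  arma::mat out(nt, ns, arma::fill::zeros);
  arma::vec n = n0;
  double t = t0;
  int iout = 0;
  double events = 0;
  RNGScope scope;
  while (iout < nt) {
    // propensities
    double a0 = 0.0;
    arma::vec a(nr);
    for (int r = 0; r < nr; ++r) {
      double ar = c[r];
      int i = ri(0, r), j = ri(1, r);
      if (i >= 0) ar *= n[i];
      if (j >= 0) ar *= (i == j) ? (n[j] - 1.0) / 2.0 : n[j];
      if (ar < 0) ar = 0;
      a[r] = ar;
      a0 += ar;
    }
    double tau;
    if (a0 <= 0) {
      tau = R_PosInf;
    } else {
      double u = unif_rand();
      if (u <= 0) u = 1e-300;
      tau = -std::log(u) / a0;
    }
    double tnext = t + tau;
    while (iout < nt && times[iout] < tnext) {
      out.row(iout++) = n.t();
    }
    if (iout >= nt) break;
    if (!std::isfinite(tnext)) break;
    t = tnext;
    // pick reaction
    double target = unif_rand() * a0, cum = 0.0;
    int rsel = nr - 1;
    for (int r = 0; r < nr; ++r) {
      cum += a[r];
      if (target <= cum) { rsel = r; break; }
    }
    n += S.col(rsel);
    for (int i = 0; i < ns; ++i) if (n[i] < 0) n[i] = 0;
    if (++events > max_events)
      stop("SSA exceeded %g events at t = %f s", max_events, t);
  }
  // remaining sample times (system exhausted)
  while (iout < nt) out.row(iout++) = n.t();
  return out;
}
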