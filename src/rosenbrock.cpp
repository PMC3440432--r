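// Stiff integration of mass-action reaction networks.
//
// Generalized Rosenbrock-Wanner stepper (Kaps-Rentrop with Shampine's
// parameter set; 4 stages, order 4 with embedded order-3 error estimate)
// for the autonomous system y' = S v(y), where v_r = k_r * prod of reactant
// concentrations (at most bimolecular).  The Jacobian is assembled
// analytically from the same reaction data, so RHS and Jacobian cannot
// drift apart.  Steps are truncated at every requested report time, so the
// output grid is hit exactly (no dense-output interpolation).

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

const double GAM = 0.5;
const double A21 = 2.0, A31 = 48.0 / 25.0, A32 = 6.0 / 25.0;
const double C21 = -8.0, C31 = 372.0 / 25.0, C32 = 12.0 / 5.0;
const double C41 = -112.0 / 125.0, C42 = -54.0 / 125.0, C43 = -2.0 / 5.0;
const double B1 = 19.0 / 9.0, B2 = 0.5, B3 = 25.0 / 108.0, B4 = 125.0 / 108.0;
const double E1 = 17.0 / 54.0, E2 = 7.0 / 36.0, E3 = 0.0, E4 = 125.0 / 108.0;
const double SAFETY = 0.9, GROW = 1.5, PGROW = -0.25;
const double SHRNK = 0.5, PSHRNK = -1.0 / 3.0, ERRCON = 0.1296;

struct Net {
  arma::mat S;              // n_species x n_reactions
  arma::ivec r1, r2;        // 0-based reactant indices; r2 = -1 if unimolecular
  arma::vec k;

  arma::vec rhs(const arma::vec& y) const {
    arma::vec v(k.n_elem);
    for (arma::uword r = 0; r < k.n_elem; ++r) {
      double f = k[r] * y[r1[r]];
      if (r2[r] >= 0) f *= y[r2[r]];
      v[r] = f;
    }
    return S * v;
  }

  arma::mat jac(const arma::vec& y) const {
    arma::mat J(S.n_rows, S.n_rows, arma::fill::zeros);
    for (arma::uword r = 0; r < k.n_elem; ++r) {
      if (r2[r] < 0) {
        J.col(r1[r]) += k[r] * S.col(r);
      } else {
        // d(k*y1*y2)/dy1 = k*y2, /dy2 = k*y1 (accumulates to 2ky for y1==y2)
        J.col(r1[r]) += k[r] * y[r2[r]] * S.col(r);
        J.col(r2[r]) += k[r] * y[r1[r]] * S.col(r);
      }
    }
    return J;
  }
};

}  // namespace

// [[Rcpp::export(name = ".ros_rhs")]]
arma::vec ros_rhs(const arma::mat& stoich, const arma::ivec& react1,
                  const arma::ivec& react2, const arma::vec& rate,
                  const arma::vec& y) {
  Net net{stoich, react1 - 1, react2 - 1, rate};
  return net.rhs(y);
}

// [[Rcpp::export(name = ".ros_jac")]]
arma::mat ros_jac(const arma::mat& stoich, const arma::ivec& react1,
                  const arma::ivec& react2, const arma::vec& rate,
                  const arma::vec& y) {
  Net net{stoich, react1 - 1, react2 - 1, rate};
  return net.jac(y);
}

// [[Rcpp::export(name = ".ros_integrate")]]
List ros_integrate(const arma::mat& stoich, const arma::ivec& react1,
                   const arma::ivec& react2, const arma::vec& rate,
                   const arma::vec& y0, const arma::vec& times,
                   double rtol, double atol, double max_steps) {
  Net net{stoich, react1 - 1, react2 - 1, rate};
  const arma::uword n = y0.n_elem;
  arma::mat out(times.n_elem, n);
  arma::vec y = y0;
  out.row(0) = y.t();

  double t = times[0];
  double h = std::min(1e-3, (times[times.n_elem - 1] - t) / 10.0);
  long nstep = 0, nreject = 0;
  int status = 0;
  arma::uword bad_species = 0;

  const arma::mat I = arma::eye(n, n);

  for (arma::uword it = 1; it < times.n_elem && status == 0; ++it) {
    const double T = times[it];
    while (t < T) {
      if (++nstep > max_steps) { status = 2; break; }
      bool truncated = false;
      if (h > T - t) { h = T - t; truncated = true; }

      arma::vec f0 = net.rhs(y);
      arma::mat J = net.jac(y);

      double errmax = 0.0;
      arma::vec ynew;
      bool solved = false;
      {
        arma::mat A = I / (GAM * h) - J;
        arma::mat L, U, P;
        if (arma::lu(L, U, P, A)) {
          auto lin = [&](const arma::vec& b) {
            return arma::vec(arma::solve(arma::trimatu(U),
                     arma::solve(arma::trimatl(L), P * b)));
          };
          arma::vec g1 = lin(f0);
          arma::vec f1 = net.rhs(y + A21 * g1);
          arma::vec g2 = lin(f1 + (C21 / h) * g1);
          arma::vec f2 = net.rhs(y + A31 * g1 + A32 * g2);
          arma::vec g3 = lin(f2 + (C31 * g1 + C32 * g2) / h);
          arma::vec g4 = lin(f2 + (C41 * g1 + C42 * g2 + C43 * g3) / h);
          ynew = y + B1 * g1 + B2 * g2 + B3 * g3 + B4 * g4;
          arma::vec err = E1 * g1 + E2 * g2 + E3 * g3 + E4 * g4;
          if (ynew.is_finite()) {
            solved = true;
            for (arma::uword i = 0; i < n; ++i) {
              double sc = atol + rtol * std::max(std::fabs(y[i]),
                                                 std::fabs(ynew[i]));
              errmax = std::max(errmax, std::fabs(err[i]) / sc);
            }
          }
        }
      }

      if (solved && errmax <= 1.0) {
        t += h;
        y = ynew;
        h *= (errmax > ERRCON) ? std::min(GROW, SAFETY * std::pow(errmax, PGROW))
                               : GROW;
      } else {
        ++nreject;
        double fac = solved ? std::max(SHRNK, SAFETY * std::pow(errmax, PSHRNK))
                            : SHRNK;
        h *= fac;
        if (!(t + h > t)) {  // step-size underflow
          status = 1;
          bad_species = arma::index_max(arma::abs(f0));
          break;
        }
      }
      (void)truncated;
    }
    if (status != 0) break;
    out.row(it) = y.t();
  }

  return List::create(
    _["conc"] = out, _["steps"] = (double)nstep, _["rejected"] = (double)nreject,
    _["status"] = status, _["bad_species"] = (double)(bad_species + 1));
}
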