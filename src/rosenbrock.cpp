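// Stiff integration of the reduced normalized linlog mass balances:
// a 4-stage L-stable Rosenbrock method (Shampine coefficient set) with
// embedded 3rd-order error estimate and analytic Jacobian.  Mirrors the
// reference R implementation (engine = "r") exactly in structure; the two
// engines are cross-checked in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LinlogSys {
  const mat& Lhat;   // balanced x active-independent
  const vec& ohat;   // balanced offset (moiety totals + frozen species)
  const mat& NR;     // active-independent x reactions
  const vec& Dind_inv;
  const mat& E;      // reactions x balanced
  const vec& eJ0;
  double clamp;

  // returns false on non-finite state
  bool rhs(const vec& x, vec& dx, vec& chat) const {
    chat = Lhat * x + ohat;
    if (!chat.is_finite()) return false;
    vec lc = log(arma::max(chat, vec(chat.n_elem, fill::value(clamp))));
    vec r = eJ0 % (1.0 + E * lc);
    dx = Dind_inv % (NR * r);
    return dx.is_finite();
  }

  mat jac(const vec& chat) const {
    vec w(chat.n_elem);
    for (uword i = 0; i < chat.n_elem; ++i)
      w(i) = chat(i) > clamp ? 1.0 / chat(i) : 0.0;
    mat A = E;
    A.each_col() %= eJ0;
    A.each_row() %= w.t();
    mat J = NR * (A * Lhat);
    J.each_col() %= Dind_inv;
    return J;
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_rosenbrock")]]
arma::mat cpp_rosenbrock(const arma::mat& Lhat, const arma::vec& ohat,
                         const arma::mat& NR, const arma::vec& Dind_inv,
                         const arma::mat& E, const arma::vec& eJ0,
                         double clamp, arma::vec x, const arma::vec& times,
                         double rtol, double atol, int max_steps) {
  const double GAM = 0.5;
  const double A21 = 2.0, A31 = 48.0 / 25.0, A32 = 6.0 / 25.0;
  const double C21 = -8.0, C31 = 372.0 / 25.0, C32 = 12.0 / 5.0;
  const double C41 = -112.0 / 125.0, C42 = -54.0 / 125.0, C43 = -2.0 / 5.0;
  const double B1 = 19.0 / 9.0, B2 = 0.5, B3 = 25.0 / 108.0, B4 = 125.0 / 108.0;
  const double E1 = 17.0 / 54.0, E2 = 7.0 / 36.0, E3 = 0.0, E4 = 125.0 / 108.0;

  LinlogSys sys{Lhat, ohat, NR, Dind_inv, E, eJ0, clamp};
  const uword n = x.n_elem, nb = ohat.n_elem, nt = times.n_elem;
  mat out(nt, nb);
  out.row(0) = (Lhat * x + ohat).t();

  double t = times(0);
  double h = std::min((times(1) - times(0)) / 10.0, 1.0);
  int n_steps = 0;
  vec dx0(n), dx(n), chat(nb), chat_tmp(nb);

  for (uword k = 1; k < nt; ++k) {
    const double tend = times(k);
    while (t < tend - 1e-12 * std::max(1.0, std::fabs(tend))) {
      if (h > tend - t) h = tend - t;
      if (++n_steps > max_steps)
        Rcpp::stop("integration failure: step budget exhausted at t = %g min", t);

      bool ok = sys.rhs(x, dx0, chat);
      mat Winv;
      if (ok) {
        mat W = -sys.jac(chat);
        W.diag() += 1.0 / (GAM * h);
        ok = inv(Winv, W);
      }
      vec g1, g2, g3, g4, xn;
      double errmax = datum::inf;
      if (ok) {
        auto lusolve = [&](const vec& b) { return vec(Winv * b); };
        g1 = lusolve(dx0);
        ok = sys.rhs(x + A21 * g1, dx, chat_tmp);
        if (ok) {
          g2 = lusolve(dx + C21 * g1 / h);
          ok = sys.rhs(x + A31 * g1 + A32 * g2, dx, chat_tmp);
        }
        if (ok) {
          g3 = lusolve(dx + (C31 * g1 + C32 * g2) / h);
          g4 = lusolve(dx + (C41 * g1 + C42 * g2 + C43 * g3) / h);
          xn = x + B1 * g1 + B2 * g2 + B3 * g3 + B4 * g4;
          ok = xn.is_finite();
        }
        if (ok) {
          vec err = E1 * g1 + E2 * g2 + E3 * g3 + E4 * g4;
          vec sc = atol + rtol * arma::max(abs(x), abs(xn));
          errmax = abs(err / sc).max();
        }
      }
      if (!ok) {
        h /= 10.0;
        if (h < 1e-12)
          Rcpp::stop("integration failure: step size underflow at t = %g min", t);
        continue;
      }
      if (errmax <= 1.0) {
        t += h;
        x = xn;
        h *= std::min(5.0, std::max(0.2, 0.9 * std::pow(errmax, -0.25)));
      } else {
        h *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
        if (h < 1e-12)
          Rcpp::stop("integration failure: step size underflow at t = %g min", t);
      }
    }
    out.row(k) = (Lhat * x + ohat).t();
  }
  return out;
}
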