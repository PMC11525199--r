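#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Kolmogorov backward equations of the three-type branching process
// (progenitor, post-mitotic basal, first-suprabasal), evaluated on an
// m_size x n_size grid of roots of unity and integrated by fixed-step RK4.
// Returns the PGF of the founding state at each requested time; the R side
// inverts it with a 2D FFT. F_S and F_D have closed forms; only F_P needs
// numerical integration.
// [[Rcpp::export]]
List pgf_integrate_cpp(int m_size, int n_size, double lam, double a, double b,
                       double c, double gam, double mu, IntegerVector state0,
                       NumericVector t_weeks, int n_steps) {
  typedef std::complex<double> cplx;
  const int G = m_size * n_size;
  const double PI2 = 6.283185307179586476925286766559;
  std::vector<cplx> X(G), Z(G), Fp(G);
  for (int j = 0; j < n_size; ++j) {
    cplx z = std::polar(1.0, PI2 * j / n_size);
    for (int i = 0; i < m_size; ++i) {
      cplx x = std::polar(1.0, PI2 * i / m_size);
      X[i + m_size * j] = x;
      Z[i + m_size * j] = z;
      Fp[i + m_size * j] = x;
    }
  }
  const bool same_rate = std::fabs(gam - mu) <= 1e-10;
  // F_D(t) = x e^{-gam t} + (1 - e^{-gam t}) + gam (z - 1) q(t)
  auto fd_scalars = [&](double t, double &eg, double &q) {
    eg = std::exp(-gam * t);
    q = same_rate ? t * eg : (std::exp(-mu * t) - eg) / (gam - mu);
  };
  std::vector<cplx> k1(G), k2(G), k3(G), k4(G), tmp(G);
  auto deriv = [&](const std::vector<cplx> &F, double eg, double q,
                   std::vector<cplx> &out) {
    for (int g = 0; g < G; ++g) {
      cplx gd = X[g] * eg + (1.0 - eg) + gam * (Z[g] - 1.0) * q;
      out[g] = lam * (a * F[g] * F[g] + b * F[g] * gd + c * gd * gd - F[g]);
    }
  };

  double t_max = 0.0;
  for (int i = 0; i < t_weeks.size(); ++i)
    if (t_weeks[i] > t_max) t_max = t_weeks[i];
  const double h_all = (n_steps > 0 && t_max > 0) ? t_max / n_steps : 1.0;

  List out(t_weeks.size());
  double t_now = 0.0;
  for (int i = 0; i < t_weeks.size(); ++i) {
    const double target = t_weeks[i];
    while (t_now < target - 1e-12) {
      const double h = std::min(h_all, target - t_now);
      double eg0, q0, egh, qh, eg1, q1;
      fd_scalars(t_now, eg0, q0);
      fd_scalars(t_now + h / 2, egh, qh);
      fd_scalars(t_now + h, eg1, q1);
      deriv(Fp, eg0, q0, k1);
      for (int g = 0; g < G; ++g) tmp[g] = Fp[g] + h / 2 * k1[g];
      deriv(tmp, egh, qh, k2);
      for (int g = 0; g < G; ++g) tmp[g] = Fp[g] + h / 2 * k2[g];
      deriv(tmp, egh, qh, k3);
      for (int g = 0; g < G; ++g) tmp[g] = Fp[g] + h * k3[g];
      deriv(tmp, eg1, q1, k4);
      for (int g = 0; g < G; ++g)
        Fp[g] += h / 6 * (k1[g] + 2.0 * k2[g] + 2.0 * k3[g] + k4[g]);
      t_now += h;
    }
    double eg, q;
    fd_scalars(t_now, eg, q);
    ComplexMatrix total(m_size, n_size);
    for (int g = 0; g < G; ++g) {
      cplx fd = X[g] * eg + (1.0 - eg) + gam * (Z[g] - 1.0) * q;
      cplx fs = 1.0 + (Z[g] - 1.0) * std::exp(-mu * t_now);
      cplx v = 1.0;
      for (int r = 0; r < state0[0]; ++r) v *= Fp[g];
      for (int r = 0; r < state0[1]; ++r) v *= fd;
      for (int r = 0; r < state0[2]; ++r) v *= fs;
      total[g].r = v.real();
      total[g].i = v.imag();
    }
    out[i] = total;
  }
  return out;
}
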